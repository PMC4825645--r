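{
  "n_f1_families": 47,
  "alleles_per_genome_mean": 0.48,
  "class_probabilities": {
    "ZYGOTIC_LETHAL": 0.6,
    "STERILE_TYPE_I": 0.15,
    "STERILE_TYPE_II": 0.1,
    "VISIBLE_VIABLE": 0.15
  },
  "penetrance": 1,
  "maternal_dominance": 0,
  "f2_cohort_size_range": [2, 13],
  "primary_male_rate": 0.036,
  "eggless_window_sessions": 24,
  "sessions_observed": 24,
  "rearing_survival": 0.95,
  "seed": 2016
}
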