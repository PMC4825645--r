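# killiscreen

Simulation and analysis of simultaneous zygotic/sterile forward-genetic
screens in self-fertilizing hermaphroditic fish.

The mangrove killifish (*Kryptolebias marmoratus*) is the only known
self-fertilizing hermaphroditic vertebrate. Selfing makes it unusually
efficient for forward genetics: a heterozygous carrier (*m/+*) of an
ENU-induced recessive allele produces, by simply selfing, offspring in the
Mendelian 1:2:1 ratio, so 25% of screened individuals are homozygous
mutants — against 1/16 in a gonochoristic (separate-sex) model such as
zebrafish, and with one generation fewer. `killiscreen` packages the
quantitative machinery of such a screen for people designing or analysing
one:

* **exact selfing genetics** — offspring genotype distributions under
  self-fertilization, survivor-conditioned distributions (a selfed
  carrier of an embryonic lethal leaves surviving fish at 2 carriers :
  1 wild-type), and seeded sampling;
* **a gene-drop screen simulator** — four generations (F1 founders
  heterozygous for a Poisson load of induced alleles, F2 cohorts, F3/F4
  clutch collections over discrete sessions) with embryonic lethality,
  maternal-effect (Type I) and non-egg-layer (Type II) sterility,
  per-allele penetrance, partial dominant maternal effects, primary
  males, rearing loss and background embryo attrition, emitting tidy
  pedigree and per-embryo clutch tables plus a ground-truth table;
* **the screen's decision rules** — a fish is Type I sterile when ≥ 20
  scored embryos are ≥ 90% nonviable-or-unfertilized, Type II when no
  eggs appear over a > 2-month window; fertile fish are called zygotic
  carriers from mutant-phenotype embryo counts; parents are
  backward-genotyped from reared descendants (≥ 1 sterile descendant ⇒
  carrier; ≥ 8 all-fertile ⇒ wild-type; otherwise the honest `*/+`
  undetermined class);
* **screen-design power calculations** — detection probability
  `1 − (1 − p)^n` and minimum cohort sizes for selfing (p = 1/4) versus
  gonochoristic intercross (p = 1/16) designs;
* **segregation statistics** — Pearson chi-square goodness-of-fit tests
  with per-cell contributions, including the integer-rounded
  expected-count dialect used in printed screen tables, with broom-style
  `tidy()`/`glance()` and `autoplot()` methods.

Everything takes and returns plain data frames/tibbles, so the pieces
compose with the pipe.

## Worked example

Test whether 92 observed wild-type and 189 carrier F2 fish are consistent
with the 1 : 2 ratio expected among survivors of a selfed zygotic-lethal
carrier, using integer-rounded expected counts:

```r
library(killiscreen)

segregation_test(c(92, 189), c(1, 2), "PAPER_INTEGER")
#> Chi-square goodness of fit
#>                [,1]    [,2]
#> Observed     92.000 189.000
#> Expected     94.000 187.000
#> Contribution  0.043   0.021
#> chi-square = 0.064, df = 1, critical value = 3.84 (alpha = 0.05)
#> counts are consistent with the expected ratio
```

A chi-square of 0.064 on df = 1 is far below the 3.84 critical value:
the cohort segregates as expected for a recessive embryonic lethal.

Compare breeding designs at the 90% detection level:

```r
design_comparison(0.90)
#> # A tibble: 4 × 6
#>   system                        p convention      n_required detection_probability generations_to_homozygote
#>   <chr>                     <dbl> <chr>                <int>                 <dbl>                     <int>
#> 1 SELFING                  0.25   STRICT                   9                 0.925                         2
#> 2 SELFING                  0.25   NEAREST_PERCENT          8                 0.900                         2
#> 3 GONOCHORISTIC_INTERCROSS 0.0625 STRICT                  36                 0.902                         3
#> 4 GONOCHORISTIC_INTERCROSS 0.0625 NEAREST_PERCENT         35                 0.896                         3
```

Eight selfing fish match the detection power of 35 intercrosses, one
generation earlier.

Simulate a screen and run the classifier against it:

```r
cfg  <- screen_config(n_f1_families = 12, seed = 2016)
sim  <- simulate_screen(cfg)
sim
#> <screen_simulation>
#>   families: 12 | fish: 211 | embryos: 17537
#>   truth: CARRIER=36 PRIMARY_MALE=5 STERILE_I=9 WILD_TYPE=139

calls <- classify_screen(sim$pedigree, sim$clutches)
calls
#> <screen_calls>
#>   calls: CARRIER=12 PRIMARY_MALE=5 STERILE_I=9 WILD_TYPE=163
#>   families: 12
```

All 9 truly sterile fish are called sterile; the excess of `WILD_TYPE`
calls over the truth is expected — heterozygous carriers of *sterile*
alleles look fertile and wild-type from their own clutches and are only
resolved by backward genotyping (`calls$calls$backward_call`).

## File formats

`write_pedigree()` / `read_pedigree()` use a single-parent TSV dialect
(standard two-parent pedigree formats cannot express selfing):
`fish_id`, `family_id`, `generation` (P/F1/F2/F3/F4), `parent_id`,
`role` (HERMAPHRODITE/PRIMARY_MALE), `status` (ADULT/JUVENILE_DEATH/...),
`sessions_observed`, and optional `true_genotype`. Clutch tables carry
one row per embryo: `embryo_id`, `parent_id`, `family_id`,
`session_index`, `fertilized` (0/1), `viable` (0/1), `phenotype_labels`
(semicolon-joined). Missing values are `.`. Configurations are single
JSON objects; unknown keys are rejected.

A thin command-line front end over these functions lives in
`inst/cli/killiscreen.R` (subcommands `simulate`, `classify`, `power`,
`gof`, `reproduce`).

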