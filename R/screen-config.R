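#' Allele functional classes
#'
#' The four functional classes of induced recessive alleles the simulator
#' models: embryonic-lethal zygotic alleles, maternal-effect sterility
#' (Type I: homozygous mothers lay fertilized but nonviable eggs),
#' non-egg-layer sterility (Type II: ovotestis/anatomical defects, no eggs
#' laid), and homozygous-viable visible alleles (e.g. pigmentation).
#'
#' @export
allele_classes <- function() {
  c("ZYGOTIC_LETHAL", "STERILE_TYPE_I", "STERILE_TYPE_II", "VISIBLE_VIABLE")
}

#' Screen simulator configuration
#'
#' Bundles every parameter of the multi-generation screen simulation.
#' Defaults emulate the study conditions of a simultaneous zygotic/sterile
#' ENU screen in a selfing killifish: a Poisson allele load calibrated so
#' roughly a quarter of mutagenized genomes carry at least one zygotic
#' lethal, F2 cohorts of 2-13 scored fish per family, a 3.6% primary-male
#' rate, clutches collected three times a week, and a two-month (24
#' session) egg-collection window per adult.
#'
#' @param n_f1_families Number of mutagenized F1 founder lineages.
#' @param alleles_per_genome_mean Poisson mean of induced recessive
#'   alleles per mutagenized genome. The default 0.48, combined with the
#'   default class probabilities, gives a zygotic-lethal class mean of
#'   about 0.29, i.e. ~25% of genomes carry at least one zygotic lethal.
#' @param alleles_per_genome Optional fixed allele count per genome
#'   (overrides the Poisson draw); useful for controlled experiments with
#'   exactly one allele per founder.
#' @param class_probabilities Named probabilities over
#'   [allele_classes()]; must sum to 1.
#' @param penetrance Probability that a homozygote expresses the mutant
#'   phenotype (zygotic lethality, sterility, or visible marker).
#' @param maternal_dominance Probability that a *heterozygous* Type I
#'   mother expresses the maternal effect (partial dominance); 0 under
#'   simple recessive inheritance.
#' @param f2_cohort_size_range Integer range (min, max) of F2 fish scored
#'   per family; drawn uniformly.
#' @param primary_male_rate Bernoulli probability that a reared fish is a
#'   primary male (genotype-independent); males lay no clutches.
#' @param clutch_size_mean,clutch_size_max Embryos per collection session
#'   are Poisson(`clutch_size_mean`) truncated to `[0, clutch_size_max]`.
#' @param sessions_per_week Collection sessions per week (cadence only;
#'   used to convert the two-month eggless criterion into sessions).
#' @param min_sessions_to_maturity Sessions elapsed before collection
#'   starts (collection is assumed to begin at sexual maturity).
#' @param eggless_window_sessions Sessions with zero eggs needed before a
#'   fish can be called a Type II (non-egg-layer) sterile; default 24
#'   (3 sessions/week for ~8 weeks).
#' @param sessions_observed Collection sessions simulated per adult.
#' @param rearing_survival Probability a viable embryo selected for
#'   rearing survives to adulthood.
#' @param background_nonviable Baseline probability that an embryo from a
#'   fertile mother is nonviable for reasons unrelated to the induced
#'   alleles (clutch attrition is substantial even in nonsterile lines).
#' @param background_unfertilized Baseline probability an egg is laid
#'   unfertilized (no perivitelline halo); unfertilized eggs are never
#'   viable.
#' @param n_f3_reared_per_f2 F3 fish reared to adulthood per fertile F2
#'   parent in families selected for sterile confirmation.
#' @param rear_f3 Which families rear F3 to adulthood:
#'   `"sterile_families"` (only families with a sterile F2, the
#'   confirmation design), `"all"`, or `"none"`.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(n_f1_families = 47L,
                          alleles_per_genome_mean = 0.48,
                          alleles_per_genome = NULL,
                          class_probabilities = c(
                            ZYGOTIC_LETHAL = 0.60,
                            STERILE_TYPE_I = 0.15,
                            STERILE_TYPE_II = 0.10,
                            VISIBLE_VIABLE = 0.15
                          ),
                          penetrance = 1,
                          maternal_dominance = 0,
                          f2_cohort_size_range = c(2L, 13L),
                          primary_male_rate = 0.036,
                          clutch_size_mean = 4,
                          clutch_size_max = 25L,
                          sessions_per_week = 3L,
                          min_sessions_to_maturity = 0L,
                          eggless_window_sessions = 24L,
                          sessions_observed = 24L,
                          rearing_survival = 0.95,
                          background_nonviable = 0.20,
                          background_unfertilized = 0.02,
                          n_f3_reared_per_f2 = 6L,
                          rear_f3 = c("sterile_families", "all", "none"),
                          seed = 1L) {
  rear_f3 <- match.arg(rear_f3)
  cfg <- list(
    n_f1_families = as.integer(n_f1_families),
    alleles_per_genome_mean = alleles_per_genome_mean,
    alleles_per_genome = if (is.null(alleles_per_genome)) NULL else as.integer(alleles_per_genome),
    class_probabilities = class_probabilities,
    penetrance = penetrance,
    maternal_dominance = maternal_dominance,
    f2_cohort_size_range = as.integer(f2_cohort_size_range),
    primary_male_rate = primary_male_rate,
    clutch_size_mean = clutch_size_mean,
    clutch_size_max = as.integer(clutch_size_max),
    sessions_per_week = as.integer(sessions_per_week),
    min_sessions_to_maturity = as.integer(min_sessions_to_maturity),
    eggless_window_sessions = as.integer(eggless_window_sessions),
    sessions_observed = as.integer(sessions_observed),
    rearing_survival = rearing_survival,
    background_nonviable = background_nonviable,
    background_unfertilized = background_unfertilized,
    n_f3_reared_per_f2 = as.integer(n_f3_reared_per_f2),
    rear_f3 = rear_f3,
    seed = as.integer(seed)
  )
  validate_screen_config(cfg)
}

validate_screen_config <- function(cfg) {
  err <- function(msg) rlang::abort(paste0("invalid screen_config: ", msg))
  prob_fields <- c(
    "penetrance", "maternal_dominance", "primary_male_rate",
    "rearing_survival", "background_nonviable", "background_unfertilized"
  )
  for (f in prob_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      err(paste0(f, " must be a single probability in [0, 1]"))
    }
  }
  cp <- cfg$class_probabilities
  if (is.null(names(cp)) || !all(names(cp) %in% allele_classes())) {
    err("class_probabilities must be named by allele classes")
  }
  if (any(cp < 0) || any(cp > 1)) err("class_probabilities must lie in [0, 1]")
  if (abs(sum(cp) - 1) > 1e-9) err("class_probabilities must sum to 1")
  if (cfg$n_f1_families < 1) err("n_f1_families must be positive")
  if (is.na(cfg$alleles_per_genome_mean) || cfg$alleles_per_genome_mean < 0) {
    err("alleles_per_genome_mean must be nonnegative")
  }
  if (!is.null(cfg$alleles_per_genome) && cfg$alleles_per_genome < 0) {
    err("alleles_per_genome must be nonnegative")
  }
  r <- cfg$f2_cohort_size_range
  if (length(r) != 2 || any(r < 1) || r[1] > r[2]) {
    err("f2_cohort_size_range must be an increasing pair of positive integers")
  }
  for (f in c("clutch_size_max", "sessions_per_week", "eggless_window_sessions",
              "sessions_observed", "n_f3_reared_per_f2")) {
    if (cfg[[f]] < 1) err(paste0(f, " must be positive"))
  }
  if (cfg$min_sessions_to_maturity < 0) err("min_sessions_to_maturity must be nonnegative")
  if (cfg$clutch_size_mean < 0) err("clutch_size_mean must be nonnegative")
  structure(cfg, class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat("  families:", x$n_f1_families,
      "| allele load:", if (is.null(x$alleles_per_genome)) {
        paste0("Poisson(", x$alleles_per_genome_mean, ")")
      } else {
        paste0("fixed ", x$alleles_per_genome)
      }, "\n")
  cat("  class probabilities:",
      paste(names(x$class_probabilities), signif(x$class_probabilities, 3),
            sep = "=", collapse = " "), "\n")
  cat("  penetrance:", x$penetrance,
      "| maternal dominance:", x$maternal_dominance, "\n")
  cat("  F2 cohort:", paste(x$f2_cohort_size_range, collapse = "-"),
      "| male rate:", x$primary_male_rate,
      "| rearing survival:", x$rearing_survival, "\n")
  cat("  sessions observed:", x$sessions_observed,
      "| clutch ~ Poisson(", x$clutch_size_mean, ") | seed:", x$seed, "\n")
  invisible(x)
}

#' Classification rules for clutch-based phenotype calls
#'
#' Decision thresholds for sterility and carrier calling. Defaults follow
#' the screen's criteria: a fish is Type I sterile when, after scoring at
#' least 20 embryos, 90% or more are nonviable or unfertilized; Type II
#' sterile when no eggs appear over a window greater than two months
#' (24 thrice-weekly sessions) after maturity; a fertile fish is called a
#' zygotic carrier when at least 2 scored embryos show a family mutant
#' phenotype; a wild-type backward-genotype call requires at least 8
#' fertile reared descendants (residual miss probability 0.75^8 = 10%).
#'
#' @param min_embryos_scored Minimum embryos scored before a Type I or
#'   carrier/wild-type call is attempted.
#' @param nonviable_fraction_threshold Pooled nonviable-or-unfertilized
#'   fraction at or above which a fish is Type I sterile.
#' @param eggless_window_sessions Zero-egg sessions required for a
#'   Type II call.
#' @param carrier_min_mutant_embryos Minimum embryos with a family mutant
#'   phenotype for a carrier call.
#' @param backward_sterile_fraction Expected sterile fraction among
#'   offspring of a carrier (reported with backward-genotype evidence).
#' @param wildtype_min_fertile_offspring Fertile reared descendants
#'   required before an all-fertile sibship supports a wild-type call;
#'   fewer yields the undetermined `*/+` class.
#' @param confirm_total_embryos Target embryo count for confirming a
#'   sterile call (recorded in evidence; not a gate).
#' @return A list of class `classification_rules`.
#' @export
classification_rules <- function(min_embryos_scored = 20L,
                                 nonviable_fraction_threshold = 0.90,
                                 eggless_window_sessions = 24L,
                                 carrier_min_mutant_embryos = 2L,
                                 backward_sterile_fraction = 0.25,
                                 wildtype_min_fertile_offspring = 8L,
                                 confirm_total_embryos = 100L) {
  rules <- list(
    min_embryos_scored = as.integer(min_embryos_scored),
    nonviable_fraction_threshold = nonviable_fraction_threshold,
    eggless_window_sessions = as.integer(eggless_window_sessions),
    carrier_min_mutant_embryos = as.integer(carrier_min_mutant_embryos),
    backward_sterile_fraction = backward_sterile_fraction,
    wildtype_min_fertile_offspring = as.integer(wildtype_min_fertile_offspring),
    confirm_total_embryos = as.integer(confirm_total_embryos)
  )
  if (rules$min_embryos_scored < 1) {
    rlang::abort("min_embryos_scored must be at least 1")
  }
  if (rules$nonviable_fraction_threshold < 0 || rules$nonviable_fraction_threshold > 1) {
    rlang::abort("nonviable_fraction_threshold must lie in [0, 1]")
  }
  if (rules$backward_sterile_fraction < 0 || rules$backward_sterile_fraction > 1) {
    rlang::abort("backward_sterile_fraction must lie in [0, 1]")
  }
  if (rules$eggless_window_sessions < 1 || rules$carrier_min_mutant_embryos < 1 ||
      rules$wildtype_min_fertile_offspring < 1 || rules$confirm_total_embryos < 1) {
    rlang::abort("count thresholds must be positive")
  }
  structure(rules, class = "classification_rules")
}
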