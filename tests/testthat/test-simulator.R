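one_allele_config <- function(class, ..., seed = 1) {
  probs <- stats::setNames(rep(0, 4), allele_classes())
  probs[class] <- 1
  screen_config(alleles_per_genome = 1, class_probabilities = probs,
                seed = seed, ...)
}

test_that("a null screen (no induced alleles) is all wild-type", {
  cfg <- screen_config(n_f1_families = 4, alleles_per_genome = 0,
                       background_nonviable = 0, background_unfertilized = 0,
                       seed = 3)
  sim <- simulate_screen(cfg)
  expect_true(all(sim$clutches$viable))
  expect_true(all(sim$truth$true_class %in% c("WILD_TYPE", "PRIMARY_MALE")))
  expect_true(all(sim$pedigree$true_genotype == "+/+"))
})

test_that("clutch conservation: fertilized-nonviable + unfertilized + viable = size", {
  cfg <- one_allele_config("ZYGOTIC_LETHAL", n_f1_families = 6, seed = 11)
  sim <- simulate_screen(cfg)
  cl <- sim$clutches
  n_viable <- sum(cl$viable)
  n_fert_nonviable <- sum(cl$fertilized & !cl$viable)
  n_unfert <- sum(!cl$fertilized)
  expect_equal(n_viable + n_fert_nonviable + n_unfert, nrow(cl))
  expect_true(all(cl$fertilized[cl$viable]))  # viable implies fertilized
})

test_that("the same seed gives bit-identical pedigree and clutch tables", {
  cfg <- screen_config(n_f1_families = 5, seed = 99)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$clutches, b$clutches)
  expect_identical(a$truth, b$truth)
})

test_that("expressed Type I mothers lay fully fertilized, fully nonviable clutches", {
  cfg <- one_allele_config("STERILE_TYPE_I", seed = 5)
  alleles <- mutant_allele("s1", "STERILE_TYPE_I", "maternal effect")
  set.seed(5)
  emb <- dplyr::bind_rows(lapply(1:30, function(i) {
    simulate_clutch(c(s1 = 2), i, cfg, alleles, parent_id = "mom",
                    maternal_effect = TRUE)
  }))
  expect_gt(nrow(emb), 0)
  expect_true(all(emb$fertilized))
  expect_false(any(emb$viable))
})

test_that("expressed Type II mothers lay no eggs at all", {
  cfg <- one_allele_config("STERILE_TYPE_II", seed = 5)
  alleles <- mutant_allele("s2", "STERILE_TYPE_II", "nonegg layer")
  set.seed(5)
  emb <- dplyr::bind_rows(lapply(1:24, function(i) {
    simulate_clutch(c(s2 = 2), i, cfg, alleles, parent_id = "mom",
                    no_egg_layer = TRUE)
  }))
  expect_equal(nrow(emb), 0)
})

test_that("mutant-phenotype fraction reflects penetrance (0.25 x penetrance)", {
  cfg <- one_allele_config("ZYGOTIC_LETHAL", penetrance = 0.6, seed = 21,
                           background_nonviable = 0.1)
  alleles <- mutant_allele("m1", "ZYGOTIC_LETHAL", "curly tail", penetrance = 0.6)
  set.seed(21)
  emb <- dplyr::bind_rows(lapply(1:2600, function(i) {
    simulate_clutch(c(m1 = 1), i, cfg, alleles, parent_id = "mom")
  }))
  expect_gte(nrow(emb), 10000)
  fert <- emb[emb$fertilized, ]  # phenotype scored on fertilized eggs only
  frac <- mean(nzchar(fert$phenotype_labels))
  expect_true(within_3sd(frac, 0.25 * 0.6, nrow(fert)))
})

test_that("rearing respects survival and primary-male parameters", {
  cfg <- screen_config(rearing_survival = 1, primary_male_rate = 0, seed = 1)
  embryos <- tibble::tibble(
    embryo_id = paste0("e", 1:200), viable = TRUE
  )
  set.seed(2)
  reared <- rear_cohort(embryos, cfg, id_prefix = "x")
  expect_equal(nrow(reared), 200)
  expect_true(all(reared$status == "ADULT"))
  expect_true(all(reared$role == "HERMAPHRODITE"))

  # male fraction matches the configured Bernoulli rate
  cfg2 <- screen_config(rearing_survival = 1, primary_male_rate = 0.036, seed = 1)
  big <- tibble::tibble(embryo_id = paste0("e", 1:10000), viable = TRUE)
  set.seed(8)
  reared2 <- rear_cohort(big, cfg2, id_prefix = "y")
  frac_male <- mean(reared2$role == "PRIMARY_MALE")
  expect_true(within_3sd(frac_male, 0.036, 10000))

  # no viable embryos: warning and empty cohort (allele loss)
  none <- tibble::tibble(embryo_id = "e1", viable = FALSE)
  expect_warning(out <- rear_cohort(none, cfg, id_prefix = "z"), "no viable")
  expect_equal(nrow(out), 0)
})

test_that("allele loss by drift: both survivors wild-type with probability 1/9", {
  # cohort of 2 survivors of a selfed m/+ with lethal m/m: each is +/+
  # with probability 1/3 independently
  set.seed(31)
  n_rep <- 10000
  d <- self_cross_distribution(c(m = 1))
  surv <- survivor_distribution(d, "m")
  draws1 <- sample(surv$m, n_rep, replace = TRUE, prob = surv$prob)
  draws2 <- sample(surv$m, n_rep, replace = TRUE, prob = surv$prob)
  both_wt <- mean(draws1 == 0 & draws2 == 0)
  expect_true(within_3sd(both_wt, 1 / 9, n_rep))
})

test_that("surviving F2 adults of zygotic-lethal carriers are 2/3 carriers", {
  cfg <- one_allele_config("ZYGOTIC_LETHAL", n_f1_families = 120,
                           f2_cohort_size_range = c(8, 8),
                           primary_male_rate = 0, seed = 17)
  sim <- simulate_screen(cfg)
  f2 <- sim$truth[sim$truth$generation == "F2", ]
  n <- nrow(f2)
  expect_gte(n, 900)
  expect_true(within_3sd(mean(f2$zygotic_carrier), 2 / 3, n))
  # no homozygous mutant survives at penetrance 1
  expect_false(any(grepl("=2", sim$pedigree$true_genotype[
    sim$pedigree$generation == "F2"])))
})

test_that("a quarter of F2 adults from Type I sterile founders are sterile", {
  cfg <- one_allele_config("STERILE_TYPE_I", n_f1_families = 100,
                           f2_cohort_size_range = c(10, 10),
                           primary_male_rate = 0, rear_f3 = "none", seed = 23)
  sim <- simulate_screen(cfg)
  f2 <- sim$truth[sim$truth$generation == "F2", ]
  n <- nrow(f2)
  expect_true(within_3sd(mean(f2$true_class == "STERILE_I"), 0.25, n))
})

test_that("maternal dominance raises the sterile fraction among F3 of carriers", {
  run_frac <- function(md, seed) {
    cfg <- one_allele_config("STERILE_TYPE_I", n_f1_families = 60,
                             f2_cohort_size_range = c(8, 8),
                             maternal_dominance = md,
                             primary_male_rate = 0, seed = seed)
    sim <- simulate_screen(cfg)
    f3 <- dplyr::inner_join(
      sim$truth[sim$truth$generation == "F3", ],
      dplyr::select(sim$pedigree, "fish_id", "parent_id"), by = "fish_id"
    )
    parents <- sim$pedigree[match(f3$parent_id, sim$pedigree$fish_id), ]
    from_carrier <- grepl("=1", parents$true_genotype)
    mean(f3$true_class[from_carrier] %in% c("STERILE_I", "STERILE_II"))
  }
  f0 <- run_frac(0, 41)
  f5 <- run_frac(0.5, 41)
  n_eff <- 500  # conservative lower bound on reared F3 of carriers
  expect_true(abs(f0 - 0.25) <= 3 * sqrt(0.25 * 0.75 / n_eff))
  expect_gt(f5, f0 + 0.1)
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(screen_config(primary_male_rate = 1.5), "probability")
  expect_error(screen_config(class_probabilities = c(ZYGOTIC_LETHAL = 0.5)),
               "sum to 1")
  expect_error(screen_config(f2_cohort_size_range = c(5, 2)), "increasing")
  expect_error(screen_config(alleles_per_genome_mean = -1), "nonnegative")
})
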