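# build a one-row clutch summary directly
make_summary <- function(parent_id = "f1", n_scored, n_nonviable = 0,
                         n_unfertilized = 0, mutant = integer(0),
                         sessions_observed = 24, sessions_spanned = NULL) {
  if (is.null(sessions_spanned)) sessions_spanned <- min(n_scored, sessions_observed)
  tibble::tibble(
    parent_id = parent_id,
    n_scored = as.integer(n_scored),
    n_viable = as.integer(n_scored - n_nonviable),
    n_nonviable = as.integer(n_nonviable),
    n_unfertilized = as.integer(n_unfertilized),
    mutant_counts = list(mutant),
    sessions_spanned = as.integer(sessions_spanned),
    sessions_with_zero_eggs = as.integer(sessions_observed - sessions_spanned)
  )
}

test_that("clutch summaries aggregate counts and sessions per parent", {
  clutches <- tibble::tibble(
    parent_id = rep("f1", 20),
    session_index = rep(1:3, c(7, 8, 5)),
    fertilized = rep(TRUE, 20),
    viable = rep(TRUE, 20),
    phenotype_labels = rep("", 20)
  )
  s <- summarize_clutches(clutches, sessions_observed = 24)
  expect_equal(s$n_scored, 20)
  expect_equal(s$n_viable, 20)
  expect_equal(s$n_nonviable, 0)
  expect_equal(s$sessions_spanned, 3)
  expect_equal(s$sessions_with_zero_eggs, 21)

  # 18 fertilized-nonviable + 2 viable
  clutches2 <- tibble::tibble(
    parent_id = "f2", session_index = rep(1L, 20),
    fertilized = TRUE, viable = rep(c(FALSE, TRUE), c(18, 2)),
    phenotype_labels = ""
  )
  s2 <- summarize_clutches(clutches2)
  expect_equal(s2$n_nonviable, 18)
  expect_equal(s2$n_viable, 2)

  # a parent with no embryo rows at all gets an all-empty summary
  obs <- tibble::tibble(fish_id = c("f1", "f3"), sessions_observed = c(24L, 24L))
  s3 <- summarize_clutches(clutches, sessions_observed = obs)
  row3 <- s3[s3$parent_id == "f3", ]
  expect_equal(row3$n_scored, 0)
  expect_equal(row3$sessions_with_zero_eggs, 24)

  # phenotype labels are tallied per label
  clutches4 <- tibble::tibble(
    parent_id = "f4", session_index = 1:3, fertilized = TRUE,
    viable = c(TRUE, FALSE, FALSE),
    phenotype_labels = c("", "curly tail", "curly tail;dwarf")
  )
  counts <- summarize_clutches(clutches4)$mutant_counts[[1]]
  expect_equal(counts[["curly tail"]], 2L)
  expect_equal(counts[["dwarf"]], 1L)

  expect_error(
    summarize_clutches(tibble::tibble(
      parent_id = "x", session_index = 1L, fertilized = FALSE, viable = TRUE,
      phenotype_labels = ""
    )),
    "cannot be viable"
  )
})

test_that("Type I sterility needs >= 20 scored and >= 90% nonviable", {
  rules <- classification_rules()
  expect_equal(call_sterility(make_summary(n_scored = 20, n_nonviable = 19),
                              rules)$call, "STERILE_I")
  expect_equal(call_sterility(make_summary(n_scored = 20, n_nonviable = 18),
                              rules)$call, "STERILE_I")  # 0.90 exactly
  expect_equal(call_sterility(make_summary(n_scored = 20, n_nonviable = 17),
                              rules)$call, "FERTILE")    # 0.85
  expect_equal(call_sterility(make_summary(n_scored = 19, n_nonviable = 19),
                              rules)$call, "INDETERMINATE")
})

test_that("Type II sterility needs a full eggless window", {
  rules <- classification_rules()
  expect_equal(call_sterility(make_summary(n_scored = 0, sessions_observed = 24,
                                           sessions_spanned = 0), rules)$call,
               "STERILE_II")
  expect_equal(call_sterility(make_summary(n_scored = 0, sessions_observed = 10,
                                           sessions_spanned = 0), rules)$call,
               "INDETERMINATE")
})

test_that("sterility calls validate their input", {
  bad <- make_summary(n_scored = 20, n_nonviable = 5)
  bad$n_viable <- 10L
  expect_error(call_sterility(bad), "inconsistent")
})

test_that("carrier calls use the mutant-embryo count threshold", {
  rules <- classification_rules()
  fam <- c("curly tail")
  s5 <- make_summary(n_scored = 20, n_nonviable = 5,
                     mutant = c(`curly tail` = 5L))
  expect_equal(call_zygotic_carrier(s5, fam, rules)$call, "CARRIER")
  s0 <- make_summary(n_scored = 20)
  expect_equal(call_zygotic_carrier(s0, fam, rules)$call, "WILD_TYPE")
  s1 <- make_summary(n_scored = 20, n_nonviable = 1,
                     mutant = c(`curly tail` = 1L))
  expect_equal(call_zygotic_carrier(s1, fam, rules)$call, "WILD_TYPE")
  loose <- classification_rules(carrier_min_mutant_embryos = 1)
  expect_equal(call_zygotic_carrier(s1, fam, loose)$call, "CARRIER")
  # labels outside the family set do not count
  s_other <- make_summary(n_scored = 20, n_nonviable = 5,
                          mutant = c(dwarf = 5L))
  expect_equal(call_zygotic_carrier(s_other, fam, rules)$call, "WILD_TYPE")
  # too few embryos: indeterminate, not an error
  s_few <- make_summary(n_scored = 10, mutant = c(`curly tail` = 3L))
  expect_equal(call_zygotic_carrier(s_few, fam, rules)$call, "INDETERMINATE")
})

test_that("backward genotyping follows descendant sterility", {
  rules <- classification_rules()
  expect_equal(
    backward_genotype("p", c(rep("STERILE_I", 3), rep("FERTILE", 7)), rules)$call,
    "CARRIER"
  )
  expect_equal(backward_genotype("p", rep("FERTILE", 8), rules)$call, "WILD_TYPE")
  expect_equal(backward_genotype("p", rep("FERTILE", 3), rules)$call, "STAR_PLUS")
  expect_equal(backward_genotype("p", character(0), rules)$call, "STAR_PLUS")
  # a carrier call always has at least one sterile descendant behind it
  for (k in 0:5) {
    calls <- c(rep("STERILE_II", k), rep("FERTILE", 8))
    got <- backward_genotype("p", calls, rules)
    if (got$call == "CARRIER") expect_gte(got$n_sterile_offspring, 1)
  }
})

test_that("family categories name the union of confirmed types", {
  expect_equal(categorize_family(c("CARRIER", "CARRIER", "WILD_TYPE")), "Zygotic")
  expect_equal(
    categorize_family(c("STERILE_I", "STERILE_II", "CARRIER", "WILD_TYPE")),
    "Sterile I and II/zygotic"
  )
  expect_equal(categorize_family(c("WILD_TYPE", "WILD_TYPE")),
               "Zygotic not confirmed")
  expect_equal(categorize_family(c("STERILE_I", "WILD_TYPE")),
               "Sterile I/zygotic not confirmed")
  expect_equal(categorize_family(c("STERILE_II", "CARRIER")),
               "Sterile II/zygotic")
})

test_that("classifier recovers true F2 classes on simulated data", {
  probs <- stats::setNames(rep(0, 4), allele_classes())
  probs["ZYGOTIC_LETHAL"] <- 1
  cfg <- screen_config(
    n_f1_families = 60, alleles_per_genome = 1, class_probabilities = probs,
    penetrance = 1, f2_cohort_size_range = c(8, 8), primary_male_rate = 0,
    rear_f3 = "none", seed = 77
  )
  sim <- simulate_screen(cfg)
  calls <- classify_screen(sim$pedigree, sim$clutches)
  j <- dplyr::inner_join(calls$calls, sim$truth, by = "fish_id")
  j <- j[j$n_scored >= 20, ]
  carriers <- j[j$zygotic_carrier, ]
  sens <- mean(carriers$call == "CARRIER")
  expect_gte(nrow(carriers), 200)
  expect_gte(sens, 0.97)
  # no wild-type fish called sterile at moderate background nonviability
  wt <- j[!j$zygotic_carrier, ]
  expect_false(any(wt$call %in% c("STERILE_I", "STERILE_II")))
})

test_that("Type I sterile sensitivity is 1 at full penetrance", {
  probs <- stats::setNames(rep(0, 4), allele_classes())
  probs["STERILE_TYPE_I"] <- 1
  cfg <- screen_config(
    n_f1_families = 40, alleles_per_genome = 1, class_probabilities = probs,
    penetrance = 1, f2_cohort_size_range = c(8, 8), primary_male_rate = 0,
    rear_f3 = "none", seed = 78
  )
  sim <- simulate_screen(cfg)
  calls <- classify_screen(sim$pedigree, sim$clutches)
  j <- dplyr::inner_join(calls$calls, sim$truth, by = "fish_id")
  sterile_truth <- j[j$true_class == "STERILE_I" & j$n_scored >= 20, ]
  expect_gte(nrow(sterile_truth), 30)
  expect_true(all(sterile_truth$call == "STERILE_I"))
})

test_that("each fish gets exactly one call and sterile types are exclusive", {
  cfg <- screen_config(n_f1_families = 10, seed = 13)
  sim <- simulate_screen(cfg)
  calls <- classify_screen(sim$pedigree, sim$clutches)
  expect_false(any(duplicated(calls$calls$fish_id)))
  # every screened adult (clutch-collected hermaphrodite or primary male)
  # gets a call; F1 founders are not screened
  adults <- sim$pedigree[sim$pedigree$status == "ADULT", ]
  screened <- adults[adults$sessions_observed > 0 | adults$role == "PRIMARY_MALE", ]
  expect_setequal(calls$calls$fish_id, screened$fish_id)
  # Type I requires >= 20 scored, Type II requires 0 scored: exclusive
  st <- calls$calls[calls$calls$call %in% c("STERILE_I", "STERILE_II"), ]
  expect_true(all(st$n_scored[st$call == "STERILE_I"] >= 20))
  expect_true(all(st$n_scored[st$call == "STERILE_II"] == 0))
})
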