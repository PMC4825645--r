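#' Define one induced mutant allele
#'
#' One ENU-induced recessive allele with a functional class, a free-text
#' phenotype label, a homozygous penetrance, and (for maternal-effect
#' alleles) a heterozygous maternal-dominance fraction.
#'
#' @param allele_id Unique allele identifier within a screen.
#' @param allele_class One of [allele_classes()].
#' @param phenotype_label Free-text phenotype (e.g. "curly tail",
#'   "golden yolk").
#' @param penetrance Fraction of homozygotes expressing the phenotype.
#' @param maternal_dominance Fraction of heterozygous mothers expressing
#'   a maternal effect (Type I alleles only; default 0).
#' @return A one-row tibble; rows from several calls can be bound into an
#'   allele table for [simulate_clutch()].
#' @export
mutant_allele <- function(allele_id, allele_class, phenotype_label = allele_id,
                          penetrance = 1, maternal_dominance = 0) {
  if (!allele_class %in% allele_classes()) {
    rlang::abort(paste0("unknown allele_class: ", allele_class))
  }
  if (penetrance < 0 || penetrance > 1 || maternal_dominance < 0 || maternal_dominance > 1) {
    rlang::abort("penetrance and maternal_dominance must lie in [0, 1]")
  }
  tibble::tibble(
    allele_id = as.character(allele_id),
    allele_class = allele_class,
    phenotype_label = as.character(phenotype_label),
    penetrance = penetrance,
    maternal_dominance = maternal_dominance
  )
}

# phenotype label pool drawn on when the simulator invents alleles
label_pool <- function(class) {
  switch(class,
    ZYGOTIC_LETHAL = c(
      "curly tail", "short tail", "no trunk", "dwarf", "eye defects",
      "skull defects", "jaw defects", "gastrula defects", "embryonic lethal"
    ),
    STERILE_TYPE_I = c("maternal effect"),
    STERILE_TYPE_II = c("nonegg layer", "embryo holder"),
    VISIBLE_VIABLE = c("golden yolk", "hyper-pigmented", "pigmentation defects")
  )
}

# Draw embryos for one mother across sessions. `sizes` is the per-session
# clutch size vector. Returns a tibble with one row per embryo including
# per-allele dosage columns (named by allele_id).
make_embryos <- function(mother, sizes, alleles, config,
                         parent_id, maternal_effect = FALSE) {
  n <- sum(sizes)
  session_index <- rep(seq_along(sizes), sizes)
  if (n == 0L) {
    return(tibble::tibble(
      embryo_id = character(), parent_id = character(),
      session_index = integer(), fertilized = logical(),
      viable = logical(), phenotype_labels = character()
    ))
  }
  geno <- sample_offspring(mother, n)
  fertilized <- rep(TRUE, n)
  viable <- rep(TRUE, n)
  labels <- vector("list", n)

  if (maternal_effect) {
    # maternal arrest: eggs are fertilized (halo present) but none develop
    viable[] <- FALSE
  } else {
    fertilized <- stats::runif(n) >= config$background_unfertilized
    viable[!fertilized] <- FALSE
    # embryo-autonomous expression of homozygous alleles
    for (i in seq_len(nrow(alleles))) {
      cls <- alleles$allele_class[i]
      if (!cls %in% c("ZYGOTIC_LETHAL", "VISIBLE_VIABLE")) next
      hom <- fertilized & geno[[alleles$allele_id[i]]] == 2
      expressed <- hom & stats::runif(n) < alleles$penetrance[i]
      if (cls == "ZYGOTIC_LETHAL") viable[expressed] <- FALSE
      for (j in which(expressed)) {
        labels[[j]] <- c(labels[[j]], alleles$phenotype_label[i])
      }
    }
    bg_dead <- fertilized & stats::runif(n) < config$background_nonviable
    viable[bg_dead] <- FALSE
  }

  out <- tibble::tibble(
    embryo_id = paste0(parent_id, "-s", session_index, "-e",
                       stats::ave(session_index, session_index, FUN = seq_along)),
    parent_id = parent_id,
    session_index = as.integer(session_index),
    fertilized = fertilized,
    viable = viable,
    phenotype_labels = if (all(lengths(labels) == 0)) {
      character(n)
    } else {
      purrr::map_chr(labels, ~ paste(unique(.x), collapse = ";"))
    }
  )
  dplyr::bind_cols(out, geno)
}

clutch_sizes <- function(n_sessions, config) {
  sizes <- stats::rpois(n_sessions, config$clutch_size_mean)
  pmin(sizes, config$clutch_size_max)
}

#' Simulate one clutch collection session
#'
#' Draws a clutch from an adult hermaphrodite: the clutch size is
#' truncated-Poisson (forced to zero for an expressed non-egg-layer),
#' embryo genotypes follow Mendelian selfing, and viability reflects the
#' allele classes, per-allele penetrance, the mother's expressed maternal
#' effect, and background attrition.
#'
#' @param mother Named dosage vector (the mother's genotype).
#' @param session_index Collection session number.
#' @param config A [screen_config()].
#' @param alleles Allele table ([mutant_allele()] rows) for the alleles
#'   segregating in the family.
#' @param parent_id Identifier recorded on the embryos.
#' @param maternal_effect Does the mother express a Type I maternal
#'   effect (all embryos fertilized but nonviable)?
#' @param no_egg_layer Does the mother express Type II sterility (clutch
#'   size forced to zero)?
#' @return Tibble of embryos (possibly zero rows) with dosage columns.
#' @export
simulate_clutch <- function(mother, session_index, config, alleles,
                            parent_id = "mother",
                            maternal_effect = FALSE, no_egg_layer = FALSE) {
  mother <- validate_genotype(mother)
  size <- if (no_egg_layer) 0L else clutch_sizes(1L, config)
  emb <- make_embryos(mother, size, alleles, config, parent_id,
                      maternal_effect = maternal_effect)
  emb$session_index <- rep(as.integer(session_index), nrow(emb))
  if (nrow(emb) > 0) {
    emb$embryo_id <- paste0(parent_id, "-s", session_index, "-e", seq_len(nrow(emb)))
  }
  emb
}

#' Rear a cohort of embryos to adulthood
#'
#' Selects viable embryos in order, applies juvenile rearing survival and
#' the primary-male rate, and returns fish records. Rearing stops once
#' `n_target` adults are obtained.
#'
#' @param embryos Embryo tibble (needs `embryo_id` and `viable`).
#' @param config A [screen_config()].
#' @param n_target Number of adults to aim for (default: rear every
#'   viable embryo).
#' @param id_prefix Prefix for generated fish ids.
#' @return Tibble with `fish_id`, `source_embryo_id`, `role`
#'   (HERMAPHRODITE/PRIMARY_MALE) and `status` (ADULT/JUVENILE_DEATH).
#'   Warns and returns zero rows when no embryo is viable (allele loss).
#' @export
rear_cohort <- function(embryos, config, n_target = Inf, id_prefix = "fish") {
  viable <- embryos[embryos$viable, , drop = FALSE]
  if (nrow(viable) == 0L) {
    rlang::warn(paste0(id_prefix, ": no viable embryos to rear (cohort lost)"))
    return(tibble::tibble(
      fish_id = character(), source_embryo_id = character(),
      role = character(), status = character()
    ))
  }
  survives <- stats::runif(nrow(viable)) < config$rearing_survival
  is_male <- stats::runif(nrow(viable)) < config$primary_male_rate
  # rear embryos in collection order; stop once the adult target is reached
  adults_cum <- cumsum(survives)
  last <- if (is.finite(n_target) && any(adults_cum >= n_target)) {
    which(adults_cum >= n_target)[1]
  } else {
    length(survives)
  }
  keep <- seq_len(last)
  sel <- viable[keep, , drop = FALSE]
  surv <- survives[keep]
  male <- is_male[keep]
  tibble::tibble(
    fish_id = paste0(id_prefix, "-", seq_len(nrow(sel))),
    source_embryo_id = sel$embryo_id,
    role = ifelse(surv & male, "PRIMARY_MALE", "HERMAPHRODITE"),
    status = ifelse(surv, "ADULT", "JUVENILE_DEATH")
  )
}

# fish-level expression of sterility classes given a dosage vector
express_sterility <- function(geno, alleles, config) {
  expressed <- ""
  for (i in seq_len(nrow(alleles))) {
    cls <- alleles$allele_class[i]
    d <- geno[[alleles$allele_id[i]]]
    if (cls == "STERILE_TYPE_II" && d == 2 &&
        stats::runif(1) < alleles$penetrance[i]) {
      expressed <- "II"
    }
  }
  if (expressed == "") {
    for (i in seq_len(nrow(alleles))) {
      cls <- alleles$allele_class[i]
      d <- geno[[alleles$allele_id[i]]]
      if (cls == "STERILE_TYPE_I") {
        if (d == 2 && stats::runif(1) < alleles$penetrance[i]) expressed <- "I"
        if (d == 1 && stats::runif(1) < alleles$maternal_dominance[i]) expressed <- "I"
      }
    }
  }
  expressed
}

genotype_string <- function(geno) {
  carried <- geno[geno > 0]
  if (length(carried) == 0) return("+/+")
  paste(paste0(names(carried), "=", carried), collapse = ";")
}

true_class_of <- function(geno, alleles, expressed) {
  if (expressed == "I") return("STERILE_I")
  if (expressed == "II") return("STERILE_II")
  screen_alleles <- alleles$allele_id[alleles$allele_class != "VISIBLE_VIABLE"]
  het_any <- any(unlist(geno[alleles$allele_id]) == 1)
  if (length(screen_alleles) > 0 && any(unlist(geno[screen_alleles]) %in% c(1, 2))) {
    if (any(unlist(geno[screen_alleles]) >= 1)) return("CARRIER")
  }
  if (het_any) return("CARRIER")
  "WILD_TYPE"
}

#' Simulate a full simultaneous zygotic/sterile screen
#'
#' Forward gene-drop over four generations: mutagenized P genomes give
#' heterozygous F1 founders carrying a Poisson number of induced recessive
#' alleles; F2 cohorts arise by selfing with embryonic loss of expressed
#' homozygous zygotic lethals; F2 adults lay F3 clutches over discrete
#' collection sessions (maternal-effect homozygotes lay 100%
#' fertilized-nonviable eggs, non-egg-layers lay none); in families where
#' a sterile F2 appears, F3 siblings are reared to adulthood and their F4
#' clutches collected, enabling backward genotyping.
#'
#' @param config A [screen_config()]. The simulation is fully
#'   reproducible from `config$seed`.
#' @return A list of class `screen_simulation` with elements
#'   \describe{
#'     \item{pedigree}{fish records: `fish_id`, `family_id`, `generation`,
#'       `parent_id`, `role`, `status`, `sessions_observed`,
#'       `true_genotype`.}
#'     \item{clutches}{one row per embryo: `embryo_id`, `parent_id`,
#'       `family_id`, `session_index`, `fertilized`, `viable`,
#'       `phenotype_labels`.}
#'     \item{truth}{per-adult true classification for parameter-recovery
#'       tests: `true_class`, `zygotic_carrier`, `sterile_carrier`,
#'       `hom_sterile`, `expressed_sterile`.}
#'     \item{alleles}{the induced alleles per family.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_screen(screen_config(n_f1_families = 3, seed = 7))
#' sim$pedigree
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "screen_config")) config <- validate_screen_config(config)
  set.seed(config$seed)

  fams <- purrr::map(seq_len(config$n_f1_families), sim_family, config = config)

  pedigree <- dplyr::bind_rows(purrr::map(fams, "pedigree"))
  clutches <- dplyr::bind_rows(purrr::map(fams, "clutches"))
  truth <- dplyr::bind_rows(purrr::map(fams, "truth"))
  alleles <- dplyr::bind_rows(purrr::map(fams, "alleles"))
  if (nrow(clutches) == 0L) {
    clutches <- tibble::tibble(
      embryo_id = character(), parent_id = character(), family_id = character(),
      session_index = integer(), fertilized = logical(), viable = logical(),
      phenotype_labels = character()
    )
  }
  structure(
    list(pedigree = pedigree, clutches = clutches, truth = truth,
         alleles = alleles, config = config),
    class = "screen_simulation"
  )
}

#' @export
print.screen_simulation <- function(x, ...) {
  cat("<screen_simulation>\n")
  cat("  families:", length(unique(x$pedigree$family_id)),
      "| fish:", nrow(x$pedigree),
      "| embryos:", nrow(x$clutches), "\n")
  tc <- table(x$truth$true_class)
  cat("  truth:", paste(names(tc), tc, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Simulate one F1 family end to end. Returns pedigree/clutch/truth rows.
sim_family <- function(fam_idx, config) {
  family_id <- sprintf("S%03d", fam_idx)
  k <- if (!is.null(config$alleles_per_genome)) {
    config$alleles_per_genome
  } else {
    stats::rpois(1L, config$alleles_per_genome_mean)
  }
  if (k > 0) {
    cls <- sample(names(config$class_probabilities), k, replace = TRUE,
                  prob = config$class_probabilities)
    alleles <- dplyr::bind_rows(purrr::map(seq_len(k), function(i) {
      mutant_allele(
        allele_id = paste0(family_id, "a", i),
        allele_class = cls[i],
        phenotype_label = paste0(sample(label_pool(cls[i]), 1L), " [", family_id, "a", i, "]"),
        penetrance = config$penetrance,
        maternal_dominance = config$maternal_dominance
      )
    }))
  } else {
    alleles <- mutant_allele("placeholder", "VISIBLE_VIABLE")[0, ]
  }
  alleles$family_id <- rep(family_id, nrow(alleles))

  f1_geno <- stats::setNames(rep(1, nrow(alleles)), alleles$allele_id)
  f1_id <- paste0(family_id, "-F1")

  ped <- list(fish_row(f1_id, family_id, "F1", NA_character_,
                       "HERMAPHRODITE", "ADULT", 0L, f1_geno))
  truth <- list()
  clutch_parts <- list()

  # --- F2 cohort by selfing the F1 founder -------------------------------
  size_choices <- seq(config$f2_cohort_size_range[1],
                      config$f2_cohort_size_range[2])
  target <- size_choices[sample.int(length(size_choices), 1L)]
  pool_n <- max(60L, target * 8L)
  pool <- sample_offspring(f1_geno, pool_n)
  alive <- rep(TRUE, pool_n)
  for (i in which(alleles$allele_class == "ZYGOTIC_LETHAL")) {
    hom <- pool[[alleles$allele_id[i]]] == 2
    alive <- alive & !(hom & stats::runif(pool_n) < alleles$penetrance[i])
  }
  surv_idx <- which(alive)
  f2 <- rear_embryo_rows(surv_idx, pool, config, target,
                         prefix = paste0(family_id, "-F2"))
  f2_adults <- list()
  for (row in f2) {
    geno <- row$geno
    fid <- row$fish_id
    expressed <- if (row$status == "ADULT" && row$role == "HERMAPHRODITE") {
      express_sterility(geno, alleles, config)
    } else ""
    sessions <- if (row$status == "ADULT" && row$role == "HERMAPHRODITE") {
      config$sessions_observed
    } else 0L
    ped[[length(ped) + 1L]] <- fish_row(fid, family_id, "F2", f1_id,
                                        row$role, row$status, sessions, geno)
    if (row$status == "ADULT") {
      truth[[length(truth) + 1L]] <- truth_row(fid, family_id, "F2", row$role,
                                               geno, alleles, expressed)
      if (row$role == "HERMAPHRODITE") {
        f2_adults[[length(f2_adults) + 1L]] <-
          list(fish_id = fid, geno = geno, expressed = expressed)
      }
    }
  }

  # --- F3 clutches from every F2 adult hermaphrodite ---------------------
  f2_clutches <- list()
  for (a in f2_adults) {
    sizes <- if (a$expressed == "II") {
      integer(config$sessions_observed)
    } else {
      clutch_sizes(config$sessions_observed, config)
    }
    emb <- make_embryos(a$geno, sizes, alleles, config,
                        parent_id = a$fish_id,
                        maternal_effect = a$expressed == "I")
    f2_clutches[[a$fish_id]] <- emb
  }

  # --- sterile confirmation: rear F3 in families with a sterile F2 -------
  family_sterile <- any(purrr::map_chr(f2_adults, "expressed") != "")
  rear_here <- switch(config$rear_f3,
    all = TRUE,
    none = FALSE,
    sterile_families = family_sterile
  )
  if (rear_here) {
    for (a in f2_adults) {
      if (a$expressed != "") next  # sterile fish leave no reared progeny
      emb <- f2_clutches[[a$fish_id]]
      reared <- withCallingHandlers(
        rear_cohort(emb, config, n_target = config$n_f3_reared_per_f2,
                    id_prefix = paste0(a$fish_id, "-F3")),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (nrow(reared) == 0L) next
      geno_cols <- alleles$allele_id
      for (j in seq_len(nrow(reared))) {
        src <- emb[emb$embryo_id == reared$source_embryo_id[j], , drop = FALSE]
        geno <- stats::setNames(as.numeric(src[1, geno_cols, drop = TRUE]), geno_cols)
        if (length(geno_cols) == 0L) geno <- stats::setNames(numeric(0), character(0))
        fid <- reared$fish_id[j]
        expressed <- if (reared$status[j] == "ADULT" && reared$role[j] == "HERMAPHRODITE") {
          express_sterility(geno, alleles, config)
        } else ""
        sessions <- if (reared$status[j] == "ADULT" && reared$role[j] == "HERMAPHRODITE") {
          config$sessions_observed
        } else 0L
        ped[[length(ped) + 1L]] <- fish_row(fid, family_id, "F3", a$fish_id,
                                            reared$role[j], reared$status[j],
                                            sessions, geno)
        if (reared$status[j] == "ADULT") {
          truth[[length(truth) + 1L]] <- truth_row(fid, family_id, "F3",
                                                   reared$role[j], geno,
                                                   alleles, expressed)
          if (reared$role[j] == "HERMAPHRODITE") {
            # F4 clutches for backward genotyping
            sizes <- if (expressed == "II") {
              integer(config$sessions_observed)
            } else {
              clutch_sizes(config$sessions_observed, config)
            }
            f4 <- make_embryos(geno, sizes, alleles, config,
                               parent_id = fid,
                               maternal_effect = expressed == "I")
            clutch_parts[[length(clutch_parts) + 1L]] <- f4
          }
        }
      }
    }
  }

  clutch_parts <- c(f2_clutches, clutch_parts)
  clutches <- dplyr::bind_rows(clutch_parts)
  if (nrow(clutches) > 0L) {
    clutches <- clutches[, c("embryo_id", "parent_id", "session_index",
                             "fertilized", "viable", "phenotype_labels")]
    clutches$family_id <- family_id
    clutches <- clutches[, c("embryo_id", "parent_id", "family_id",
                             "session_index", "fertilized", "viable",
                             "phenotype_labels")]
  }

  list(
    alleles = alleles,
    pedigree = dplyr::bind_rows(ped),
    clutches = clutches,
    truth = dplyr::bind_rows(truth)
  )
}

# walk the embryo pool in order, rearing until `target` adults
rear_embryo_rows <- function(surv_idx, pool, config, target, prefix) {
  out <- list()
  adults <- 0L
  counter <- 0L
  for (i in surv_idx) {
    if (adults >= target) break
    counter <- counter + 1L
    survives <- stats::runif(1) < config$rearing_survival
    role <- if (survives && stats::runif(1) < config$primary_male_rate) {
      "PRIMARY_MALE"
    } else {
      "HERMAPHRODITE"
    }
    geno <- stats::setNames(as.numeric(pool[i, , drop = TRUE]), names(pool))
    if (ncol(pool) == 0L) geno <- stats::setNames(numeric(0), character(0))
    out[[length(out) + 1L]] <- list(
      fish_id = paste0(prefix, "-", counter),
      geno = geno,
      role = if (survives) role else "HERMAPHRODITE",
      status = if (survives) "ADULT" else "JUVENILE_DEATH"
    )
    if (survives) adults <- adults + 1L
  }
  out
}

fish_row <- function(fish_id, family_id, generation, parent_id, role, status,
                     sessions, geno) {
  tibble::tibble(
    fish_id = fish_id, family_id = family_id, generation = generation,
    parent_id = parent_id, role = role, status = status,
    sessions_observed = as.integer(sessions),
    true_genotype = genotype_string(geno)
  )
}

truth_row <- function(fish_id, family_id, generation, role, geno, alleles, expressed) {
  zyg <- alleles$allele_id[alleles$allele_class == "ZYGOTIC_LETHAL"]
  ste <- alleles$allele_id[alleles$allele_class %in% c("STERILE_TYPE_I", "STERILE_TYPE_II")]
  tibble::tibble(
    fish_id = fish_id, family_id = family_id, generation = generation,
    role = role,
    zygotic_carrier = length(zyg) > 0 && any(unlist(geno[zyg]) == 1),
    sterile_carrier = length(ste) > 0 && any(unlist(geno[ste]) == 1),
    hom_sterile = length(ste) > 0 && any(unlist(geno[ste]) == 2),
    expressed_sterile = expressed,
    true_class = if (role == "PRIMARY_MALE") "PRIMARY_MALE" else
      true_class_of(geno, alleles, expressed)
  )
}
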