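#' Aggregate clutch records per parent
#'
#' Collapses per-embryo clutch rows into one summary row per parent:
#' embryos scored, viable/nonviable/unfertilized counts, per-label mutant
#' counts, and the session bookkeeping used by the Type II (non-egg-layer)
#' rule. Unfertilized eggs are counted within `n_nonviable` (the sterility
#' criterion pools nonviable and unfertilized progeny) and also reported
#' separately.
#'
#' @param clutches Embryo-level tibble (`parent_id`, `session_index`,
#'   `fertilized`, `viable`, `phenotype_labels`).
#' @param sessions_observed Either a single count applied to all parents
#'   or a tibble with columns `fish_id`/`parent_id` and
#'   `sessions_observed` (e.g. the simulator pedigree); used to tally
#'   zero-egg sessions. Parents present in `sessions_observed` but absent
#'   from `clutches` get all-empty summaries.
#' @return Tibble with one row per parent: `parent_id`, `n_scored`,
#'   `n_viable`, `n_nonviable`, `n_unfertilized`, `mutant_counts`
#'   (list-column of named counts per phenotype label),
#'   `sessions_spanned`, `sessions_with_zero_eggs`.
#' @export
summarize_clutches <- function(clutches, sessions_observed = NULL) {
  stopifnot(is.data.frame(clutches))
  needed <- c("parent_id", "session_index", "fertilized", "viable", "phenotype_labels")
  missing_cols <- setdiff(needed, names(clutches))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("clutch table is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (any(clutches$viable & !clutches$fertilized)) {
    rlang::abort("invalid clutch records: unfertilized embryos cannot be viable")
  }

  smry <- clutches |>
    dplyr::group_by(.data$parent_id) |>
    dplyr::summarise(
      n_scored = dplyr::n(),
      n_viable = sum(.data$viable),
      n_nonviable = sum(!.data$viable),
      n_unfertilized = sum(!.data$fertilized),
      mutant_counts = list(count_labels(.data$phenotype_labels)),
      sessions_spanned = dplyr::n_distinct(.data$session_index),
      .groups = "drop"
    )

  if (!is.null(sessions_observed)) {
    if (is.data.frame(sessions_observed)) {
      idcol <- if ("fish_id" %in% names(sessions_observed)) "fish_id" else "parent_id"
      obs <- tibble::tibble(
        parent_id = sessions_observed[[idcol]],
        sessions_observed = sessions_observed$sessions_observed
      )
      obs <- obs[obs$sessions_observed > 0, , drop = FALSE]
    } else {
      ids <- union(smry$parent_id, character(0))
      obs <- tibble::tibble(parent_id = ids,
                            sessions_observed = as.integer(sessions_observed))
    }
    smry <- obs |>
      dplyr::left_join(smry, by = "parent_id") |>
      dplyr::mutate(
        n_scored = dplyr::coalesce(.data$n_scored, 0L),
        n_viable = dplyr::coalesce(.data$n_viable, 0L),
        n_nonviable = dplyr::coalesce(.data$n_nonviable, 0L),
        n_unfertilized = dplyr::coalesce(.data$n_unfertilized, 0L),
        sessions_spanned = dplyr::coalesce(.data$sessions_spanned, 0L),
        mutant_counts = purrr::map(.data$mutant_counts,
                                   ~ if (is.null(.x)) integer(0) else .x),
        sessions_with_zero_eggs = .data$sessions_observed - .data$sessions_spanned
      ) |>
      dplyr::select(-"sessions_observed")
  } else {
    smry$sessions_with_zero_eggs <- 0L
  }
  smry
}

count_labels <- function(labels) {
  labels <- labels[!is.na(labels) & nzchar(labels)]
  if (length(labels) == 0) return(integer(0))
  tab <- table(unlist(strsplit(labels, ";", fixed = TRUE)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Call sterility from a clutch summary
#'
#' Applies the screen's sterility criteria to one adult hermaphrodite:
#' Type I (maternal-effect) when at least `min_embryos_scored` embryos
#' were scored and 90% or more were nonviable or unfertilized; Type II
#' (non-egg-layer) when no eggs at all appeared over at least the
#' two-month eggless window; `INDETERMINATE` when neither criterion's
#' evidentiary minimum is met; `FERTILE` otherwise (the fish proceeds to
#' carrier calling).
#'
#' @param summary One-row clutch summary (see [summarize_clutches()]).
#' @param rules A [classification_rules()].
#' @return One-row tibble: `fish_id`, `call`, counts, and an
#'   `evidence` string.
#' @export
call_sterility <- function(summary, rules = classification_rules()) {
  stopifnot(nrow(summary) == 1)
  if (summary$n_viable + summary$n_nonviable != summary$n_scored) {
    rlang::abort("inconsistent clutch summary: viable + nonviable must equal scored")
  }
  n <- summary$n_scored
  frac <- if (n > 0) summary$n_nonviable / n else NA_real_
  call <- if (n >= rules$min_embryos_scored &&
              frac >= rules$nonviable_fraction_threshold) {
    "STERILE_I"
  } else if (n == 0 &&
             summary$sessions_with_zero_eggs >= rules$eggless_window_sessions) {
    "STERILE_II"
  } else if (n < rules$min_embryos_scored) {
    "INDETERMINATE"
  } else {
    "FERTILE"
  }
  evidence <- if (n > 0) {
    sprintf("%d/%d nonviable or unfertilized (%.2f)", summary$n_nonviable, n, frac)
  } else {
    sprintf("0 eggs over %d zero-egg sessions", summary$sessions_with_zero_eggs)
  }
  tibble::tibble(
    fish_id = summary$parent_id, call = call,
    n_scored = n, n_viable = summary$n_viable,
    n_nonviable = summary$n_nonviable, evidence = evidence
  )
}

#' Call zygotic carrier status from a clutch summary
#'
#' For a fertile fish with enough scored embryos, calls `CARRIER` when at
#' least `carrier_min_mutant_embryos` embryos display a family mutant
#' phenotype (roughly a quarter of embryos are expected to when the
#' parent is heterozygous), `WILD_TYPE` otherwise, and `INDETERMINATE`
#' when fewer than `min_embryos_scored` embryos were scored.
#'
#' @param summary One-row clutch summary.
#' @param family_phenotype_labels Character vector of mutant phenotype
#'   labels segregating in the family.
#' @param rules A [classification_rules()].
#' @return One-row tibble: `fish_id`, `call`, `n_mutant`, `evidence`.
#' @export
call_zygotic_carrier <- function(summary, family_phenotype_labels,
                                 rules = classification_rules()) {
  stopifnot(nrow(summary) == 1)
  counts <- summary$mutant_counts[[1]]
  n_mutant <- sum(counts[names(counts) %in% family_phenotype_labels])
  call <- if (summary$n_scored < rules$min_embryos_scored) {
    "INDETERMINATE"
  } else if (n_mutant >= rules$carrier_min_mutant_embryos) {
    "CARRIER"
  } else {
    "WILD_TYPE"
  }
  tibble::tibble(
    fish_id = summary$parent_id, call = call, n_mutant = as.integer(n_mutant),
    evidence = sprintf("%d/%d embryos with a family mutant phenotype",
                       n_mutant, summary$n_scored)
  )
}

#' Backward-genotype a parent from its reared descendants
#'
#' Infers a parent's genotype at a sterile locus from the phenotypes of
#' its reared offspring: a carrier (s/+) produces ~25% (or more) sterile
#' offspring, so one or more sterile descendants makes the parent a
#' `CARRIER`; an all-fertile sibship of at least
#' `wildtype_min_fertile_offspring` supports `WILD_TYPE` (the residual
#' miss probability at 8 offspring is 0.75^8, about 10%); anything less
#' is the honest undetermined class `STAR_PLUS` (*/+).
#'
#' @param fish_id Parent identifier.
#' @param descendant_calls Character vector of calls for the reared
#'   descendants (values from [call_sterility()]).
#' @param rules A [classification_rules()].
#' @return One-row tibble: `fish_id`, `call`, counts of sterile/fertile
#'   descendants, `evidence`.
#' @export
backward_genotype <- function(fish_id, descendant_calls,
                              rules = classification_rules()) {
  n_sterile <- sum(descendant_calls %in% c("STERILE_I", "STERILE_II"))
  n_fertile <- sum(descendant_calls %in% c("FERTILE"))
  call <- if (n_sterile >= 1) {
    "CARRIER"
  } else if (n_fertile >= rules$wildtype_min_fertile_offspring) {
    "WILD_TYPE"
  } else {
    "STAR_PLUS"
  }
  tibble::tibble(
    fish_id = fish_id, call = call,
    n_sterile_offspring = as.integer(n_sterile),
    n_fertile_offspring = as.integer(n_fertile),
    evidence = sprintf("%d sterile / %d fertile reared offspring",
                       n_sterile, n_fertile)
  )
}

#' Categorize a family from its members' calls
#'
#' Produces a family-level category naming the union of confirmed
#' mutation types, e.g. `"Zygotic"`, `"Sterile I/zygotic"`,
#' `"Sterile I and II/zygotic"`, or `"Zygotic not confirmed"` when no
#' carrier and no sterile call exists among scored members.
#'
#' @param member_calls Character vector of calls for the family's scored
#'   members (values `CARRIER`, `WILD_TYPE`, `STERILE_I`, `STERILE_II`,
#'   `STAR_PLUS`, `INDETERMINATE`).
#' @return A single category string.
#' @export
categorize_family <- function(member_calls) {
  has_i <- any(member_calls == "STERILE_I")
  has_ii <- any(member_calls == "STERILE_II")
  zygotic <- any(member_calls == "CARRIER")
  sterile_part <- if (has_i && has_ii) {
    "Sterile I and II"
  } else if (has_i) {
    "Sterile I"
  } else if (has_ii) {
    "Sterile II"
  } else {
    ""
  }
  zygotic_part <- if (zygotic) "Zygotic" else "Zygotic not confirmed"
  if (nzchar(sterile_part)) {
    # sterile families carry the zygotic verdict as a lowercase suffix
    paste0(sterile_part, "/", tolower(substr(zygotic_part, 1, 1)),
           substr(zygotic_part, 2, nchar(zygotic_part)))
  } else {
    zygotic_part
  }
}

#' Classify every fish in a simulated or recorded screen
#'
#' Runs the full decision cascade over pedigree and clutch tables:
#' primary males are set aside, each adult hermaphrodite is scored for
#' sterility and (if fertile) zygotic carrier status from its own
#' clutches, and parents with reared descendants are backward-genotyped
#' from the descendants' sterility calls.
#'
#' @param pedigree Pedigree tibble (simulator dialect; see
#'   [simulate_screen()]).
#' @param clutches Embryo-level clutch tibble.
#' @param rules A [classification_rules()].
#' @return A list of class `screen_calls` with
#'   \describe{
#'     \item{calls}{per-fish tibble: `fish_id`, `family_id`, `generation`,
#'       `call` (the fish's own clutch-based call), `backward_call`
#'       (from reared descendants, `NA` when none), counts and evidence.}
#'     \item{families}{per-family tibble: `family_id`, `category`,
#'       `n_carriers`, `n_scored_members`, `mean_mutant_percent`.}
#'   }
#' @export
classify_screen <- function(pedigree, clutches, rules = classification_rules()) {
  validate_pedigree(pedigree)
  adults <- pedigree |>
    dplyr::filter(.data$status == "ADULT")
  herm <- adults |> dplyr::filter(.data$role == "HERMAPHRODITE")
  males <- adults |> dplyr::filter(.data$role == "PRIMARY_MALE")

  smry <- summarize_clutches(clutches, sessions_observed = herm)

  family_labels <- clutches |>
    dplyr::filter(nzchar(.data$phenotype_labels)) |>
    dplyr::mutate(label = strsplit(.data$phenotype_labels, ";", fixed = TRUE)) |>
    tidyr::unnest("label") |>
    dplyr::distinct(.data$family_id, .data$label)

  calls <- purrr::map(seq_len(nrow(smry)), function(i) {
    row <- smry[i, ]
    fish <- herm[herm$fish_id == row$parent_id, ]
    labels <- family_labels$label[family_labels$family_id == fish$family_id[1]]
    st <- call_sterility(row, rules)
    if (st$call == "FERTILE") {
      zc <- call_zygotic_carrier(row, labels, rules)
      st$call <- zc$call
      st$n_mutant <- zc$n_mutant
      st$evidence <- paste(st$evidence, zc$evidence, sep = "; ")
    } else {
      st$n_mutant <- sum(row$mutant_counts[[1]][
        names(row$mutant_counts[[1]]) %in% labels])
    }
    st
  }) |>
    dplyr::bind_rows()

  calls <- calls |>
    dplyr::left_join(
      dplyr::select(herm, "fish_id", "family_id", "generation"),
      by = "fish_id"
    )

  if (nrow(males) > 0) {
    calls <- dplyr::bind_rows(calls, tibble::tibble(
      fish_id = males$fish_id, call = "PRIMARY_MALE",
      n_scored = 0L, n_viable = 0L, n_nonviable = 0L, n_mutant = 0L,
      evidence = "primary male (excluded from genotype tallies)",
      family_id = males$family_id, generation = males$generation
    ))
  }

  # backward genotyping: sterility calls of reared descendants refine parents
  kids <- pedigree |>
    dplyr::filter(!is.na(.data$parent_id), .data$status == "ADULT",
                  .data$role == "HERMAPHRODITE") |>
    dplyr::select("fish_id", "parent_id")
  kid_calls <- kids |>
    dplyr::inner_join(
      dplyr::select(calls, "fish_id", kid_call = "call"), by = "fish_id"
    ) |>
    dplyr::mutate(kid_call = dplyr::if_else(
      .data$kid_call %in% c("CARRIER", "WILD_TYPE"), "FERTILE", .data$kid_call
    ))
  parents_with_kids <- intersect(unique(kid_calls$parent_id), calls$fish_id)
  backward <- purrr::map(parents_with_kids, function(p) {
    backward_genotype(p, kid_calls$kid_call[kid_calls$parent_id == p], rules)
  }) |>
    dplyr::bind_rows()
  if (nrow(backward) > 0) {
    calls <- calls |>
      dplyr::left_join(
        dplyr::select(backward, "fish_id", backward_call = "call",
                      backward_evidence = "evidence"),
        by = "fish_id"
      )
  } else {
    calls$backward_call <- NA_character_
    calls$backward_evidence <- NA_character_
  }

  families <- calls |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      category = categorize_family(.data$call[.data$call != "PRIMARY_MALE"]),
      n_carriers = sum(.data$call == "CARRIER"),
      n_scored_members = sum(.data$call != "PRIMARY_MALE"),
      mean_mutant_percent = dplyr::if_else(
        any(.data$call == "CARRIER"),
        mean(100 * .data$n_mutant[.data$call == "CARRIER"] /
               .data$n_scored[.data$call == "CARRIER"]),
        NA_real_
      ),
      .groups = "drop"
    )

  structure(list(calls = calls, families = families), class = "screen_calls")
}

#' @export
print.screen_calls <- function(x, ...) {
  cat("<screen_calls>\n")
  tc <- table(x$calls$call)
  cat("  calls:", paste(names(tc), tc, sep = "=", collapse = " "), "\n")
  cat("  families:", nrow(x$families), "\n")
  invisible(x)
}
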