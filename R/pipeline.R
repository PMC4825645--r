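#' Run the full screen pipeline
#'
#' Composes simulate, classify, summarize and goodness-of-fit into one
#' reproducible run: simulates the screen from a configuration, writes
#' pedigree/clutch/calls/family TSVs, a cohort summary, segregation
#' chi-square results, and a run manifest. Rerunning with the same
#' configuration and seed produces byte-identical outputs.
#'
#' @param config A [screen_config()] or a path to a config JSON.
#' @param out_dir Output directory (created if absent).
#' @param rules A [classification_rules()].
#' @param seed Optional seed overriding `config$seed`.
#' @param truth Also write the truth table and the `true_genotype`
#'   pedigree column.
#' @return The run manifest (invisibly also written as
#'   `manifest.json`): configuration hash, seed, file list, and summary
#'   counts.
#' @export
run_pipeline <- function(config, out_dir, rules = classification_rules(),
                         seed = NULL, truth = FALSE) {
  if (is.character(config)) config <- read_screen_config(config)
  if (!inherits(config, "screen_config")) config <- validate_screen_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(paste0("cannot create output directory: ", out_dir))
  }

  sim <- simulate_screen(config)
  calls <- classify_screen(sim$pedigree, sim$clutches, rules)

  paths <- list(
    pedigree = file.path(out_dir, "pedigree.tsv"),
    clutches = file.path(out_dir, "clutches.tsv"),
    calls = file.path(out_dir, "calls.tsv"),
    families = file.path(out_dir, "families.tsv"),
    cohort_summary = file.path(out_dir, "cohort_summary.tsv"),
    gof = file.path(out_dir, "gof.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_pedigree(sim$pedigree, paths$pedigree, truth = truth)
  write_clutches(sim$clutches, paths$clutches)
  write_calls(dplyr::select(calls$calls, -dplyr::any_of("mutant_counts")),
              paths$calls)
  readr::write_tsv(calls$families, paths$families, na = ".")
  if (truth) {
    paths$truth <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(sim$truth, paths$truth, na = ".")
  }

  embryos_per_parent <- sim$clutches |>
    dplyr::count(.data$parent_id, name = "n_embryos") |>
    dplyr::inner_join(dplyr::select(calls$calls, "fish_id", "call"),
                      by = c(parent_id = "fish_id"))
  readr::write_tsv(
    cohort_summary(embryos_per_parent, .data$n_embryos, .data$call),
    paths$cohort_summary, na = "."
  )

  # zygotic segregation: wild-type vs carrier among scored F2 fish
  f2 <- calls$calls[calls$calls$generation == "F2", ]
  n_wt <- sum(f2$call == "WILD_TYPE")
  n_car <- sum(f2$call == "CARRIER")
  gof <- if (n_wt + n_car > 0) {
    glance(segregation_test(c(n_wt, n_car), c(1, 2), "EXACT"))
  } else {
    tibble::tibble()
  }
  jsonlite::write_json(
    list(observed = c(n_wt, n_car), ratio = c(1, 2), result = gof),
    paths$gof, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("killiscreen")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = purrr::map_chr(paths[names(paths) != "manifest"], identity),
    counts = list(
      fish = nrow(sim$pedigree),
      embryos = nrow(sim$clutches),
      families = nrow(calls$families)
    )
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Bar chart of classification calls
#'
#' @param object A `screen_calls` object from [classify_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_calls <- function(object, ...) {
  d <- dplyr::count(object$calls, .data$call)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$call, -.data$n),
                                  y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fish") +
    ggplot2::theme_minimal()
}
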