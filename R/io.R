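#' @section File dialects:
#' All tables are UTF-8, tab-separated with a header row; missing values
#' are written as `.`. The pedigree dialect has a single `parent_id`
#' column (selfing pedigrees have one parent, which standard two-parent
#' pedigree formats cannot express). Documented column-by-column in the
#' README.
#' @name killiscreen-io
NULL

PEDIGREE_COLS <- c("fish_id", "family_id", "generation", "parent_id",
                   "role", "status", "sessions_observed", "true_genotype")
CLUTCH_COLS <- c("embryo_id", "parent_id", "family_id", "session_index",
                 "fertilized", "viable", "phenotype_labels")

validate_pedigree <- function(pedigree) {
  missing_cols <- setdiff(setdiff(PEDIGREE_COLS, "true_genotype"), names(pedigree))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("pedigree is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  dup <- duplicated(pedigree$fish_id)
  if (any(dup)) {
    rlang::abort(paste0("duplicate fish_id at row(s) ",
                        paste(which(dup), collapse = ", ")))
  }
  has_parent <- !is.na(pedigree$parent_id)
  dangling <- has_parent & !(pedigree$parent_id %in% pedigree$fish_id)
  if (any(dangling)) {
    rlang::abort(paste0("dangling parent_id at row(s) ",
                        paste(which(dangling), collapse = ", ")))
  }
  gen_order <- c(P = 0, F1 = 1, F2 = 2, F3 = 3, F4 = 4)
  if (!all(pedigree$generation %in% names(gen_order))) {
    rlang::abort("generation labels must be P, F1, F2, F3 or F4")
  }
  parent_gen <- gen_order[pedigree$generation[
    match(pedigree$parent_id, pedigree$fish_id)]]
  bad_gen <- has_parent & (gen_order[pedigree$generation] != parent_gen + 1)
  if (any(bad_gen, na.rm = TRUE)) {
    rlang::abort(paste0("parent must be of the previous generation; row(s) ",
                        paste(which(bad_gen), collapse = ", ")))
  }
  invisible(pedigree)
}

validate_clutches <- function(clutches) {
  missing_cols <- setdiff(CLUTCH_COLS, names(clutches))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("clutch table is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  dup <- duplicated(clutches$embryo_id)
  if (any(dup)) {
    rlang::abort(paste0("duplicate embryo_id at row(s) ",
                        paste(which(dup), collapse = ", ")))
  }
  bad <- clutches$viable & !clutches$fertilized
  if (any(bad)) {
    rlang::abort(paste0("unfertilized embryos cannot be viable; row(s) ",
                        paste(which(bad), collapse = ", ")))
  }
  invisible(clutches)
}

#' Read and write screen tables
#'
#' Readers and writers for the pedigree, clutch and calls TSV dialects.
#' Reading validates the table (required columns, unique ids, no dangling
#' `parent_id`, generation ordering, embryo viability implying
#' fertilization) and aborts naming offending rows; `write` then `read`
#' is the identity on valid tables.
#'
#' @param path File path.
#' @param pedigree,clutches,calls The table to write.
#' @param truth Keep the `true_genotype` column when writing a pedigree
#'   (off by default).
#' @return Readers return a validated tibble; writers return the input
#'   invisibly.
#' @name screen-io
NULL

#' @rdname screen-io
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                         col_types = readr::cols(
                           sessions_observed = readr::col_integer(),
                           .default = readr::col_character()
                         ))
  validate_pedigree(ped)
  ped
}

#' @rdname screen-io
#' @export
write_pedigree <- function(pedigree, path, truth = FALSE) {
  out <- pedigree
  if (!truth) out$true_genotype <- NULL
  readr::write_tsv(out, path, na = ".")
  invisible(pedigree)
}

#' @rdname screen-io
#' @export
read_clutches <- function(path) {
  cl <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                        col_types = readr::cols(
                          session_index = readr::col_integer(),
                          fertilized = readr::col_integer(),
                          viable = readr::col_integer(),
                          .default = readr::col_character()
                        ))
  cl$fertilized <- cl$fertilized == 1L
  cl$viable <- cl$viable == 1L
  cl$phenotype_labels <- dplyr::coalesce(cl$phenotype_labels, "")
  validate_clutches(cl)
  cl
}

#' @rdname screen-io
#' @export
write_clutches <- function(clutches, path) {
  out <- clutches[, CLUTCH_COLS]
  out$fertilized <- as.integer(out$fertilized)
  out$viable <- as.integer(out$viable)
  out$phenotype_labels[!nzchar(out$phenotype_labels)] <- NA_character_
  readr::write_tsv(out, path, na = ".")
  invisible(clutches)
}

#' @rdname screen-io
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, na = ".", show_col_types = FALSE)
}

#' @rdname screen-io
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(calls, path, na = ".")
  invisible(calls)
}

#' Read and write configuration JSON
#'
#' A [screen_config()] (and optionally [classification_rules()])
#' serialized as a single JSON object. Unknown keys are rejected so that
#' misspelled parameters fail loudly rather than silently falling back to
#' defaults.
#'
#' @param path JSON file path.
#' @param config,rules Object to write.
#' @name config-io
NULL

#' @rdname config-io
#' @export
read_screen_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(screen_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown screen_config keys: ",
                        paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$class_probabilities)) {
    raw$class_probabilities <- unlist(raw$class_probabilities)
  }
  if (!is.null(raw$f2_cohort_size_range)) {
    raw$f2_cohort_size_range <- unlist(raw$f2_cohort_size_range)
  }
  do.call(screen_config, raw)
}

#' @rdname config-io
#' @export
write_screen_config <- function(config, path) {
  out <- unclass(config)
  out$class_probabilities <- as.list(out$class_probabilities)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(config)
}

#' @rdname config-io
#' @export
read_classification_rules <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(classification_rules))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown classification_rules keys: ",
                        paste(unknown, collapse = ", ")))
  }
  do.call(classification_rules, raw)
}

#' @rdname config-io
#' @export
write_classification_rules <- function(rules, path) {
  jsonlite::write_json(unclass(rules), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rules)
}
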