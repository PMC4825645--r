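#' Exact offspring genotype distribution under self-fertilization
#'
#' A hermaphrodite that self-crosses transmits each allele independently:
#' every heterozygous locus segregates 1:2:1 (homozygous mutant :
#' heterozygous : homozygous wild-type), homozygous loci transmit
#' deterministically, and unlinked loci combine multiplicatively. This is
#' the distribution underlying the expectation that a carrier (m/+)
#' produces 25% homozygous mutant embryos on selfing.
#'
#' @param parent Named numeric vector of allele dosages (one entry per
#'   mutant allele, values 0, 1 or 2). An empty or all-zero vector is the
#'   wild-type genotype. Loci are assumed unlinked.
#' @return A tibble with one column per allele (offspring dosage) plus a
#'   `prob` column; probabilities sum to 1.
#' @examples
#' self_cross_distribution(c(m = 1))          # 1/4 : 1/2 : 1/4
#' self_cross_distribution(c(m = 1, s = 1))   # 9 two-locus classes
#' @export
self_cross_distribution <- function(parent) {
  parent <- validate_genotype(parent)
  if (length(parent) == 0L) {
    return(tibble::tibble(prob = 1))
  }
  marginals <- purrr::map(as.list(parent), dosage_marginal)
  out <- tidyr::expand_grid(!!!purrr::map(marginals, "dosage"))
  probs <- purrr::map(marginals, "prob")
  weight <- rep(1, nrow(out))
  for (i in seq_along(probs)) {
    weight <- weight * probs[[i]][match(out[[i]], marginals[[i]]$dosage)]
  }
  out$prob <- weight
  out
}

# 1:2:1 marginal for a het locus; point mass otherwise
dosage_marginal <- function(d) {
  if (d == 1) {
    list(dosage = c(0, 1, 2), prob = c(0.25, 0.5, 0.25))
  } else {
    list(dosage = d %/% 2 * 2, prob = 1)
  }
}

validate_genotype <- function(parent) {
  if (is.null(parent)) return(numeric(0))
  if (!is.numeric(parent)) {
    rlang::abort("genotype must be a named numeric vector of dosages")
  }
  if (length(parent) > 0 && (is.null(names(parent)) || any(!nzchar(names(parent))))) {
    rlang::abort("every allele dosage must be named by its allele_id")
  }
  if (anyDuplicated(names(parent))) {
    rlang::abort("allele_id names must be unique within a genotype")
  }
  if (!all(parent %in% c(0, 1, 2))) {
    rlang::abort("allele dosages must be 0, 1 or 2")
  }
  parent
}

#' Condition a genotype distribution on survival
#'
#' Removes genotype classes killed by a lethality rule and renormalizes,
#' giving the distribution seen among survivors. Selfing a carrier of an
#' embryonic-lethal allele and conditioning on survival yields the
#' two carriers : one wild-type ratio among surviving fish.
#'
#' @param dist A genotype distribution tibble as returned by
#'   [self_cross_distribution()] (dosage columns plus `prob`).
#' @param lethal Either a character vector of allele ids (a genotype is
#'   lethal when homozygous, dosage 2, for any of them) or a predicate
#'   function taking a named dosage vector and returning `TRUE` for
#'   lethal genotypes.
#' @return The renormalized survivor distribution (same columns).
#' @examples
#' d <- self_cross_distribution(c(m = 1))
#' survivor_distribution(d, "m")   # m/+ 2/3, +/+ 1/3
#' @export
survivor_distribution <- function(dist, lethal) {
  stopifnot(is.data.frame(dist), "prob" %in% names(dist))
  allele_cols <- setdiff(names(dist), "prob")
  if (is.character(lethal)) {
    ids <- lethal
    missing_ids <- setdiff(ids, allele_cols)
    if (length(missing_ids) > 0 && length(ids) > 0) {
      # alleles absent from the distribution have dosage 0 everywhere: never lethal
      ids <- intersect(ids, allele_cols)
    }
    if (length(ids) == 0) {
      dies <- rep(FALSE, nrow(dist))
    } else {
      dies <- purrr::reduce(purrr::map(ids, ~ dist[[.x]] == 2), `|`)
    }
  } else if (is.function(lethal)) {
    dies <- purrr::map_lgl(seq_len(nrow(dist)), function(i) {
      g <- as.numeric(dist[i, allele_cols, drop = TRUE])
      names(g) <- allele_cols
      isTRUE(lethal(g))
    })
  } else {
    rlang::abort("`lethal` must be a character vector of allele ids or a predicate function")
  }
  surv <- dist[!dies, , drop = FALSE]
  total <- sum(surv$prob)
  if (total <= 0) {
    rlang::abort("all genotype classes are lethal: no survivors to condition on")
  }
  surv$prob <- surv$prob / total
  surv
}

#' Sample offspring genotypes from a selfing parent
#'
#' Stochastic counterpart of [self_cross_distribution()]: each offspring
#' receives, per locus, two independent gametes each carrying the mutant
#' allele with probability dosage/2.
#'
#' @param parent Named numeric dosage vector (see
#'   [self_cross_distribution()]).
#' @param n Number of offspring to draw.
#' @return A tibble with `n` rows and one dosage column per allele.
#'   Draws consume the session R random number stream, so results are
#'   reproducible under `set.seed()`.
#' @examples
#' set.seed(1)
#' sample_offspring(c(m = 1), n = 5)
#' @export
sample_offspring <- function(parent, n = 1) {
  parent <- validate_genotype(parent)
  n <- as.integer(n)
  stopifnot(n >= 0)
  if (length(parent) == 0L) {
    return(tibble::tibble(.rows = n))
  }
  cols <- purrr::map(as.list(parent), ~ stats::rbinom(n, 2L, .x / 2))
  tibble::as_tibble(cols)
}
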