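#' Expected counts under a segregation ratio
#'
#' Splits a total count according to ratio weights. `"EXACT"` returns the
#' real-valued expectations `total * w / sum(w)`. `"PAPER_INTEGER"`
#' reproduces the integer-rounded dialect used in printed segregation
#' tables (e.g. 281 split 1:2 as 94 and 187): each cell is rounded to the
#' nearest integer and, if the rounded cells no longer sum to the total,
#' the largest cell absorbs the difference.
#'
#' @param total Total observed count (> 0).
#' @param ratio Positive ratio weights, e.g. `c(1, 2)` or `c(3, 1)`.
#' @param rounding `"EXACT"` or `"PAPER_INTEGER"`.
#' @return Numeric vector of expected counts, summing to `total`.
#' @examples
#' expected_counts(281, c(1, 2), "PAPER_INTEGER")  # 94 187
#' expected_counts(46, c(1, 2), "PAPER_INTEGER")   # 15 31
#' @export
expected_counts <- function(total, ratio, rounding = c("EXACT", "PAPER_INTEGER")) {
  rounding <- match.arg(rounding)
  if (total <= 0) rlang::abort("total must be positive")
  if (any(ratio <= 0)) rlang::abort("ratio weights must be positive")
  exact <- total * ratio / sum(ratio)
  if (rounding == "EXACT") {
    return(exact)
  }
  rounded <- round(exact)
  deficit <- total - sum(rounded)
  if (deficit != 0) {
    i <- which.max(rounded)
    rounded[i] <- rounded[i] + deficit
  }
  rounded
}

#' Pearson chi-square goodness-of-fit test
#'
#' Plain Pearson chi-square of observed against expected counts with
#' per-cell contributions `(obs - exp)^2 / exp`, `df = cells - 1`, and
#' the conventional critical value at `alpha`. No continuity correction
#' is applied. The result records `consistent_with_ratio`, true when the
#' statistic falls below the critical value (i.e. the counts do not
#' deviate significantly from the expected ratio).
#'
#' @param observed Observed counts.
#' @param expected Expected counts (all positive; may carry the
#'   integer-rounded dialect of [expected_counts()]).
#' @param alpha Significance level for the critical value.
#' @return An object of class `gof_result`; see [tidy.gof_result()] and
#'   [glance.gof_result()].
#' @examples
#' chi_square_gof(c(92, 189), c(94, 187))  # chi2 = 0.064
#' @export
chi_square_gof <- function(observed, expected, alpha = 0.05) {
  if (length(observed) != length(expected)) {
    rlang::abort("observed and expected must have equal length")
  }
  if (any(expected <= 0)) rlang::abort("expected counts must be positive")
  if (any(observed < 0)) rlang::abort("observed counts must be nonnegative")
  contributions <- (observed - expected)^2 / expected
  chi_square <- sum(contributions)
  df <- length(observed) - 1L
  critical <- stats::qchisq(1 - alpha, df)
  structure(
    list(
      observed = observed,
      expected = expected,
      contributions = contributions,
      chi_square = chi_square,
      df = df,
      alpha = alpha,
      critical_value = critical,
      p_value = stats::pchisq(chi_square, df, lower.tail = FALSE),
      consistent_with_ratio = chi_square < critical
    ),
    class = "gof_result"
  )
}

#' Segregation goodness-of-fit test
#'
#' Convenience wrapper: builds expected counts from a ratio (optionally
#' in the integer-rounded dialect) and runs [chi_square_gof()].
#'
#' @param observed Observed counts.
#' @param ratio Ratio weights (e.g. `c(1, 2)` for 1 wild-type : 2
#'   carriers among survivors, `c(3, 1)` for 3 undetermined : 1 sterile).
#' @param rounding `"EXACT"` or `"PAPER_INTEGER"`.
#' @param alpha Significance level.
#' @return A `gof_result`.
#' @examples
#' segregation_test(c(14, 32), c(1, 2), "PAPER_INTEGER")  # chi2 = 0.099
#' segregation_test(c(84, 27), c(3, 1), "PAPER_INTEGER")  # chi2 = 0.048
#' @export
segregation_test <- function(observed, ratio,
                             rounding = c("EXACT", "PAPER_INTEGER"),
                             alpha = 0.05) {
  rounding <- match.arg(rounding)
  expected <- expected_counts(sum(observed), ratio, rounding)
  chi_square_gof(observed, expected, alpha)
}

#' @export
print.gof_result <- function(x, digits = 3, ...) {
  cat("Chi-square goodness of fit\n")
  tab <- rbind(Observed = x$observed, Expected = x$expected,
               Contribution = round(x$contributions, digits))
  print(tab)
  cat(sprintf("chi-square = %s, df = %d, critical value = %.2f (alpha = %g)\n",
              format(round(x$chi_square, digits)), x$df, x$critical_value, x$alpha))
  cat(if (x$consistent_with_ratio) {
    "counts are consistent with the expected ratio\n"
  } else {
    "counts deviate significantly from the expected ratio\n"
  })
  invisible(x)
}

#' Tidy a goodness-of-fit result
#'
#' @param x A `gof_result`.
#' @param ... Unused.
#' @return One row per cell: `observed`, `expected`, `contribution`.
#' @export
tidy.gof_result <- function(x, ...) {
  tibble::tibble(
    cell = seq_along(x$observed),
    observed = x$observed,
    expected = x$expected,
    contribution = x$contributions
  )
}

#' One-row summary of a goodness-of-fit result
#'
#' @param x A `gof_result`.
#' @param ... Unused.
#' @return A one-row tibble: `chi_square`, `df`, `p_value`,
#'   `critical_value`, `consistent_with_ratio`.
#' @export
glance.gof_result <- function(x, ...) {
  tibble::tibble(
    chi_square = x$chi_square,
    df = x$df,
    p_value = x$p_value,
    critical_value = x$critical_value,
    consistent_with_ratio = x$consistent_with_ratio
  )
}

#' Observed-versus-expected bar chart for a goodness-of-fit result
#'
#' @param object A `gof_result`.
#' @param ... Unused.
#' @param labels Optional cell labels.
#' @return A ggplot object.
#' @export
autoplot.gof_result <- function(object, ..., labels = NULL) {
  d <- tidy(object)
  d$cell <- factor(if (is.null(labels)) d$cell else labels,
                   levels = unique(if (is.null(labels)) d$cell else labels))
  d_long <- tidyr::pivot_longer(d, c("observed", "expected"),
                                names_to = "kind", values_to = "count")
  ggplot2::ggplot(d_long, ggplot2::aes(x = .data$cell, y = .data$count,
                                       fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "count", fill = NULL,
                  subtitle = sprintf("chi-square = %.3f (df = %d)",
                                     object$chi_square, object$df)) +
    ggplot2::theme_minimal()
}

#' Percent sterile among confirmation-screen descendants
#'
#' Percent of sterile offspring among reared siblings descended from
#' carrier (s/+) parents: `100 * s / (s + star_plus)` where `star_plus`
#' counts reared fish of undetermined (wild-type-or-carrier) genotype.
#' Returns `NA` when the denominator is zero (e.g. families where the
#' sterile allele was lost).
#'
#' @param n_sterile Sterile offspring count.
#' @param n_star_plus Undetermined (`*/+`) offspring count.
#' @return Percent (0-100) or `NA`. Vectorized.
#' @examples
#' family_sterile_percent(5, 15)    # 25.0
#' family_sterile_percent(13, 34)   # 27.66
#' @export
family_sterile_percent <- function(n_sterile, n_star_plus) {
  if (any(n_sterile < 0, na.rm = TRUE) || any(n_star_plus < 0, na.rm = TRUE)) {
    rlang::abort("counts must be nonnegative")
  }
  denom <- n_sterile + n_star_plus
  ifelse(denom == 0, NA_real_, 100 * n_sterile / denom)
}

#' Sum/mean/range summary table per class
#'
#' The cohort summary layout of screen reports: per-group totals, means
#' and min-max ranges of a count variable.
#'
#' @param data A data frame of classified records.
#' @param value Column (tidy-eval) holding the per-record count.
#' @param group Column (tidy-eval) holding the class label.
#' @param mean_digits Optional rounding of the mean, matching printed
#'   precision (`NULL` for full precision).
#' @return Tibble: `class`, `n`, `sum`, `mean`, `min`, `max`.
#' @examples
#' d <- tibble::tibble(g = c("a", "a", "b"), x = c(1, 5, 2))
#' cohort_summary(d, x, g)
#' @export
cohort_summary <- function(data, value, group, mean_digits = NULL) {
  if (nrow(data) == 0) {
    return(tibble::tibble(class = character(), n = integer(), sum = numeric(),
                          mean = numeric(), min = numeric(), max = numeric()))
  }
  out <- data |>
    dplyr::group_by(class = {{ group }}) |>
    dplyr::summarise(
      # the record count is computed last so it cannot mask a value column
      # that happens to be called n
      sum = sum({{ value }}),
      mean = mean({{ value }}),
      min = min({{ value }}),
      max = max({{ value }}),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("class", "n", "sum", "mean", "min", "max")
  if (!is.null(mean_digits)) out$mean <- round(out$mean, mean_digits)
  out
}
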