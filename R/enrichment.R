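#' Contingency chi-squared test with adjusted residuals
#'
#' Pearson chi-squared test of independence on an r x c count table (no
#' continuity correction) together with the adjusted (standardized) cell
#' residuals `(O - E) / sqrt(E (1 - n_i/N) (1 - n_j/N))`. Cells with
#' `|residual| > threshold` (default 2) are flagged as driving the
#' departure from independence; residuals above 2 mark a significant
#' difference between observed and expected frequencies. A warning is
#' issued when any expected count falls below 5.
#'
#' @param observed Integer matrix of counts (>= 2 rows and columns), with
#'   dimnames if available.
#' @param threshold Flagging threshold on `|adjusted residual|`
#'   (default 2, two-sided).
#' @return An object of class `chi2_adjusted`: `observed`, `expected`,
#'   `chi2`, `df`, `p`, `adjusted_residuals`, `significant_cells`.
#' @examples
#' chi2_adjusted(matrix(c(10, 20, 20, 10), 2))
#' @export
chi2_adjusted <- function(observed, threshold = 2) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || anyNA(observed)) stop("counts must be non-negative")
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    stop("need at least a 2 x 2 table")
  if (sum(observed) <= 0) stop("empty table")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop("zero row/column margin")
  ct <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected count below 5 in ", sum(ct$expected < 5), " cell(s)")
  res <- ct$stdres # classical adjusted residuals
  structure(list(observed = observed, expected = ct$expected,
                 chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, adjusted_residuals = res,
                 significant_cells = abs(res) > threshold,
                 threshold = threshold, mode = "independence"),
            class = "chi2_adjusted")
}

#' Goodness-of-fit chi-squared with standardized residuals
#'
#' One-way version of [chi2_adjusted()]: observed category counts against
#' expected proportions (e.g. urban species per order against the global
#' richness share of each order), with df = k - 1 and standardized
#' residuals `(O - E) / sqrt(E (1 - p_i))`.
#'
#' @param observed Integer vector of counts.
#' @param expected_prop Expected proportions (same length, summing to 1).
#' @param threshold Flagging threshold (default 2).
#' @return A `chi2_adjusted` object with `mode = "goodness_of_fit"`.
#' @export
chi2_gof <- function(observed, expected_prop, threshold = 2) {
  if (length(observed) != length(expected_prop))
    stop("observed and expected_prop lengths differ")
  if (any(observed < 0)) stop("counts must be non-negative")
  if (abs(sum(expected_prop) - 1) > 1e-8) stop("expected proportions must sum to 1")
  if (any(expected_prop <= 0)) stop("expected proportions must be positive")
  N <- sum(observed)
  E <- N * expected_prop
  if (any(E < 5)) warning("expected count below 5 in ", sum(E < 5), " cell(s)")
  chi2 <- sum((observed - E)^2 / E)
  df <- length(observed) - 1L
  res <- (observed - E) / sqrt(E * (1 - expected_prop))
  structure(list(observed = observed, expected = E, chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 adjusted_residuals = res,
                 significant_cells = abs(res) > threshold,
                 threshold = threshold, mode = "goodness_of_fit"),
            class = "chi2_adjusted")
}

#' @export
print.chi2_adjusted <- function(x, ...) {
  cat("Chi-squared test (", x$mode, "): chi2 = ", format(x$chi2, digits = 6),
      ", df = ", x$df, ", p = ", format.pval(x$p, digits = 4), "\n", sep = "")
  cat("adjusted residuals (|r| > ", x$threshold, " flagged *):\n", sep = "")
  r <- round(x$adjusted_residuals, 2)
  flag <- ifelse(x$significant_cells, "*", " ")
  if (is.matrix(r)) {
    out <- matrix(paste0(format(r), flag), nrow(r), dimnames = dimnames(r))
    print(out, quote = FALSE)
  } else {
    print(stats::setNames(paste0(format(r), flag), names(x$observed)), quote = FALSE)
  }
  invisible(x)
}
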