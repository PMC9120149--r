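#' Pearson chi-squared contingency test
#'
#' Classical Pearson chi-squared without Yates continuity correction, with
#' `df = (r - 1)(c - 1)`. All tests in this package are two-sided.
#'
#' @param t matrix of nonnegative integer counts, at least 2x2.
#' @return a list of class `test_result`: `statistic`, `df`, `p`,
#'   `expected`, `method`.
#' @export
chi2_contingency <- function(t) {
  t <- as.matrix(t)
  if (nrow(t) < 2 || ncol(t) < 2) stop("need at least a 2x2 table")
  if (any(t < 0)) stop("negative counts")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    stop("contingency table has an all-zero margin")
  }
  res <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter), p = res$p.value,
                 expected = res$expected,
                 method = "chi-squared contingency (no continuity correction)"),
            class = "test_result")
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table.
#'
#' @param t 2x2 matrix of nonnegative integer counts.
#' @return a `test_result` with `statistic` = conditional ML odds ratio.
#' @export
fisher_exact <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2, 2))) stop("fisher_exact needs a 2x2 table")
  res <- stats::fisher.test(t, alternative = "two.sided")
  structure(list(statistic = unname(res$estimate), df = NA_integer_,
                 p = min(1, res$p.value),  # guard against 1 + eps roundoff
                 method = "Fisher exact (two-sided)"),
            class = "test_result")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|`; the p-value is exact when
#' `length(x) * length(y) <= 10^4` and there are no ties, asymptotic
#' otherwise.
#'
#' @param x,y numeric samples, both nonempty.
#' @return a `test_result` with `statistic` = D.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  exact <- length(x) * length(y) <= 1e4 &&
    !any(duplicated(c(x, y)))
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  structure(list(statistic = unname(res$statistic), df = NA_integer_,
                 p = min(1, res$p.value),
                 method = "two-sample Kolmogorov-Smirnov (two-sided)"),
            class = "test_result")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone, capped at 1, returned in input
#' order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials (>= 1).
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lo, hi)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Intron phase distributions and their pairwise comparisons
#'
#' Counts introns per phase (0/1/2), optionally per category (e.g. shared
#' LECA / unique LECA / post-LECA), and compares every pair of categories
#' with a chi-squared test on the 2x3 table, adjusting the p-values with
#' Benjamini-Hochberg across the comparison set. Empty categories are
#' dropped with a warning.
#'
#' @param phases integer vector of phases in `{0, 1, 2}`.
#' @param category optional factor/character of the same length.
#' @return a list of class `phase_distribution`: `counts` (matrix
#'   categories x phases, or a single-row matrix), `comparisons`
#'   (data.frame with `statistic`, `df`, `p`, `p_adj`) or `NULL`.
#' @export
phase_distribution <- function(phases, category = NULL) {
  stopifnot(all(phases %in% 0:2))
  phases <- factor(phases, levels = 0:2)
  if (is.null(category)) {
    counts <- matrix(table(phases), nrow = 1,
                     dimnames = list("all", levels(phases)))
    return(structure(list(counts = counts, comparisons = NULL),
                     class = "phase_distribution"))
  }
  category <- if (is.factor(category)) category else factor(category)
  counts <- table(category, phases)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("dropping empty categor(ies): ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  counts <- unclass(counts)
  comparisons <- NULL
  if (nrow(counts) >= 2) {
    pairs <- utils::combn(seq_len(nrow(counts)), 2)
    rows <- apply(pairs, 2, function(ij) {
      res <- chi2_contingency(counts[ij, , drop = FALSE])
      c(statistic = res$statistic, df = res$df, p = res$p)
    })
    comparisons <- data.frame(cat1 = rownames(counts)[pairs[1, ]],
                              cat2 = rownames(counts)[pairs[2, ]],
                              statistic = rows["statistic", ],
                              df = rows["df", ], p = rows["p", ])
    comparisons$p_adj <- bh_fdr(comparisons$p)
  }
  structure(list(counts = counts, comparisons = comparisons),
            class = "phase_distribution")
}
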