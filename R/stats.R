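#' Create a test-result record
#'
#' Common return shape for the statistical primitives: a list with the
#' statistic, a p-value in \[0, 1\], the alternative and a method label.
#' Extra fields (odds ratio, correlation, fold change) ride along.
#'
#' @param statistic Test statistic.
#' @param p_value P-value in \[0, 1\] (or `NA` for undefined results).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param method Non-empty method label.
#' @param ... Extra named fields.
#' @return A list with class `"embryodyn_test"`.
#' @export
test_result <- function(statistic, p_value, alternative, method, ...) {
  stopifnot(nzchar(method),
            is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(list(statistic = unname(statistic),
                 p_value = unname(min(p_value, 1)),
                 alternative = alternative, method = method, ...),
            class = "embryodyn_test")
}

#' @export
print.embryodyn_test <- function(x, ...) {
  cat(x$method, " (", x$alternative, "): statistic = ",
      signif(x$statistic, 5), ", p = ", signif(x$p_value, 5), "\n",
      sep = "")
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test on the table `rbind(c(a, b), c(c, d))`. The
#' two-sided p-value sums the probabilities of all tables (at fixed
#' margins) no more likely than the observed one; `greater`/`less` are
#' one-sided on cell `a`. The conditional odds-ratio MLE is returned
#' (`Inf` allowed for empty off-diagonals).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return An `"embryodyn_test"` with `odds_ratio`.
#' @export
fisher_exact <- function(a, b, c, d, alternative = "two.sided") {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("fisher_exact: negative or missing cell count")
  if (sum(cells) == 0) stop("fisher_exact: all margins empty")
  ft <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE),
                           alternative = alternative)
  test_result(statistic = unname(ft$estimate), p_value = ft$p.value,
              alternative = alternative, method = "Fisher exact test",
              odds_ratio = unname(ft$estimate))
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test. Exact p-values are used for small samples
#' (`length(x) + length(y) <= 12`) without ties; otherwise the normal
#' approximation with tie and continuity correction applies. The reported
#' statistic is U for `x` relative to `y`.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return An `"embryodyn_test"`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  if (length(x) < 1 || length(y) < 1)
    stop("mann_whitney_u: empty sample")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  test_result(statistic = unname(wt$statistic), p_value = wt$p.value,
              alternative = alternative,
              method = "Mann-Whitney U test")
}

#' Pearson correlation test
#'
#' Pearson r with the usual t-based p-value (`t = r sqrt(n-2) /
#' sqrt(1-r^2)` on n-2 df). Zero-variance input yields a flagged
#' `undefined` result (`r = NA`, `p = NA`) rather than an error so that
#' consumers can drop the pair.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return An `"embryodyn_test"` with `r` and logical `undefined`.
#' @export
pearson_test <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(test_result(statistic = NA_real_, p_value = NA_real_,
                       alternative = alternative,
                       method = "Pearson correlation t-test",
                       r = NA_real_, undefined = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = alternative)
  test_result(statistic = unname(ct$statistic), p_value = ct$p.value,
              alternative = alternative,
              method = "Pearson correlation t-test",
              r = unname(ct$estimate), undefined = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1. The
#' FDR procedure behind every "FDR <= 0.05" threshold in this package.
#'
#' @param pvals Numeric p-values in \[0, 1\] (`NA` passed through).
#' @return Adjusted q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Welch test on log2-transformed replicate values
#'
#' Replicate-level differential call used by [call_degs()]: a Welch t-test
#' on `log2(value + 1)` with the log2 fold change defined as the mean
#' difference on that scale (B relative to A). Degenerate input with both
#' groups constant and equal yields `p = 1`.
#'
#' @param group_a,group_b Numeric replicate values, >= 2 each.
#' @return An `"embryodyn_test"` with `log2fc`.
#' @export
two_sample_log_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("two_sample_log_test: need >= 2 replicates per group")
  la <- log2(group_a + 1); lb <- log2(group_b + 1)
  lfc <- mean(lb) - mean(la)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    p <- if (lfc == 0) 1 else 0
    return(test_result(statistic = if (lfc == 0) 0 else Inf, p_value = p,
                       alternative = "two.sided",
                       method = "Welch t-test on log2(x+1)",
                       log2fc = lfc))
  }
  tt <- stats::t.test(lb, la, var.equal = FALSE)
  test_result(statistic = unname(tt$statistic), p_value = tt$p.value,
              alternative = "two.sided",
              method = "Welch t-test on log2(x+1)", log2fc = lfc)
}
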