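# Statistical primitives used throughout: two-sided Mann-Whitney-Wilcoxon
# rank-sum test, multiple-testing corrections, correlations.

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Exact tail probabilities are used when both samples have at most
#' `exact_max` observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is applied.
#' The two-sided p is twice the smaller tail, capped at 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"` (the switch above), `"exact"`, or `"normal"`.
#' @param exact_max Size bound for exact enumeration (default 8).
#' @return A list with `statistic` (the U statistic of `x`), `p.value`,
#'   `method`, and `n` (per-group sizes).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p.value # 1/3
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal"),
                         exact_max = 8) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) sc_stop("mann_whitney requires non-empty samples")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  ties <- table(r)
  has_ties <- any(ties > 1)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (mode == "auto") mode <- if (n <= exact_max && m <= exact_max && !has_ties) "exact" else "normal"
  if (mode == "exact") {
    if (has_ties) sc_stop("exact Mann-Whitney p is unavailable with ties")
    p.lower <- stats::pwilcox(U, n, m)
    p.upper <- 1 - stats::pwilcox(U - 1, n, m)
    p <- min(1, 2 * min(p.lower, p.upper))
    method <- "exact"
  } else {
    mu <- n * m / 2
    tie_term <- sum(ties^3 - ties)
    sigma <- sqrt((n * m / 12) * ((n + m + 1) - tie_term / ((n + m) * (n + m - 1))))
    if (sigma == 0) sc_stop("all observations identical; rank-sum test undefined")
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sigma  # continuity correction toward the mean
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie- and continuity-corrected)"
  }
  list(statistic = U, p.value = p, method = method, n = c(n = n, m = m))
}

#' Bonferroni correction
#'
#' `min(1, p * m)`. Downstream significance callers use the corrected
#' threshold 0.01 by default (see [decile_report()]).
#'
#' @param pvals P-values in `[0, 1]`.
#' @param m Number of comparisons (default `length(pvals)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE), m >= length(pvals))
  stats::p.adjust(pvals, method = "bonferroni", n = m)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up procedure with monotonicity enforcement; adjusted values
#' never fall below the raw p and are capped at 1.
#'
#' @param pvals P-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
benjamini_hochberg <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Pearson or Spearman correlation coefficient
#'
#' Spearman uses average ranks for ties. Zero variance in either input is an
#' error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return Coefficient in `[-1, 1]`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    sc_stop("correlation requires equal-length vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    sc_stop("correlation undefined for zero-variance input")
  stats::cor(x, y, method = method)
}
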