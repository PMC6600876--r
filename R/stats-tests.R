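#' @importFrom stats t.test wilcox.test shapiro.test p.adjust pt psignrank
NULL

.test_result <- function(statistic, p, test_name, df = NA_real_, n = NA_integer_) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), test_name = test_name, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  df_txt <- if (is.na(x$df)) "" else sprintf("(%g)", x$df)
  cat(sprintf("%s: statistic%s = %.4g, p = %.4g\n",
              x$test_name, df_txt, x$statistic, x$p))
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided paired t-test on differences `d = y - x`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom. By
#' convention the comparisons in this package call `paired_t(case,
#' control)`, so a positive statistic means the control group is higher.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return a `test_result` with `statistic`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- y - x
  if (sd(d) == 0) {
    stop("degenerate input: paired differences have zero variance")
  }
  res <- t.test(y, x, paired = TRUE)
  .test_result(res$statistic, res$p.value, "paired t",
               df = res$parameter, n = length(x))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom;
#' used for unpaired comparisons such as group ages.
#'
#' @param x,y numeric samples (each length >= 2, positive variance).
#' @return a `test_result`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  if (sd(x) == 0 && sd(y) == 0) {
    stop("degenerate input: both samples are constant")
  }
  res <- t.test(x, y, var.equal = FALSE)
  .test_result(res$statistic, res$p.value, "Welch t",
               df = res$parameter, n = length(x) + length(y))
}

#' Wilcoxon signed-rank test
#'
#' Paired signed-rank test on `y - x`. Zero differences are dropped, ties
#' are mid-ranked. The reported statistic `W` is the smaller of the
#' positive- and negative-rank sums. The p-value is exact (signed-rank
#' distribution, equivalent to enumerating all `2^n` sign patterns) for
#' `n <= 25` without ties, and a normal approximation with tie correction
#' otherwise.
#'
#' @param x,y paired numeric vectors.
#' @return a `test_result` (statistic `W`, no df).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) stop("fewer than 2 nonzero differences")
  r <- rank(abs(d))
  v_pos <- sum(r[d > 0])
  m_tot <- n * (n + 1) / 2
  w <- min(v_pos, m_tot - v_pos)
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= 25) {
    # symmetric null distribution: double the lower tail of the min sum
    p <- min(1, 2 * psignrank(w, n))
  } else {
    res <- suppressWarnings(wilcox.test(y, x, paired = TRUE,
                                        exact = FALSE, correct = TRUE))
    p <- res$p.value
  }
  .test_result(w, p, "Wilcoxon signed-rank", n = n)
}

#' Shapiro-Wilk normality test
#'
#' Screens samples for deviation from normality before relying on paired
#' t-tests; `W` near 1 indicates approximate normality.
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @return a `test_result` (statistic `W`, no df).
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(x) == 0) stop("degenerate input: constant sample")
  res <- shapiro.test(x)
  .test_result(res$statistic, res$p.value, "Shapiro-Wilk", n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_(i) = min_{j >= i} (m * p_(j) / j)`,
#' capped at 1, in the original order.
#'
#' @param pvals numeric p-values in `[0, 1]` (NA allowed, passed through).
#' @return numeric vector of adjusted values.
#' @export
fdr_bh <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Bonferroni correction
#'
#' @param p raw p-value(s) in `[0, 1]`.
#' @param m family size (>= 1).
#' @return `min(1, m * p)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m) {
  if (m < 1) stop("family size m must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p)
}
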