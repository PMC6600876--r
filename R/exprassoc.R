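#' @importFrom stats lm hatvalues cooks.distance pf coef var residuals
NULL

#' Donor-wise expression normalization
#'
#' Standardizes each donor's regional expression values (zero mean, unit
#' variance across regions), then averages the standardized profiles
#' across donors, yielding one normalized region-level profile per gene.
#'
#' @param donor_tables either a named list of named numeric vectors (one
#'   per donor, names = regions), or a long data.frame with columns
#'   `donor`, `region`, `value`.
#' @param gene gene symbol for the returned profile.
#' @return an [expression_profile()].
#' @export
normalize_expression <- function(donor_tables, gene = "gene") {
  if (is.data.frame(donor_tables)) {
    need <- c("donor", "region", "value")
    if (!all(need %in% names(donor_tables))) {
      stop("long-format table needs columns donor, region, value")
    }
    donor_tables <- lapply(split(donor_tables, donor_tables$donor),
                           function(d) setNames(d$value, d$region))
  }
  if (length(donor_tables) < 1) stop("need at least one donor")
  regions <- sort(names(donor_tables[[1]]))
  if (is.null(regions) || length(regions) < 2) {
    stop("each donor table must be named by region (>= 2 regions)")
  }
  std <- lapply(seq_along(donor_tables), function(i) {
    v <- donor_tables[[i]]
    if (!all(regions %in% names(v)) || length(v) != length(regions)) {
      stop("donor ", i, " does not cover the same regions as donor 1")
    }
    v <- v[regions]
    s <- sd(v)
    if (s == 0) stop("donor ", i, " has zero expression variance")
    (v - mean(v)) / s
  })
  avg <- Reduce(`+`, std) / length(std)
  expression_profile(gene, avg, donor_count = length(std))
}

#' Simple regression of a regional graph metric on gene expression
#'
#' Ordinary least squares fit of
#' `metric ~ intercept + beta * expression` across regions, with the full
#' influence diagnostics needed to assess single-region leverage:
#' residuals, hat values and Cook's distances.
#'
#' @param metric_by_region named numeric vector of the graph metric
#'   (names = region labels).
#' @param expression an [expression_profile()] (or named numeric vector).
#' @param regions optional character vector restricting the fit to a
#'   subset of regions (e.g. cortical only); default uses all regions
#'   present in both inputs.
#' @return object of class `expression_regression`: slope `beta` (with
#'   standard error `beta_se`), `intercept`, `r_squared`, `f_statistic`
#'   with `df1`/`df2`, `p_value`, and per-region `residuals`, `leverage`,
#'   `cooks`.
#' @export
fit_expression_regression <- function(metric_by_region, expression,
                                      regions = NULL) {
  xvals <- if (inherits(expression, "expression_profile")) {
    expression$values
  } else {
    expression
  }
  common <- intersect(names(metric_by_region), names(xvals))
  if (!is.null(regions)) common <- intersect(common, regions)
  n <- length(common)
  if (n < 3) stop("need at least 3 regions with both metric and expression")
  y <- as.numeric(metric_by_region[common])
  x <- as.numeric(xvals[common])
  if (var(x) == 0) stop("constant predictor: expression has no variance")
  if (var(y) == 0) stop("constant outcome: metric has no variance")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  fstat <- unname(sm$fstatistic["value"])
  df2 <- n - 2
  h <- unname(hatvalues(fit))
  cd <- unname(cooks.distance(fit))
  # numerically perfect fit: residuals are machine noise, influence is nil
  if (sum(residuals(fit)^2) <= 1e-24 * sum((y - mean(y))^2)) {
    cd <- rep(0, n)
  }
  cd[is.nan(cd)] <- 0            # exact zero residual variance
  cd[h >= 1 - 1e-12] <- Inf      # exact leverage point
  structure(list(
    beta = unname(coef(fit)[2]),
    beta_se = unname(sm$coefficients[2, "Std. Error"]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    f_statistic = fstat,
    df1 = 1L, df2 = as.integer(df2),
    p_value = pf(fstat, 1, df2, lower.tail = FALSE),
    n = n, regions = common,
    residuals = setNames(unname(residuals(fit)), common),
    leverage = setNames(h, common),
    cooks = setNames(cd, common),
    x = setNames(x, common), y = setNames(y, common),
    gene = if (inherits(expression, "expression_profile"))
      expression$gene else NA_character_
  ), class = "expression_regression")
}

#' @export
print.expression_regression <- function(x, ...) {
  cat(sprintf(
    "Expression regression%s: F(%d,%d) = %.3f, R2 = %.3f, beta = %.4g, p = %.3g\n",
    if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
    x$df1, x$df2, x$f_statistic, x$r_squared, x$beta, x$p_value))
  invisible(x)
}

#' Influential regions by Cook's distance
#'
#' Flags observations whose Cook's distance
#' `c_i = e_i^2 h_ii / (p s^2 (1 - h_ii)^2)` (p = 2 parameters) exceeds
#' the cutoff. The default rule is `4/n`; a fixed numeric cutoff may be
#' given instead. Exact leverage points (`h = 1`) carry infinite distance
#' and are always flagged.
#'
#' @param result an [fit_expression_regression()] result.
#' @param cutoff_rule `"four_over_n"` (default) or a numeric cutoff.
#' @return character vector of flagged region labels, with the numeric
#'   cutoff as attribute `"cutoff"`.
#' @export
cooks_flags <- function(result, cutoff_rule = "four_over_n") {
  stopifnot(inherits(result, "expression_regression"))
  cutoff <- if (is.numeric(cutoff_rule)) {
    cutoff_rule
  } else if (identical(cutoff_rule, "four_over_n")) {
    4 / result$n
  } else {
    stop("cutoff_rule must be 'four_over_n' or a number")
  }
  flagged <- names(result$cooks)[result$cooks > cutoff]
  attr(flagged, "cutoff") <- cutoff
  flagged
}

#' Refit the expression regression without selected regions
#'
#' Sensitivity analysis: re-fits the regression on the complement of
#' `excluded`, so influential regions can be checked for driving the
#' association. Residual degrees of freedom shrink by the number of
#' excluded regions.
#'
#' @inheritParams fit_expression_regression
#' @param excluded character vector of region labels to drop.
#' @return an `expression_regression` on the remaining regions.
#' @export
sensitivity_refit <- function(metric_by_region, expression, excluded,
                              regions = NULL) {
  keep <- setdiff(names(metric_by_region), excluded)
  if (!is.null(regions)) keep <- intersect(keep, regions)
  fit_expression_regression(metric_by_region[keep], expression)
}

#' Multi-gene, multi-group, multi-metric regression screen
#'
#' Fits one expression regression per (group, gene, metric) cell and
#' applies a single Bonferroni family over all cells
#' (`m = groups x genes x metrics`), testing whether an association is
#' specific to one gene rather than generic to regional expression.
#'
#' @param metrics_by_group named list (one element per group) of named
#'   lists (one per metric) of named numeric region vectors.
#' @param expressions named list of [expression_profile()] objects, one
#'   per gene.
#' @param regions optional region subset for every fit (e.g. cortical
#'   regions only).
#' @return data.frame with one row per cell: `group`, `gene`, `metric`,
#'   `n`, `beta`, `r_squared`, `f`, `df2`, `p`, `p_corr`; the family size
#'   is attached as attribute `"m"`.
#' @export
multi_gene_screen <- function(metrics_by_group, expressions,
                              regions = NULL) {
  if (length(metrics_by_group) < 1 || length(expressions) < 1) {
    stop("need at least one group and one gene")
  }
  groups <- names(metrics_by_group)
  genes <- names(expressions)
  metrics <- names(metrics_by_group[[1]])
  if (is.null(groups) || is.null(genes) || is.null(metrics)) {
    stop("metrics_by_group and expressions must be named")
  }
  for (g in groups) {
    if (!identical(names(metrics_by_group[[g]]), metrics)) {
      stop("all groups must provide the same metrics")
    }
  }
  m <- length(groups) * length(genes) * length(metrics)
  cells <- expand.grid(group = groups, gene = genes, metric = metrics,
                       stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    fit <- fit_expression_regression(
      metrics_by_group[[cells$group[i]]][[cells$metric[i]]],
      expressions[[cells$gene[i]]], regions = regions)
    data.frame(group = cells$group[i], gene = cells$gene[i],
               metric = cells$metric[i], n = fit$n, beta = fit$beta,
               r_squared = fit$r_squared, f = fit$f_statistic,
               df2 = fit$df2, p = fit$p_value)
  }))
  res$p_corr <- bonferroni(res$p, m)
  attr(res, "m") <- m
  res
}
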