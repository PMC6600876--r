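#' Threshold curve
#'
#' A graph metric evaluated over a strictly increasing grid of
#' streamline-count thresholds. Integrating the curve (see [auc()]) frees
#' downstream comparisons from committing to one arbitrary threshold.
#'
#' @param grid strictly increasing numeric threshold values (length >= 2).
#' @param values metric value at each grid point.
#' @param metric_name name of the metric.
#' @return object of class `threshold_curve`.
#' @export
threshold_curve <- function(grid, values, metric_name = "metric") {
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  if (length(grid) < 2) stop("grid must have at least 2 points")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (length(values) != length(grid)) {
    stop("values and grid must have equal length")
  }
  structure(list(grid = grid, values = values, metric_name = metric_name),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("Threshold curve '%s': %d points on [%g, %g], AUC = %.4g\n",
              x$metric_name, length(x$grid), min(x$grid), max(x$grid),
              auc(x)))
  invisible(x)
}

# Resolve a metric specification to function(weighted_network) -> scalar.
# Accepts a function, one of the named global metrics, or
# "class_mean:<class>" for an edge-class mean weight.
.resolve_metric <- function(metric) {
  if (is.function(metric)) return(metric)
  if (!is.character(metric) || length(metric) != 1) {
    stop("metric must be a function or a metric name")
  }
  if (startsWith(metric, "class_mean:")) {
    cls <- sub("^class_mean:", "", metric)
    if (!cls %in% c("subcortical", "left", "right", "interhemispheric")) {
      stop("unknown edge class: ", cls)
    }
    return(function(net) {
      m <- edge_class_mean_weights(net)
      if (cls %in% names(m)) unname(m[cls]) else NA_real_
    })
  }
  switch(metric,
    mean_degree = function(net) mean(node_degree(net)),
    mean_strength = function(net) mean(node_strength(net)),
    mean_clustering = function(net) mean(clustering_weighted(net)),
    global_efficiency = function(net) global_efficiency(net),
    stop("unknown metric: ", metric))
}

#' Evaluate a metric across a threshold grid
#'
#' Rebuilds the weighted network at each threshold in `grid` and evaluates
#' the metric, producing a [threshold_curve()].
#'
#' @param counts symmetric streamline-count matrix.
#' @param fa symmetric mean-FA matrix.
#' @param parcellation a [parcellation()].
#' @param grid strictly increasing numeric thresholds (length >= 2).
#' @param metric a function `weighted_network -> scalar`, one of
#'   `"mean_degree"`, `"mean_strength"`, `"mean_clustering"`,
#'   `"global_efficiency"`, or `"class_mean:<class>"`.
#' @param weight_mode passed to [build_weighted_network()].
#' @param ... further arguments to [build_weighted_network()].
#' @return a [threshold_curve()].
#' @export
threshold_sweep <- function(counts, fa, parcellation, grid,
                            metric = "mean_strength", weight_mode = "fa",
                            ...) {
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing with at least 2 points")
  }
  fn <- .resolve_metric(metric)
  name <- if (is.character(metric)) metric else "metric"
  vals <- vapply(grid, function(tau) {
    fn(build_weighted_network(counts, fa, parcellation, threshold = tau,
                              weight_mode = weight_mode, ...))
  }, numeric(1))
  threshold_curve(grid, vals, name)
}

#' Area under a threshold curve
#'
#' Trapezoidal integral of the metric over the threshold grid; exact for
#' piecewise-linear curves.
#'
#' @param curve a [threshold_curve()], or a numeric vector of values (then
#'   `grid` must be supplied).
#' @param grid thresholds, when `curve` is a plain vector.
#' @return numeric scalar.
#' @export
auc <- function(curve, grid = NULL) {
  if (inherits(curve, "threshold_curve")) {
    grid <- curve$grid
    values <- curve$values
  } else {
    values <- as.numeric(curve)
  }
  if (is.null(grid) || length(grid) < 2) {
    stop("need a grid with at least 2 points")
  }
  sum(diff(grid) * (values[-1] + values[-length(values)]) / 2)
}

#' Bootstrapped confidence interval around the median
#'
#' Percentile bootstrap interval for the sample median, used for the error
#' bars on group curves.
#'
#' @param values numeric sample (length >= 2).
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed optional integer seed for reproducible intervals; the
#'   caller's RNG state is left untouched.
#' @return named numeric vector `c(low, high)`.
#' @importFrom stats median quantile
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000, level = 0.95,
                                seed = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  meds <- vapply(seq_len(n_boot), function(b) {
    median(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(quantile(meds, c(alpha, 1 - alpha), type = 7))
  c(low = ci[1], high = ci[2])
}
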