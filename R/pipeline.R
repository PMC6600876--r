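#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. The defaults are the
#' package's documented choices: an integer streamline-count threshold
#' grid 0-20, FA edge weights, joint (all-subject) consensus, Shapiro
#' screening at 0.05 and FDR at 0.05.
#'
#' @param cohort_dir directory holding a cohort written by
#'   [write_cohort()] (`NULL` when a cohort object is passed to
#'   [run_pipeline()] directly).
#' @param out_dir directory for result tables (`NULL` = do not write).
#' @param grid threshold grid: a numeric vector or a string `"A:B:STEP"`.
#' @param weight_mode edge-weight definition (default `"fa"`).
#' @param consensus_scope `"joint"` or `"per_group"`.
#' @param nodal_metrics nodal metrics to compare (default degree,
#'   strength, clustering; add `"local_efficiency"` for the full set).
#' @param alpha_normality Shapiro-Wilk screening level.
#' @param fdr_level FDR significance level.
#' @param n_boot bootstrap resamples for median CIs.
#' @param seed integer seed for bootstrap resampling.
#' @param expression_files named character vector of expression file
#'   paths (names = gene symbols), for the association stage.
#' @param regression_regions `"cortical"` (default) restricts the
#'   expression regressions to cortical regions; `"all"` uses every
#'   region with expression data.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(cohort_dir = NULL, out_dir = NULL,
                            grid = 0:20, weight_mode = "fa",
                            consensus_scope = "joint",
                            nodal_metrics = c("degree", "strength",
                                              "clustering"),
                            alpha_normality = 0.05, fdr_level = 0.05,
                            n_boot = 10000, seed = 1,
                            expression_files = NULL,
                            regression_regions = c("cortical", "all")) {
  if (is.character(grid) && length(grid) == 1) {
    parts <- as.numeric(strsplit(grid, ":")[[1]])
    if (length(parts) != 3 || any(is.na(parts))) {
      stop("grid string must have the form 'A:B:STEP'")
    }
    grid <- seq(parts[1], parts[2], by = parts[3])
  }
  grid <- .grid_check(grid)
  regression_regions <- match.arg(regression_regions)
  if (!consensus_scope %in% c("joint", "per_group")) {
    stop("consensus_scope must be 'joint' or 'per_group'")
  }
  stopifnot(all(nodal_metrics %in% c("degree", "strength", "clustering",
                                     "local_efficiency")))
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir, grid = grid,
                 weight_mode = weight_mode,
                 consensus_scope = consensus_scope,
                 nodal_metrics = nodal_metrics,
                 alpha_normality = alpha_normality, fdr_level = fdr_level,
                 n_boot = n_boot, seed = as.integer(seed),
                 expression_files = expression_files,
                 regression_regions = regression_regions),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$expression_files)) {
    vals$expression_files <- unlist(vals$expression_files)
  }
  do.call(pipeline_config, vals)
}

# Per-subject mean regional AUC/span of a nodal metric, averaged within a
# group: the regional table entering the expression regressions.
.group_mean_nodal <- function(cohort, group, metric, grid, weight_mode) {
  span <- diff(range(grid))
  subs <- cohort_subjects(cohort, group)
  vals <- vapply(subs, function(s) {
    w <- if (weight_mode == "fa") s$fa else s$counts
    .auc_rows(.sweep_nodal(s$counts, w, grid, metric), grid) / span
  }, numeric(nrow(cohort$parcellation)))
  setNames(rowMeans(vals), cohort$parcellation$label)
}

#' Run the full group-analysis pipeline
#'
#' Chains the four analysis stages on a cohort: (1) edge-class weight
#' comparison, (2) global graph-metric comparison with consensus
#' thresholding, (3) nodal comparisons with FDR, and — when expression
#' profiles are supplied — (4) the gene-expression association screen on
#' group-average regional metrics. Result tables are returned as a bundle
#' and optionally written as delimited text with a machine-readable run
#' log.
#'
#' @param config a [pipeline_config()].
#' @param cohort a cohort object; when `NULL`, read from
#'   `config$cohort_dir`.
#' @param expressions optional named list of [expression_profile()]
#'   objects; when `NULL`, read from `config$expression_files`.
#' @return list with `edge_class`, `global`, `nodal` (one table per
#'   metric), `expression_screen` (or NULL), and `log`.
#' @export
run_pipeline <- function(config, cohort = NULL, expressions = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_seen <- character(0)
  wh <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  if (is.null(cohort)) {
    if (is.null(config$cohort_dir)) {
      stop("no cohort given and no cohort_dir configured")
    }
    cohort <- read_cohort(config$cohort_dir)
  }
  if (is.null(expressions) && !is.null(config$expression_files)) {
    expressions <- lapply(seq_along(config$expression_files), function(i) {
      read_expression(config$expression_files[i],
                      gene = names(config$expression_files)[i])
    })
    names(expressions) <- names(config$expression_files)
  }

  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = wh),
             error = function(e) {
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  }
  edge_class <- stage("edge_class", edge_class_comparison(
    cohort, config$grid, config$weight_mode))
  global <- stage("global", global_group_comparison(
    cohort, config$grid, config$weight_mode, consensus = TRUE,
    consensus_scope = config$consensus_scope))
  nodal <- lapply(config$nodal_metrics, function(m) {
    stage(paste0("nodal_", m), nodal_group_comparison(
      cohort, m, config$grid, config$weight_mode,
      config$alpha_normality, config$fdr_level))
  })
  names(nodal) <- config$nodal_metrics

  screen <- NULL
  if (!is.null(expressions)) {
    screen <- stage("expression", {
      regions <- if (config$regression_regions == "cortical") {
        cohort$parcellation$label[cortical_regions(cohort$parcellation)]
      } else NULL
      metrics_by_group <- lapply(c(case = "case", control = "control"),
        function(g) {
          lapply(setNames(nm = config$nodal_metrics), function(m) {
            .group_mean_nodal(cohort, g, m, config$grid,
                              config$weight_mode)
          })
        })
      multi_gene_screen(metrics_by_group, expressions, regions = regions)
    })
  }

  log <- list(
    package_version = as.character(utils::packageVersion("strucnet")),
    r_version = R.version.string,
    config = {
      cl <- unclass(config)
      cl[setdiff(names(cl), c("expression_files", "out_dir", "cohort_dir"))]
    },
    expression_genes = names(expressions),
    n_pairs = length(cohort$pairs),
    n_regions = nrow(cohort$parcellation),
    warnings = warnings_seen)

  bundle <- list(edge_class = edge_class, global = global, nodal = nodal,
                 expression_screen = screen, log = log)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(edge_class, file.path(config$out_dir, "edge_class.csv"),
              row.names = FALSE)
    write.csv(global, file.path(config$out_dir, "global_metrics.csv"),
              row.names = FALSE)
    for (m in names(nodal)) {
      write.csv(nodal[[m]],
                file.path(config$out_dir, paste0("nodal_", m, ".csv")),
                row.names = FALSE)
    }
    if (!is.null(screen)) {
      write.csv(screen,
                file.path(config$out_dir, "expression_screen.csv"),
                row.names = FALSE)
    }
    yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))
  }
  bundle
}
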