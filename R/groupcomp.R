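#' @importFrom stats median
NULL

# ---- internal fast sweep machinery -------------------------------------
# These helpers recompute metrics across the threshold grid directly on
# the raw matrices (equivalent to threshold_sweep + build_weighted_network
# at each grid point, which the tests assert) but without re-validating
# the container at every step, since the group comparisons rebuild
# networks thousands of times in calibration runs.

.grid_check <- function(grid) {
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing with at least 2 points")
  }
  as.numeric(grid)
}

# Class-mean weight curves for one subject: 4 x |grid|
.sweep_class_means <- function(counts, fa, cls_ut, grid) {
  ut <- upper.tri(counts)
  cvals <- counts[ut]
  wvals <- fa[ut]
  classes <- c("subcortical", "left", "right", "interhemispheric")
  cls_f <- factor(cls_ut, levels = classes)
  sizes <- tabulate(cls_f, nbins = 4)
  out <- matrix(0, 4, length(grid), dimnames = list(classes, NULL))
  for (t in seq_along(grid)) {
    keep <- cvals > grid[t]
    sums <- vapply(split(wvals * keep, cls_f), sum, numeric(1))
    out[, t] <- ifelse(sizes > 0, sums / sizes, NA_real_)
  }
  out
}

# Global metric curves for one subject: rows degree/strength/clustering/
# efficiency (+ consensus variants when masks supplied), cols = grid.
.sweep_global <- function(counts, fa, grid, masks = NULL) {
  n <- nrow(counts)
  rows <- c("degree", "strength", "clustering", "efficiency")
  if (!is.null(masks)) {
    rows <- c(rows, "clustering_consensus", "efficiency_consensus")
  }
  out <- matrix(0, length(rows), length(grid),
                dimnames = list(rows, NULL))
  for (t in seq_along(grid)) {
    w <- fa * (counts > grid[t])
    out["degree", t] <- mean(rowSums(w > 0))
    out["strength", t] <- mean(rowSums(w))
    out["clustering", t] <- mean(clustering_weighted(w))
    out["efficiency", t] <- if (max(w) > 0) global_efficiency(w) else 0
    if (!is.null(masks)) {
      wm <- w * masks[[t]]
      out["clustering_consensus", t] <- mean(clustering_weighted(wm))
      out["efficiency_consensus", t] <-
        if (max(wm) > 0) global_efficiency(wm) else 0
    }
  }
  out
}

# Nodal metric curves for one subject: n x |grid|
.sweep_nodal <- function(counts, fa, grid, metric) {
  n <- nrow(counts)
  out <- matrix(0, n, length(grid))
  for (t in seq_along(grid)) {
    w <- fa * (counts > grid[t])
    out[, t] <- switch(metric,
      degree = rowSums(w > 0),
      strength = rowSums(w),
      clustering = clustering_weighted(w),
      local_efficiency = local_efficiency(w),
      stop("unknown nodal metric: ", metric))
  }
  out
}

# Per-threshold consensus masks over a set of subjects (list of n x n 0/1)
.consensus_masks <- function(subjects, grid) {
  lapply(grid, function(tau) {
    m <- NULL
    for (s in subjects) {
      keep <- s$counts > tau
      m <- if (is.null(m)) keep else m & keep
    }
    diag(m) <- FALSE
    m + 0
  })
}

.auc_rows <- function(mat, grid) {
  apply(mat, 1, function(v) auc(v, grid = grid))
}

.se <- function(x) sd(x) / sqrt(length(x))

.shapiro_or_na <- function(x) {
  if (length(x) < 3 || sd(x) == 0) {
    return(c(W = NA_real_, p = NA_real_))
  }
  r <- shapiro_wilk(x)
  c(W = r$statistic, p = r$p)
}

# Assemble one comparison row (group summaries + paired t) from matched
# case/control value vectors.
.compare_row <- function(case_vals, ctrl_vals) {
  sh_case <- .shapiro_or_na(case_vals)
  sh_ctrl <- .shapiro_or_na(ctrl_vals)
  degen <- sd(ctrl_vals - case_vals) == 0
  if (degen) {
    t_stat <- NA_real_; df <- NA_real_; p <- NA_real_
  } else {
    tt <- paired_t(case_vals, ctrl_vals)   # positive t = control higher
    t_stat <- tt$statistic; df <- tt$df; p <- tt$p
  }
  data.frame(case_mean = mean(case_vals), case_se = .se(case_vals),
             case_shapiro_w = sh_case["W"], case_shapiro_p = sh_case["p"],
             control_mean = mean(ctrl_vals), control_se = .se(ctrl_vals),
             control_shapiro_w = sh_ctrl["W"],
             control_shapiro_p = sh_ctrl["p"],
             t = t_stat, df = df, p = p, degenerate = degen,
             row.names = NULL)
}

# ---- public group comparisons ------------------------------------------

#' Edge-class group comparison
#'
#' For each subject and anatomical edge class, the class-mean edge weight
#' (zeros included) is evaluated across the threshold grid and reduced to
#' its area under the curve divided by the grid span (a
#' threshold-averaged class weight, on the FA scale). Classes are then
#' compared between cases and controls with paired t-tests, Bonferroni
#' corrected over the four classes.
#'
#' @param cohort a cohort from [generate_cohort()] or [read_cohort()].
#' @param grid strictly increasing streamline-count thresholds
#'   (default `0:20`).
#' @param weight_mode edge-weight definition (default `"fa"`).
#' @return data.frame with one row per edge class: group means, SEs,
#'   Shapiro-Wilk screens, paired `t`, `df`, `p` and Bonferroni `p_corr`.
#' @export
edge_class_comparison <- function(cohort, grid = 0:20, weight_mode = "fa") {
  grid <- .grid_check(grid)
  if (length(cohort$pairs) < 2) stop("need at least 2 pairs")
  span <- diff(range(grid))
  cls_ut <- edge_class_matrix(cohort$parcellation)[
    upper.tri(matrix(0, nrow(cohort$parcellation),
                     nrow(cohort$parcellation)))]
  per_subject <- function(s) {
    w <- if (weight_mode == "fa") s$fa else s$counts
    .auc_rows(.sweep_class_means(s$counts, w, cls_ut, grid), grid) / span
  }
  case_auc <- vapply(cohort$pairs, function(p) per_subject(p$case),
                     numeric(4))
  ctrl_auc <- vapply(cohort$pairs, function(p) per_subject(p$control),
                     numeric(4))
  rows <- do.call(rbind, lapply(1:4, function(k) {
    .compare_row(case_auc[k, ], ctrl_auc[k, ])
  }))
  out <- cbind(data.frame(class = rownames(case_auc)), rows)
  if (any(out$degenerate)) {
    stop("degenerate input: zero paired variance in class(es) ",
         paste(out$class[out$degenerate], collapse = ", "))
  }
  out$p_corr <- bonferroni(out$p, 4)
  out
}

#' Global graph-metric group comparison
#'
#' Mean degree, mean strength, mean clustering coefficient and global
#' efficiency are evaluated per subject across the threshold grid and
#' reduced to AUC / grid span. Clustering and efficiency are
#' density-sensitive, so they are additionally computed on
#' consensus-masked networks (at each threshold, only connections present
#' in every subject of the consensus pool are retained). Paired t-tests
#' per metric, Bonferroni corrected over the four metrics within each
#' variant.
#'
#' @inheritParams edge_class_comparison
#' @param consensus compute the consensus-masked variant of clustering
#'   and efficiency (default TRUE).
#' @param consensus_scope `"joint"` pools all subjects into one consensus
#'   (the default); `"per_group"` computes a separate consensus per group.
#' @return data.frame with one row per metric and variant
#'   (`native` or `consensus`).
#' @export
global_group_comparison <- function(cohort, grid = 0:20, weight_mode = "fa",
                                    consensus = TRUE,
                                    consensus_scope = c("joint",
                                                        "per_group")) {
  grid <- .grid_check(grid)
  consensus_scope <- match.arg(consensus_scope)
  if (length(cohort$pairs) < 2) stop("need at least 2 pairs")
  span <- diff(range(grid))
  masks_case <- masks_ctrl <- NULL
  if (consensus) {
    if (consensus_scope == "joint") {
      masks_case <- masks_ctrl <- .consensus_masks(cohort_subjects(cohort),
                                                   grid)
    } else {
      masks_case <- .consensus_masks(cohort_subjects(cohort, "case"), grid)
      masks_ctrl <- .consensus_masks(cohort_subjects(cohort, "control"),
                                     grid)
    }
  }
  per_subject <- function(s, masks) {
    w <- if (weight_mode == "fa") s$fa else s$counts
    .auc_rows(.sweep_global(s$counts, w, grid, masks), grid) / span
  }
  nr <- if (consensus) 6 else 4
  case_auc <- vapply(cohort$pairs, function(p) per_subject(p$case, masks_case),
                     numeric(nr))
  ctrl_auc <- vapply(cohort$pairs,
                     function(p) per_subject(p$control, masks_ctrl),
                     numeric(nr))
  metric_names <- rownames(case_auc)
  rows <- do.call(rbind, lapply(seq_len(nr), function(k) {
    .compare_row(case_auc[k, ], ctrl_auc[k, ])
  }))
  out <- cbind(data.frame(
    metric = sub("_consensus$", "", metric_names),
    variant = ifelse(grepl("_consensus$", metric_names),
                     "consensus", "native")), rows)
  if (any(out$degenerate)) {
    stop("degenerate input: zero paired variance for metric(s) ",
         paste(out$metric[out$degenerate], collapse = ", "))
  }
  out$p_corr <- NA_real_
  for (v in unique(out$variant)) {
    sel <- out$variant == v
    out$p_corr[sel] <- bonferroni(out$p[sel], 4)
  }
  out
}

#' Nodal graph-metric group comparison
#'
#' Per region, the chosen nodal metric is evaluated across the threshold
#' grid for every subject and reduced to AUC / grid span; regions are
#' compared between the matched groups with paired t-tests and
#' Benjamini-Hochberg FDR across regions. Each group's regional values
#' are screened with Shapiro-Wilk at `alpha_normality`; regions failing
#' the screen keep their statistics but are flagged (`normality_ok =
#' FALSE`) and excluded from significance claims. Regions with
#' zero-variance paired differences are marked `degenerate` and removed
#' from the FDR family (with a warning).
#'
#' @inheritParams edge_class_comparison
#' @param metric one of `"degree"`, `"strength"`, `"clustering"`,
#'   `"local_efficiency"`.
#' @param alpha_normality Shapiro-Wilk screening level (default 0.05).
#' @param fdr_level FDR significance level for the `significant` flag
#'   (default 0.05).
#' @return data.frame (class `node_stats_table`) with one row per region:
#'   group means/SEs, Shapiro statistics, `t`, `df`, `p`, FDR-adjusted
#'   `q`, and the flags `normality_ok`, `degenerate`, `significant`.
#' @export
nodal_group_comparison <- function(cohort,
                                   metric = c("degree", "strength",
                                              "clustering",
                                              "local_efficiency"),
                                   grid = 0:20, weight_mode = "fa",
                                   alpha_normality = 0.05,
                                   fdr_level = 0.05) {
  metric <- match.arg(metric)
  grid <- .grid_check(grid)
  if (length(cohort$pairs) < 2) stop("need at least 2 pairs")
  span <- diff(range(grid))
  n <- nrow(cohort$parcellation)
  per_subject <- function(s) {
    w <- if (weight_mode == "fa") s$fa else s$counts
    .auc_rows(.sweep_nodal(s$counts, w, grid, metric), grid) / span
  }
  case_auc <- vapply(cohort$pairs, function(p) per_subject(p$case),
                     numeric(n))
  ctrl_auc <- vapply(cohort$pairs, function(p) per_subject(p$control),
                     numeric(n))
  rows <- do.call(rbind, lapply(seq_len(n), function(k) {
    .compare_row(case_auc[k, ], ctrl_auc[k, ])
  }))
  out <- cbind(data.frame(region = cohort$parcellation$label), rows)
  out$normality_ok <- !is.na(out$case_shapiro_p) &
    !is.na(out$control_shapiro_p) &
    out$case_shapiro_p > alpha_normality &
    out$control_shapiro_p > alpha_normality
  if (any(out$degenerate)) {
    warning(sum(out$degenerate),
            " region(s) with zero-variance differences removed from the",
            " FDR family")
  }
  out$q <- NA_real_
  out$q[!out$degenerate] <- fdr_bh(out$p[!out$degenerate])
  out$significant <- !out$degenerate & out$normality_ok &
    !is.na(out$q) & out$q <= fdr_level
  attr(out, "metric") <- metric
  class(out) <- c("node_stats_table", "data.frame")
  out
}
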