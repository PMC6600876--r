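#' @importFrom stats rnorm runif rpois qnorm pnorm dnorm
NULL

# Truncated-normal sampler on (lo, hi) by inverse-CDF; exact and vectorized.
# sd = 0 degenerates to the (clamped) mean.
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  mean <- rep_len(mean, n)
  if (all(sd == 0)) return(pmin(pmax(mean, lo), hi))
  a <- pnorm(lo, mean, sd)
  b <- pnorm(hi, mean, sd)
  u <- runif(n, a, b)
  q <- qnorm(u, mean, sd)
  pmin(pmax(q, lo), hi)   # guard numerical spill at the bounds
}

# Mean of a normal(mu, sd) truncated to (lo, hi): closed form.
.truncnorm_mean <- function(mu, sd, lo = 0, hi = 1) {
  if (sd == 0) return(min(max(mu, lo), hi))
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Expression profile
#'
#' Regional gene-expression values bound to a parcellation's regions.
#'
#' @param gene gene symbol.
#' @param values named numeric vector, one finite value per region.
#' @param donor_count number of donors averaged into the profile.
#' @return object of class `expression_profile`.
#' @export
expression_profile <- function(gene, values, donor_count = 1L) {
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("values must be uniquely named by region")
  }
  if (!all(is.finite(values))) stop("expression values must be finite")
  structure(list(gene = gene, values = values,
                 donor_count = as.integer(donor_count)),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("Expression profile '%s': %d regions, %d donor(s)\n",
              x$gene, length(x$values), x$donor_count))
  invisible(x)
}

#' Generate a synthetic expression map with a hemispheric gradient
#'
#' Draws per-region expression values with dispersion `spatial_sd` and adds
#' `left_offset` to left-hemisphere cortical regions, emulating a gene
#' expressed more strongly in the left than the right hemisphere.
#' Deterministic given `seed`.
#'
#' @param parcellation a [parcellation()].
#' @param left_offset mean expression surplus of left over right cortical
#'   regions (default 0.5).
#' @param spatial_sd standard deviation of regional variation (default 0.1).
#' @param seed integer seed.
#' @param gene gene symbol attached to the profile.
#' @return an [expression_profile()] covering every region.
#' @export
generate_expression_map <- function(parcellation, left_offset = 0.5,
                                    spatial_sd = 0.1, seed = 1,
                                    gene = "GENE1") {
  if (spatial_sd < 0) stop("spatial_sd must be >= 0")
  n <- nrow(parcellation)
  vals <- local_seed(seed, rnorm(n, 0, spatial_sd))
  left <- parcellation$hemisphere == "left" & parcellation$tissue == "cortical"
  vals[left] <- vals[left] + left_offset
  names(vals) <- parcellation$label
  expression_profile(gene, vals, donor_count = 1L)
}

# Evaluate expr with a temporary RNG seeded at `seed`, restoring the
# caller's stream afterwards.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic cohort specification
#'
#' Parameters of the matched-pair cohort generator. Defaults mirror the
#' study conditions: 7 case/control pairs on an 85-region parcellation,
#' control edge-class mean FA (computed over all region pairs of a class,
#' absent connections counting as zero) of 0.18 subcortical-cortical,
#' 0.33 left-hemispheric, 0.30 right-hemispheric and 0.06
#' interhemispheric.
#'
#' @param n_pairs number of age-matched case/control pairs (default 7).
#' @param density expected fraction of nonzero edges in control networks
#'   (default 0.4).
#' @param class_mean_fa named vector of target control class-mean FA
#'   (zeros included) for `subcortical`, `left`, `right`,
#'   `interhemispheric`.
#' @param global_attenuation multiplicative case/control weight ratio in
#'   (0, 1]; 1 plants no global effect.
#' @param expression_coupling slope linking a node's expression value to
#'   extra attenuation of its incident edges in cases; 0 plants no
#'   regional effect.
#' @param subject_noise_sd per-edge FA noise scale; 0 makes subjects exact
#'   copies of the pair template (and the case an exact attenuated copy of
#'   its control).
#' @param count_scale mean streamline count of present edges (default 15).
#' @param backbone_fraction fraction of the target density carried by the
#'   cohort-wide shared backbone (a spanning tree plus common random
#'   edges, present in every subject) rather than by subject-specific
#'   edges; keeps group-consensus networks non-degenerate (default 0.7).
#' @param seed integer master seed; per-pair substreams are derived from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 7, density = 0.4,
                        class_mean_fa = c(subcortical = 0.18, left = 0.33,
                                          right = 0.30,
                                          interhemispheric = 0.06),
                        global_attenuation = 1, expression_coupling = 0,
                        subject_noise_sd = 0.02, count_scale = 15,
                        backbone_fraction = 0.7, seed = 1) {
  req <- c("subcortical", "left", "right", "interhemispheric")
  if (!all(req %in% names(class_mean_fa))) {
    stop("class_mean_fa must name all four edge classes")
  }
  if (any(class_mean_fa <= 0 | class_mean_fa >= 1)) {
    stop("class_mean_fa values must lie in (0, 1)")
  }
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (global_attenuation <= 0 || global_attenuation > 1) {
    stop("global_attenuation must be in (0, 1]")
  }
  if (subject_noise_sd < 0) stop("subject_noise_sd must be >= 0")
  if (count_scale <= 0) stop("count_scale must be positive")
  if (backbone_fraction <= 0 || backbone_fraction > 1) {
    stop("backbone_fraction must be in (0, 1]")
  }
  structure(list(n_pairs = as.integer(n_pairs), density = density,
                 class_mean_fa = class_mean_fa[req],
                 global_attenuation = global_attenuation,
                 expression_coupling = expression_coupling,
                 subject_noise_sd = subject_noise_sd,
                 count_scale = count_scale,
                 backbone_fraction = backbone_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Per-node attenuation factor from expression coupling, clamped to (0, 1].
.node_attenuation <- function(expression_values, coupling) {
  pmin(pmax(1 - coupling * expression_values, 1e-6), 1)
}

# Random spanning tree over n nodes (edge list, 2 columns).
.spanning_tree <- function(n) {
  perm <- sample.int(n)
  anchor <- vapply(2:n, function(i) perm[sample.int(i - 1, 1)], integer(1))
  cbind(pmin(perm[-1], anchor), pmax(perm[-1], anchor))
}

#' Generate a matched-pair synthetic cohort
#'
#' Builds `n_pairs` case/control subject pairs with known planted effects.
#' Each pair shares an edge-support template: a cohort-wide spanning-tree
#' backbone (guaranteeing the group consensus network stays connected)
#' plus pair-specific Erdos-Renyi edges at the configured density.
#' A pair-level FA template per present edge is drawn from a truncated
#' normal centred on the class target (the class target divided by the
#' density, so that the zero-included class mean matches
#' `class_mean_fa`). Both pair members are truncated-normal observations
#' of that template — the case around the template times
#' `global_attenuation` times the expression-coupled factor of both
#' endpoints, the control around the template itself — so with no planted
#' effect the two group labels are exchangeable. Streamline
#' counts are Poisson around `count_scale` (attenuated the same way for
#' cases), so count thresholds remove case edges earlier. Edges are
#' treated as independent given their class mean (between-subject edge
#' covariance is not modelled).
#'
#' Reproducibility: the master seed drives cohort-level structure; pair
#' `p` uses the derived substream seed `(seed + 104729 * p) mod (2^31 - 1)`.
#'
#' @param parcellation a [parcellation()].
#' @param expression an [expression_profile()] on the same parcellation.
#' @param spec a [cohort_spec()].
#' @return object of class `cohort`: list with `pairs` (each a list with
#'   `case` and `control` subjects holding `id`, `group`, `pair`, `age`,
#'   `counts`, `fa`), `parcellation`, and `spec`.
#' @export
generate_cohort <- function(parcellation, expression, spec) {
  stopifnot(inherits(parcellation, "parcellation"),
            inherits(expression, "expression_profile"),
            inherits(spec, "cohort_spec"))
  labels <- parcellation$label
  if (!identical(sort(names(expression$values)), sort(labels))) {
    stop("expression profile does not cover the parcellation regions")
  }
  xvals <- expression$values[labels]
  n <- length(labels)
  npair <- n * (n - 1) / 2
  ut <- upper.tri(matrix(0, n, n))
  cls <- edge_class_matrix(parcellation)[ut]
  mu_present <- spec$class_mean_fa[cls] / spec$density
  if (any(mu_present >= 1)) {
    stop("class_mean_fa / density implies present-edge FA >= 1; ",
         "raise density or lower class means")
  }
  a_node <- .node_attenuation(xvals, spec$expression_coupling)
  att_pair <- (spec$global_attenuation *
                 outer(a_node, a_node))[ut]   # per-edge case factor

  # cohort-level structure: shared backbone = spanning tree + common
  # random edges carrying backbone_fraction of the target density
  ut_idx <- which(ut)
  backbone <- local_seed(spec$seed, {
    tree <- .spanning_tree(n)
    tree_idx <- (tree[, 2] - 1) * n + tree[, 1]   # upper-triangle linear idx
    bb <- ut_idx %in% tree_idx
    target_bb <- spec$backbone_fraction * spec$density * npair
    q_bb <- max(0, (target_bb - (n - 1)) / (npair - (n - 1)))
    bb | (runif(npair) < q_bb)
  })
  # pair-specific edges fill the remaining density
  m_bb <- sum(backbone)
  q <- max(0, (spec$density * npair - m_bb) / (npair - m_bb))

  sym_mat <- function(vals) {
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    m[ut] <- vals
    m + t(m)
  }
  sd_ <- spec$subject_noise_sd

  pairs <- lapply(seq_len(spec$n_pairs), function(p) {
    local_seed((spec$seed + 104729 * p) %% (2^31 - 1), {
      support <- backbone | (runif(npair) < q)
      m <- sum(support)
      # pair template: both pair members are noisy observations of it,
      # so with no planted effect case and control are exchangeable
      template <- numeric(npair)
      template[support] <- .rtruncnorm(m, mu_present[support], sd_)
      if (sd_ > 0) {
        ctrl_fa <- case_fa <- numeric(npair)
        ctrl_fa[support] <- .rtruncnorm(m, template[support], sd_)
        case_fa[support] <- .rtruncnorm(m, (template * att_pair)[support],
                                        sd_)
      } else {
        ctrl_fa <- template
        case_fa <- template * att_pair
      }
      lam_ctrl <- spec$count_scale
      lam_case <- spec$count_scale * att_pair
      if (sd_ > 0) {
        ctrl_counts <- ifelse(support, 1 + rpois(npair, lam_ctrl - 1), 0)
        case_counts <- ifelse(support,
                              1 + rpois(npair, pmax(lam_case - 1, 0)), 0)
      } else {
        ctrl_counts <- ifelse(support, round(lam_ctrl), 0)
        case_counts <- ifelse(support, pmax(1, round(lam_case)), 0)
      }
      ctrl_age <- runif(1, 10, 43)
      case_age <- min(max(ctrl_age + runif(1, -2, 2), 5), 50)
      list(
        case = list(id = sprintf("pair%02d_case", p), group = "case",
                    pair = p, age = case_age,
                    counts = sym_mat(case_counts), fa = sym_mat(case_fa)),
        control = list(id = sprintf("pair%02d_control", p),
                       group = "control", pair = p, age = ctrl_age,
                       counts = sym_mat(ctrl_counts), fa = sym_mat(ctrl_fa))
      )
    })
  })
  structure(list(pairs = pairs, parcellation = parcellation, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d matched pairs, %d regions, ",
                     "attenuation = %g, coupling = %g\n"),
              length(x$pairs), nrow(x$parcellation),
              x$spec$global_attenuation, x$spec$expression_coupling))
  invisible(x)
}

#' All subjects of a cohort as a flat list
#' @param cohort a cohort from [generate_cohort()].
#' @param group optional filter, `"case"` or `"control"`.
#' @return list of subject records.
#' @export
cohort_subjects <- function(cohort, group = NULL) {
  out <- unlist(lapply(cohort$pairs, function(p) list(p$case, p$control)),
                recursive = FALSE)
  if (!is.null(group)) out <- Filter(function(s) s$group == group, out)
  out
}

#' Planted ground truth of a synthetic cohort
#'
#' Records the effects planted by a [cohort_spec()] so recovery tests can
#' check what the downstream pipeline ought to find: the global
#' case/control weight ratio, the regions whose coupled attenuation
#' exceeds the median (empty when `expression_coupling = 0`), and the
#' planted expression-attenuation slope.
#'
#' @param spec a [cohort_spec()].
#' @param expression the [expression_profile()] used for generation.
#' @return list with `global_ratio`, `coupled_nodes` (character labels),
#'   `slope`, `null_cohort` (TRUE when no effect is planted), and
#'   `expected_class_means` (analytic control class means including
#'   truncation).
#' @export
planted_truth <- function(spec, expression) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(expression, "expression_profile"))
  coupled <- character(0)
  if (spec$expression_coupling != 0) {
    a <- .node_attenuation(expression$values, spec$expression_coupling)
    atten <- 1 - a
    coupled <- names(a)[atten > median(atten)]
  }
  mu_present <- spec$class_mean_fa / spec$density
  expected <- vapply(mu_present, .truncnorm_mean,
                     numeric(1), sd = spec$subject_noise_sd) * spec$density
  list(global_ratio = spec$global_attenuation,
       coupled_nodes = coupled,
       slope = spec$expression_coupling,
       null_cohort = spec$global_attenuation == 1 &&
         spec$expression_coupling == 0,
       expected_class_means = expected)
}
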