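#' Weighted structural network
#'
#' Container binding a symmetric nonnegative region-by-region weight matrix
#' to a [parcellation()]. Weights are fractional anisotropy (FA) when
#' `weight_mode = "fa"`, or one of the alternative streamline-count based
#' definitions.
#'
#' @param weights symmetric nonnegative numeric matrix with zero diagonal;
#'   rows/columns follow the parcellation order.
#' @param parcellation a [parcellation()].
#' @param weight_mode one of `"fa"`, `"count"`, `"count_roi_norm"`,
#'   `"count_length_norm"`.
#' @param threshold the streamline-count threshold used to build the
#'   network (`NA` if none was applied).
#'
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, parcellation,
                             weight_mode = c("fa", "count", "count_roi_norm",
                                             "count_length_norm"),
                             threshold = NA_real_) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(parcellation, "parcellation"))
  weights <- as.matrix(weights)
  n <- nrow(parcellation)
  if (!is.numeric(weights) || nrow(weights) != n || ncol(weights) != n) {
    stop("weights must be a numeric ", n, "x", n, " matrix")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (max(abs(weights - t(weights))) > 1e-9) {
    stop("weights must be symmetric")
  }
  if (any(diag(weights) != 0)) {
    diag(weights) <- 0
  }
  if (weight_mode == "fa" && any(weights > 1)) {
    stop("FA weights must lie in [0, 1]")
  }
  dimnames(weights) <- list(parcellation$label, parcellation$label)
  structure(list(weights = weights, parcellation = parcellation,
                 weight_mode = weight_mode, threshold = threshold),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- nrow(x$weights)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Weighted network: %d regions, %d edges, mode = %s%s\n",
              n, m, x$weight_mode,
              if (is.na(x$threshold)) "" else
                sprintf(", threshold = %g", x$threshold)))
  invisible(x)
}

#' Symmetric streamline intersection
#'
#' Tractography streamline counts are direction-dependent; the symmetric
#' intersection averages streamlines starting and ending in each region
#' pair: `out[i,j] = (raw[i,j] + raw[j,i]) / 2`, with the diagonal zeroed.
#'
#' @param raw_counts square nonnegative numeric matrix of directed
#'   streamline counts.
#' @return symmetric matrix with zero diagonal.
#' @export
symmetric_density <- function(raw_counts) {
  raw_counts <- as.matrix(raw_counts)
  if (nrow(raw_counts) != ncol(raw_counts)) {
    stop("raw_counts must be square")
  }
  if (any(raw_counts < 0)) stop("raw_counts must be nonnegative")
  out <- (raw_counts + t(raw_counts)) / 2
  diag(out) <- 0
  out
}

#' Build a thresholded weighted network
#'
#' Implements the binarize-then-weight edge construction: the streamline
#' count matrix is thresholded (strictly: an edge is kept where
#' `counts > threshold`), the resulting binary mask is multiplied with the
#' chosen weight map. Supported weight modes:
#' \describe{
#'   \item{`fa`}{mean FA of the connection (the primary analysis weight).}
#'   \item{`count`}{the streamline count itself.}
#'   \item{`count_roi_norm`}{count divided by the mean size of the two
#'     regions, `counts[i,j] / ((size[i] + size[j]) / 2)`.}
#'   \item{`count_length_norm`}{count divided by mean streamline length,
#'     `counts[i,j] / lengths[i,j]`.}
#' }
#'
#' @param counts symmetric streamline-count matrix.
#' @param fa symmetric mean-FA matrix (values in `[0, 1]`); required for
#'   `"fa"` mode.
#' @param parcellation a [parcellation()].
#' @param threshold streamline-count threshold (kept edges have
#'   `counts > threshold`).
#' @param weight_mode edge-weight definition, see Details.
#' @param roi_sizes per-region sizes (e.g. voxel counts), required for
#'   `"count_roi_norm"`.
#' @param lengths per-edge mean streamline length matrix, required for
#'   `"count_length_norm"`.
#' @return a [weighted_network()].
#' @export
build_weighted_network <- function(counts, fa = NULL, parcellation,
                                   threshold = 0,
                                   weight_mode = c("fa", "count",
                                                   "count_roi_norm",
                                                   "count_length_norm"),
                                   roi_sizes = NULL, lengths = NULL) {
  weight_mode <- match.arg(weight_mode)
  counts <- as.matrix(counts)
  n <- nrow(parcellation)
  if (nrow(counts) != n || ncol(counts) != n) {
    stop("counts matrix does not match parcellation size")
  }
  mask <- counts > threshold
  mask <- mask | t(mask)        # counts symmetric by contract; be safe
  diag(mask) <- FALSE
  w <- switch(weight_mode,
    fa = {
      if (is.null(fa)) stop("fa matrix required for weight_mode = 'fa'")
      fa <- as.matrix(fa)
      if (any(fa < 0 | fa > 1)) stop("FA values must lie in [0, 1]")
      mask * fa
    },
    count = mask * counts,
    count_roi_norm = {
      if (is.null(roi_sizes)) {
        stop("roi_sizes required for weight_mode = 'count_roi_norm'")
      }
      if (length(roi_sizes) != n || any(roi_sizes <= 0)) {
        stop("roi_sizes must be ", n, " positive values")
      }
      denom <- outer(roi_sizes, roi_sizes, function(a, b) (a + b) / 2)
      mask * counts / denom
    },
    count_length_norm = {
      if (is.null(lengths)) {
        stop("lengths required for weight_mode = 'count_length_norm'")
      }
      lengths <- as.matrix(lengths)
      safe <- ifelse(lengths > 0, lengths, 1)
      mask * counts / safe
    })
  weighted_network(w, parcellation, weight_mode, threshold = threshold)
}

#' Group-consensus edge mask
#'
#' Consensus thresholding retains only the connections present in every
#' subject, equalizing network density across groups before comparing
#' density-sensitive metrics (clustering, efficiency). The mask is the
#' element-wise intersection of all input networks' supports.
#'
#' @param networks list of [weighted_network()] objects on one parcellation.
#' @return binary (0/1) symmetric matrix with zero diagonal.
#' @export
consensus_mask <- function(networks) {
  if (length(networks) < 1) stop("need at least one network")
  labels <- networks[[1]]$parcellation$label
  mask <- matrix(TRUE, length(labels), length(labels))
  for (net in networks) {
    if (!identical(net$parcellation$label, labels)) {
      stop("all networks must share one parcellation")
    }
    mask <- mask & (net$weights > 0)
  }
  diag(mask) <- FALSE
  out <- mask + 0
  dimnames(out) <- list(labels, labels)
  out
}

#' Apply a binary mask to a network
#'
#' @param network a [weighted_network()].
#' @param mask binary symmetric matrix (same size).
#' @return a [weighted_network()] with `weights * mask` and the original
#'   weight mode.
#' @export
apply_mask <- function(network, mask) {
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(network$weights))) {
    stop("mask dimensions do not match network")
  }
  if (max(abs(mask - t(mask))) > 0) stop("mask must be symmetric")
  weighted_network(network$weights * (mask != 0), network$parcellation,
                   network$weight_mode, threshold = network$threshold)
}

#' Anatomical class of an edge
#'
#' Every region pair belongs to exactly one of four classes:
#' `"subcortical"` (at least one subcortical endpoint, including
#' subcortical-subcortical pairs), `"left"` (both endpoints left cortical),
#' `"right"` (both right cortical), or `"interhemispheric"` (cortical
#' endpoints in opposite hemispheres).
#'
#' @param parcellation a [parcellation()].
#' @param i,j region indices (1-based), `i != j`.
#' @return character scalar, the edge class.
#' @export
edge_class_of <- function(parcellation, i, j) {
  if (i == j) stop("edge endpoints must differ")
  ti <- parcellation$tissue[i]; tj <- parcellation$tissue[j]
  if (ti == "subcortical" || tj == "subcortical") return("subcortical")
  hi <- parcellation$hemisphere[i]; hj <- parcellation$hemisphere[j]
  if (hi == "left" && hj == "left") return("left")
  if (hi == "right" && hj == "right") return("right")
  "interhemispheric"
}

#' Edge-class matrix for a parcellation
#'
#' Vectorized version of [edge_class_of()]: classifies all region pairs at
#' once.
#'
#' @param parcellation a [parcellation()].
#' @return character matrix, `class[i,j]` for all pairs (`NA` diagonal).
#' @export
edge_class_matrix <- function(parcellation) {
  sub <- parcellation$tissue == "subcortical"
  left <- parcellation$hemisphere == "left" & !sub
  right <- parcellation$hemisphere == "right" & !sub
  n <- nrow(parcellation)
  cls <- matrix("interhemispheric", n, n)
  cls[outer(left, left, "&")] <- "left"
  cls[outer(right, right, "&")] <- "right"
  cls[outer(sub, sub, "|")] <- "subcortical"
  diag(cls) <- NA_character_
  dimnames(cls) <- list(parcellation$label, parcellation$label)
  cls
}

#' Per-class mean edge weight
#'
#' Mean weight over all unordered region pairs of each anatomical class.
#' Absent connections count as zero, so a sparse class has a low mean even
#' if its present edges are strong; this is the convention used for
#' edge-weight group comparisons.
#'
#' @param network a [weighted_network()].
#' @return named numeric vector over the classes present in the
#'   parcellation (`subcortical`, `left`, `right`, `interhemispheric`).
#' @export
edge_class_mean_weights <- function(network) {
  cls <- edge_class_matrix(network$parcellation)
  ut <- upper.tri(cls)
  tapply(network$weights[ut], cls[ut], mean)
}
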