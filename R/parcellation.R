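#' Region parcellation
#'
#' A parcellation is the ordered list of brain regions that defines node
#' identity for every network, metric table and expression profile in the
#' package. Each region carries a unique label, a hemisphere
#' (`"left"`, `"right"`, or `"none"` for midline structures) and a tissue
#' class (`"cortical"` or `"subcortical"`).
#'
#' @param labels character vector of unique region labels.
#' @param hemisphere character vector, one of `"left"`, `"right"`, `"none"`
#'   per region.
#' @param tissue character vector, `"cortical"` or `"subcortical"` per region.
#'
#' @return An object of class `parcellation`: a data.frame with columns
#'   `label`, `hemisphere`, `tissue`.
#' @export
parcellation <- function(labels, hemisphere, tissue) {
  labels <- as.character(labels)
  hemisphere <- as.character(hemisphere)
  tissue <- as.character(tissue)
  n <- length(labels)
  if (length(hemisphere) != n || length(tissue) != n) {
    stop("labels, hemisphere and tissue must have equal length")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate region labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!all(hemisphere %in% c("left", "right", "none"))) {
    stop("hemisphere must be 'left', 'right' or 'none'")
  }
  if (!all(tissue %in% c("cortical", "subcortical"))) {
    stop("tissue must be 'cortical' or 'subcortical'")
  }
  if (any(hemisphere == "none" & tissue == "cortical")) {
    stop("cortical regions must be lateralized (hemisphere 'left' or 'right')")
  }
  out <- data.frame(label = labels, hemisphere = hemisphere, tissue = tissue,
                    stringsAsFactors = FALSE)
  class(out) <- c("parcellation", "data.frame")
  out
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation: %d regions (%d cortical, %d subcortical)\n",
              nrow(x), sum(x$tissue == "cortical"),
              sum(x$tissue == "subcortical")))
  invisible(x)
}

#' Number of regions in a parcellation
#' @param parc a [parcellation()].
#' @return integer count of regions.
#' @export
n_regions <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  nrow(parc)
}

#' Desikan-Killiany cortical region names
#'
#' The 34 cortical regions per hemisphere of the Desikan-Killiany atlas,
#' without hemisphere prefix.
#'
#' @return character vector of 34 names.
#' @export
dk_cortical_names <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
    "lingual", "medialorbitofrontal", "middletemporal", "parahippocampal",
    "paracentral", "parsopercularis", "parsorbitalis", "parstriangularis",
    "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
    "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
    "superiorfrontal", "superiorparietal", "superiortemporal",
    "supramarginal", "frontalpole", "temporalpole", "transversetemporal",
    "insula")
}

#' Standard subcortical region labels
#'
#' Seventeen subcortical structures: the brain stem plus bilateral
#' cerebellum, thalamus, caudate, putamen, pallidum, hippocampus, amygdala
#' and nucleus accumbens.
#'
#' @return character vector of 17 labels.
#' @export
dk_subcortical_labels <- function() {
  structures <- c("Cerebellum", "Thalamus", "Caudate", "Putamen",
                  "Pallidum", "Hippocampus", "Amygdala", "Accumbens")
  c("Brain-stem",
    paste0("Left-", structures),
    paste0("Right-", structures))
}

#' Generate a parcellation with bilateral cortex and named subcortex
#'
#' Builds the node set used throughout the pipeline: `n_cortical_per_hemi`
#' cortical regions per hemisphere (labelled `"lh-"` / `"rh-"` plus a base
#' name) and the given subcortical labels. Subcortical hemisphere is
#' inferred from a `"Left-"` / `"Right-"` label prefix; labels without such
#' a prefix (e.g. `"Brain-stem"`) are treated as midline (`hemisphere =
#' "none"`).
#'
#' @param n_cortical_per_hemi number of cortical regions per hemisphere
#'   (default 34, the Desikan-Killiany count).
#' @param subcortical_labels character vector of subcortical labels
#'   (default [dk_subcortical_labels()], 17 structures).
#' @param cortical_names base names for cortical regions, recycled to
#'   `n_cortical_per_hemi`; defaults to the Desikan-Killiany names when
#'   `n_cortical_per_hemi <= 34`, otherwise `"region<k>"`.
#'
#' @return A [parcellation()] with `2 * n_cortical_per_hemi +
#'   length(subcortical_labels)` regions; cortical regions first (all left,
#'   then all right), subcortex last.
#' @examples
#' parc <- generate_parcellation()   # 85 regions: 68 cortical + 17 subcortical
#' table(parc$tissue)
#' @export
generate_parcellation <- function(n_cortical_per_hemi = 34,
                                  subcortical_labels = dk_subcortical_labels(),
                                  cortical_names = NULL) {
  if (n_cortical_per_hemi < 1) stop("n_cortical_per_hemi must be >= 1")
  if (length(subcortical_labels) == 0) {
    stop("subcortical_labels must be nonempty")
  }
  if (anyDuplicated(subcortical_labels)) {
    stop("duplicate subcortical labels")
  }
  if (is.null(cortical_names)) {
    cortical_names <- if (n_cortical_per_hemi <= 34) {
      dk_cortical_names()[seq_len(n_cortical_per_hemi)]
    } else {
      paste0("region", seq_len(n_cortical_per_hemi))
    }
  }
  cortical_names <- cortical_names[seq_len(n_cortical_per_hemi)]
  sub_hemi <- ifelse(startsWith(subcortical_labels, "Left-"), "left",
              ifelse(startsWith(subcortical_labels, "Right-"), "right",
                     "none"))
  parcellation(
    labels = c(paste0("lh-", cortical_names),
               paste0("rh-", cortical_names),
               subcortical_labels),
    hemisphere = c(rep("left", n_cortical_per_hemi),
                   rep("right", n_cortical_per_hemi),
                   sub_hemi),
    tissue = c(rep("cortical", 2 * n_cortical_per_hemi),
               rep("subcortical", length(subcortical_labels)))
  )
}

#' Indices of cortical regions
#' @param parc a [parcellation()].
#' @return integer vector of row indices with `tissue == "cortical"`.
#' @export
cortical_regions <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  which(parc$tissue == "cortical")
}
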