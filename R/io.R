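#' @importFrom utils read.csv write.csv
NULL

#' Write a labeled symmetric matrix as delimited text
#'
#' Comma-separated with a header row and a leading label column, the
#' interchange dialect for all matrices in the package.
#'
#' @param m numeric matrix with row/column names.
#' @param path output file path.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) %||% paste0("region", seq_len(nrow(m)))
    colnames(m) <- rownames(m)
  }
  # 17 significant digits so doubles round-trip exactly
  chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  write.csv(as.data.frame(chr), path, row.names = TRUE)
  invisible(path)
}

#' Read a labeled symmetric matrix from delimited text
#'
#' Reads a matrix written by [write_matrix()], validating symmetry and
#' numeric content. When `labels` is supplied, rows/columns are realigned
#' to that order (so files whose regions are permuted load consistently).
#'
#' @param path input file path.
#' @param labels optional character vector: the expected region labels in
#'   canonical order.
#' @param tol symmetry tolerance (default 1e-9).
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, labels = NULL, tol = 1e-9) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop("non-numeric cell(s) in column '", colnames(df)[bad], "' of ",
         path)
  }
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("matrix in ", path, " is not square with matching labels")
  }
  asym <- abs(m - t(m))
  if (max(asym) > tol) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetric matrix in %s: cell (%s, %s) differs by %g",
                 path, rownames(m)[idx[1]], colnames(m)[idx[2]],
                 max(asym)))
  }
  if (!is.null(labels)) {
    if (!setequal(rownames(m), labels)) {
      stop("labels in ", path, " do not match the expected parcellation")
    }
    m <- m[labels, labels]
  }
  m
}

#' Write a parcellation table
#' @param parc a [parcellation()].
#' @param path output file path.
#' @export
write_parcellation <- function(parc, path) {
  write.csv(as.data.frame(parc), path, row.names = FALSE)
  invisible(path)
}

#' Read a parcellation table
#' @param path input file path.
#' @return a [parcellation()].
#' @export
read_parcellation <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  parcellation(df$label, df$hemisphere, df$tissue)
}

#' Write an expression profile as two-column delimited text
#' @param profile an [expression_profile()].
#' @param path output file path.
#' @export
write_expression <- function(profile, path) {
  write.csv(data.frame(region = names(profile$values),
                       value = unname(profile$values)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read an expression profile from two-column delimited text
#' @param path input file path.
#' @param gene gene symbol to attach.
#' @param donor_count donor count to attach (default 1).
#' @return an [expression_profile()].
#' @export
read_expression <- function(path, gene = NULL, donor_count = 1L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  expression_profile(gene, setNames(df$value, df$region), donor_count)
}

#' Write a cohort to a directory
#'
#' One counts and one FA matrix file per subject, plus `manifest.csv`
#' (subject id, group, pair, age, file names) and `parcellation.csv`.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.csv"))
  rows <- lapply(cohort_subjects(cohort), function(s) {
    counts_file <- paste0(s$id, "_counts.csv")
    fa_file <- paste0(s$id, "_fa.csv")
    write_matrix(s$counts, file.path(dir, counts_file))
    write_matrix(s$fa, file.path(dir, fa_file))
    data.frame(subject_id = s$id, group = s$group, pair = s$pair,
               age = s$age, counts_file = counts_file, fa_file = fa_file)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv`,
#'   `parcellation.csv` and per-subject matrix files.
#' @return a `cohort` object (without a generating spec).
#' @export
read_cohort <- function(dir) {
  parc <- read_parcellation(file.path(dir, "parcellation.csv"))
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    list(id = r$subject_id, group = r$group, pair = r$pair, age = r$age,
         counts = read_matrix(file.path(dir, r$counts_file), parc$label),
         fa = read_matrix(file.path(dir, r$fa_file), parc$label))
  })
  pair_ids <- sort(unique(manifest$pair))
  pairs <- lapply(pair_ids, function(p) {
    members <- subjects[manifest$pair == p]
    groups <- vapply(members, function(s) s$group, character(1))
    if (!setequal(groups, c("case", "control"))) {
      stop("pair ", p, " must contain exactly one case and one control")
    }
    list(case = members[[which(groups == "case")]],
         control = members[[which(groups == "control")]])
  })
  ages <- vapply(pairs, function(p) abs(p$case$age - p$control$age),
                 numeric(1))
  if (any(ages > 2 + 1e-9)) {
    warning("pair age difference exceeds 2 years for pair(s) ",
            paste(pair_ids[ages > 2 + 1e-9], collapse = ", "))
  }
  structure(list(pairs = pairs, parcellation = parc, spec = NULL),
            class = "cohort")
}
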