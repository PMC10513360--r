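#' Mean expression profiles per annotation category
#'
#' Averages raw counts over the observations of each category and normalizes
#' each category profile to unit sum, yielding the genes x categories
#' probability profiles used as transport targets.
#'
#' @param counts Observations x genes count matrix.
#' @param anno Named character vector (or factor) of category labels per
#'   observation.
#' @return Dense genes x categories matrix with unit column sums.
#' @export
mean_profiles <- function(counts, anno) {
  counts <- .check_counts(counts)
  anno <- .check_annotation(anno, rownames(counts))
  cats <- sort(unique(anno))
  ind <- .as_sparse(Matrix::sparseMatrix(
    i = seq_along(anno), j = match(anno, cats), x = 1,
    dims = c(length(anno), length(cats))
  ))
  sums <- .as_dense(Matrix::t(Matrix::crossprod(ind, counts)))  # genes x cats
  colnames(sums) <- cats
  rownames(sums) <- colnames(counts)
  cs <- colSums(sums)
  if (any(cs == 0)) stop("category without counts: ", paste(cats[cs == 0], collapse = ", "))
  sweep(sums, 2, cs, "/")
}

#' Library-size scaling followed by log1p transform
#'
#' Scales every observation to a common total and applies `log(1 + x)`.
#' All-zero observations stay zero. Sparsity is preserved.
#'
#' @param counts Observations x genes matrix.
#' @param scale Target total per observation (default `1e4`).
#' @return Matrix of the same class/shape.
#' @export
log1p_normalize <- function(counts, scale = 1e4) {
  stopifnot(scale > 0)
  x <- .row_normalize(counts, scale)
  if (is(x, "sparseMatrix")) {
    x <- .as_sparse(x)
    x@x <- log1p(x@x)
    x
  } else {
    log1p(x)
  }
}

#' Intersect the gene spaces of two matrices
#'
#' Annotation transfer requires overlapping feature spaces; genes present in
#' only one of the two matrices are dropped with a warning.
#'
#' @param a,b Observations x genes matrices.
#' @return List with elements `a` and `b` restricted to the shared genes.
#' @export
intersect_genes <- function(a, b) {
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) == 0) stop("no shared genes between the two matrices")
  dropped <- (ncol(a) - length(shared)) + (ncol(b) - length(shared))
  if (dropped > 0)
    warning(dropped, " gene columns not shared between datasets were dropped")
  list(a = a[, shared, drop = FALSE], b = b[, shared, drop = FALSE])
}
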