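#' Read an observations x genes count matrix
#'
#' Reads either a MatrixMarket triplet directory (`matrix.mtx` plus
#' `barcodes.tsv` observation ids and `features.tsv`/`genes.tsv` gene ids,
#' the layout written by common droplet pipelines) or a dense CSV with a
#' header row of gene names and a first column of observation ids.
#'
#' @param path Path to a directory containing the MTX triplet, to a `.mtx`
#'   file, or to a `.csv` file.
#' @return A sparse `dgCMatrix` (observations x genes) with id dimnames.
#' @export
read_count_matrix <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx in ", path)
    return(.read_mtx_triplet(mtx))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) return(.read_mtx_triplet(path))
  .read_csv_counts(path)
}

.read_mtx_triplet <- function(mtx_path) {
  dir <- dirname(mtx_path)
  barcodes <- file.path(dir, "barcodes.tsv")
  features <- file.path(dir, "features.tsv")
  if (!file.exists(features)) features <- file.path(dir, "genes.tsv")
  if (!file.exists(barcodes) || !file.exists(features))
    stop("missing barcodes.tsv or features.tsv next to ", mtx_path)
  m <- Matrix::readMM(mtx_path)
  obs <- readLines(barcodes)
  genes <- sapply(strsplit(readLines(features), "\t"), `[`, 1L)
  # conventionally stored genes x observations; transpose to obs x genes
  if (nrow(m) != length(genes) || ncol(m) != length(obs))
    stop("MTX dimensions do not match label files")
  m <- Matrix::t(m)
  dimnames(m) <- list(obs, genes)
  if (min(m) < 0) stop("negative entries in count matrix")
  .check_counts(.as_sparse(m))
}

.read_csv_counts <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (min(m) < 0) stop("negative entries in count matrix")
  .check_counts(.as_sparse(m))
}

#' Write a count matrix as a MatrixMarket triplet directory
#'
#' Inverse of [read_count_matrix()]; integer counts round-trip exactly.
#'
#' @param counts Observations x genes matrix with dimnames.
#' @param path Directory to create.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- .check_counts(.as_sparse(counts))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(counts), file.path(path, "matrix.mtx"))
  writeLines(rownames(counts), file.path(path, "barcodes.tsv"))
  writeLines(colnames(counts), file.path(path, "features.tsv"))
  invisible(path)
}

#' Read a per-observation categorical annotation from CSV
#'
#' @param path CSV with observation ids in the first column.
#' @param column Name or index of the label column (default first data column).
#' @return Named character vector of labels.
#' @export
read_annotation <- function(path, column = 1) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  setNames(as.character(df[[column]]), rownames(df))
}

#' Read a molecule table from CSV
#'
#' @param path CSV with at least columns `x`, `y`, `gene`.
#' @return A `data.frame` with x, y in micrometres and gene as character.
#' @export
read_molecules <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("x", "y", "gene")
  if (!all(need %in% names(df))) stop("molecule table needs columns x, y, gene")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("non-finite molecule coordinates")
  df$gene <- as.character(df$gene)
  df
}
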