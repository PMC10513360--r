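# Internal helpers shared across modules.

#' @import Matrix
#' @importFrom methods as is
#' @importFrom stats rpois rbinom rnbinom rgamma rlnorm rmultinom runif
#' @importFrom stats kmeans dist cor sd p.adjust t.test quantile optim setNames
NULL

# Coerce anything matrix-like to dgCMatrix, keeping dimnames.
.as_sparse <- function(x) {
  if (is(x, "dgCMatrix")) return(x)
  as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

.as_dense <- function(x) {
  if (is.matrix(x)) x else as.matrix(x)
}

# Validate an observations x genes count matrix.
.check_counts <- function(counts, what = "counts") {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(what, " must have observation rownames and gene colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop(what, " has duplicated observation or gene ids")
  if (min(counts) < 0) stop(what, " contains negative values")
  invisible(counts)
}

# Validate genes x categories profile matrix (unit column sums).
.check_profiles <- function(profiles) {
  if (is.null(rownames(profiles)) || is.null(colnames(profiles)))
    stop("profiles must have gene rownames and category colnames")
  cs <- colSums(profiles)
  if (any(abs(cs - 1) > 1e-9))
    stop("profile columns must sum to 1")
  if (min(profiles) < 0) stop("profiles contain negative values")
  invisible(profiles)
}

# Align a per-observation annotation (named character/factor) to obs ids.
.check_annotation <- function(anno, obs_ids) {
  if (is.null(names(anno))) {
    if (length(anno) != length(obs_ids))
      stop("annotation length does not match number of observations")
    names(anno) <- obs_ids
  }
  missing <- setdiff(obs_ids, names(anno))
  if (length(missing))
    stop("annotation missing for observations: ", paste(utils::head(missing, 5), collapse = ", "))
  as.character(anno[obs_ids])
}

# Row-normalize a matrix to given row totals; zero rows stay zero.
.row_normalize <- function(x, totals = 1) {
  rs <- rowSums(x)
  fac <- ifelse(rs > 0, totals / rs, 0)
  if (is(x, "sparseMatrix")) {
    Matrix::Diagonal(x = fac) %*% x
  } else {
    x * fac
  }
}

# Derive a reproducible stream seed from a base seed and an index,
# staying inside 32-bit integer range.
.sub_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
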