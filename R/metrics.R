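#' Bhattacharyya coefficient between two probability vectors
#'
#' `BC(p, q) = sum_g sqrt(p_g q_g)`, the overlap of two probability
#' distributions: 1 for identical distributions, 0 for disjoint supports.
#' Zero vectors are allowed and return 0.
#'
#' @param p,q Non-negative vectors, each summing to 1 (or all-zero).
#' @return Similarity in `[0, 1]`.
#' @export
bhattacharyya <- function(p, q) {
  if (min(p) < 0 || min(q) < 0) stop("negative entries in probability vector")
  sum(sqrt(p * q))
}

#' Category-to-observation cost matrix
#'
#' Computes the dissimilarity `M[t, b] = 1 - similarity` between every
#' reference profile and every observation. Observation rows are normalized
#' to probabilities first. Metrics:
#' \describe{
#'   \item{`bc`}{Bhattacharyya coefficient of the probability vectors.}
#'   \item{`cos`}{Cosine similarity of the raw vectors.}
#'   \item{`cos-log1p`}{Cosine similarity after library-size scaling and
#'     log1p transform of both sides.}
#' }
#'
#' @param profiles Genes x categories matrix with unit column sums.
#' @param data Observations x genes matrix (same gene order).
#' @param metric One of `"bc"`, `"cos"`, `"cos-log1p"`.
#' @return Dense categories x observations cost matrix in `[0, 1]`.
#' @export
cost_matrix <- function(profiles, data, metric = c("bc", "cos", "cos-log1p")) {
  metric <- match.arg(metric)
  if (nrow(profiles) != ncol(data) || !all(rownames(profiles) == colnames(data)))
    stop("profiles and data must share an identical gene space")
  zero_obs <- Matrix::rowSums(data) == 0
  if (any(zero_obs)) warning(sum(zero_obs), " all-zero observations get maximal cost")
  if (metric == "bc") {
    x <- .row_normalize(data, 1)
    if (is(x, "sparseMatrix")) { x <- .as_sparse(x); x@x <- sqrt(x@x) } else x <- sqrt(x)
    sim <- .as_dense(x %*% sqrt(profiles))              # obs x cats
  } else {
    if (metric == "cos-log1p") {
      x <- log1p_normalize(data)
      p <- log1p_normalize(t(profiles))                  # cats x genes
    } else {
      x <- data
      p <- t(profiles)
    }
    xn <- sqrt(Matrix::rowSums(x^2)); xn[xn == 0] <- 1
    pn <- sqrt(rowSums(.as_dense(p)^2)); pn[pn == 0] <- 1
    sim <- .as_dense(x %*% t(.as_dense(p)))
    sim <- sim / outer(xn, pn)
  }
  M <- t(1 - sim)                                        # cats x obs
  M[M < 0] <- 0
  M[, zero_obs] <- 1
  rownames(M) <- colnames(profiles)
  colnames(M) <- rownames(data)
  M
}
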