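# Convert a categorical annotation or composition matrix to an
# observations x categories weight matrix aligned to obs ids.
.as_composition <- function(anno, obs_ids) {
  if (is.matrix(anno) || is(anno, "Matrix")) {
    m <- .as_dense(anno)
    if (!is.null(rownames(m))) m <- m[obs_ids, , drop = FALSE]
    return(m)
  }
  labels <- .check_annotation(anno, obs_ids)
  cats <- sort(unique(labels))
  m <- matrix(0, length(obs_ids), length(cats), dimnames = list(obs_ids, cats))
  m[cbind(seq_along(labels), match(labels, cats))] <- 1
  m
}

# Pair-weight sums per (anno, center, bin): S[a, c, k] =
# sum over ordered pairs (i, j), i != j, with d(i, j) in bin k of
# w_center[i, c] * w_anno[j, a]. Shared by co-occurrence and z-scores.
.pair_weight_sums <- function(D, anno, center, bins) {
  nb <- length(bins) - 1
  out <- array(0, dim = c(ncol(anno), ncol(center), nb),
               dimnames = list(colnames(anno), colnames(center), NULL))
  for (k in seq_len(nb)) {
    B <- (D >= bins[k]) & (D < bins[k + 1])
    diag(B) <- FALSE
    out[, , k] <- t(crossprod(center, B %*% anno))   # anno x center
  }
  out
}

#' Spatial co-occurrence of annotations
#'
#' Computes `p(anno | center; x) / p(anno)`: the probability of finding
#' annotation `anno` at distance `x` (binned) from an observation carrying
#' `center`, normalized by the overall probability of `anno`. Compositional
#' weights are supported through bilinear pair weights (products of the
#' center and anno weights); self-pairs are excluded; bins are half-open
#' `[e_k, e_{k+1})`.
#'
#' @param positions n x 2 (or 3) coordinate matrix with observation
#'   rownames, micrometres.
#' @param anno Composition matrix (obs x categories) or categorical vector.
#' @param center Like `anno`; defaults to `anno`.
#' @param bins Increasing distance bin edges.
#' @return List of class `co_occurrence`: `values` (array anno x center x
#'   bin, `NaN` where no pairs support a bin), `counts` (pair weight sums),
#'   `bins`.
#' @export
co_occurrence <- function(positions, anno, center = anno, bins) {
  stopifnot(all(diff(bins) > 0), min(bins) >= 0)
  obs <- rownames(positions)
  if (is.null(obs)) obs <- rownames(positions) <- paste0("obs", seq_len(nrow(positions)))
  A <- .as_composition(anno, obs)
  C <- .as_composition(center, obs)
  D <- as.matrix(dist(positions))
  S <- .pair_weight_sums(D, A, C, bins)
  p_anno <- colSums(A) / nrow(A)
  vals <- S
  for (k in seq_len(dim(S)[3])) {
    tot <- colSums(S[, , k, drop = FALSE][, , 1])      # per center
    for (cc in seq_len(dim(S)[2])) {
      if (tot[cc] > 0) {
        vals[, cc, k] <- (S[, cc, k] / tot[cc]) / p_anno
      } else {
        vals[, cc, k] <- NaN
      }
    }
  }
  structure(list(values = vals, counts = S, bins = bins), class = "co_occurrence")
}

#' Neighborhood enrichment z-scores over distance bins
#'
#' Compares the observed pair-weight sum per (anno, center, bin) to its
#' permutation null, obtained by jointly permuting the annotation rows
#' across observations (positions fixed): `z = (obs - mean) / sd`, with
#' `z = 0` where the permutation sd is zero.
#'
#' @inheritParams co_occurrence
#' @param n_perm Number of permutations (>= 30).
#' @param seed Permutation seed.
#' @return Array anno x center x bin of z-scores.
#' @export
neighborhood_zscores <- function(positions, anno, center = anno, bins,
                                 n_perm = 100, seed = 42) {
  stopifnot(n_perm >= 30)
  obs <- rownames(positions)
  if (is.null(obs)) obs <- rownames(positions) <- paste0("obs", seq_len(nrow(positions)))
  A <- .as_composition(anno, obs)
  C <- .as_composition(center, obs)
  D <- as.matrix(dist(positions))
  S_obs <- .pair_weight_sums(D, A, C, bins)
  sum1 <- array(0, dim = dim(S_obs))
  sum2 <- array(0, dim = dim(S_obs))
  .with_seed(seed, {
    for (p in seq_len(n_perm)) {
      idx <- sample.int(nrow(A))
      Sp <- .pair_weight_sums(D, A[idx, , drop = FALSE], C[idx, , drop = FALSE], bins)
      sum1 <- sum1 + Sp
      sum2 <- sum2 + Sp^2
    }
  })
  mu <- sum1 / n_perm
  sdv <- sqrt(pmax(sum2 / n_perm - mu^2, 0))
  z <- (S_obs - mu) / sdv
  z[sdv == 0] <- 0
  dimnames(z) <- dimnames(S_obs)
  z
}
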