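#' Annotation coordinate: regularized distance to an annotation category
#'
#' For every observation, computes a stable distance to a significant
#' amount of annotation `category`: the cumulative occurrence curve
#' `N_A(d)` (fractional annotation weights counted as fractional
#' occurrences, binned in `bin_width` steps and linearly interpolated) is
#' thresholded at `N_l` to get a regularized radius `d_l`, and the
#' regularization bias is removed with a fictitious homogeneous category
#' `H` (weight 1 per observation) by solving
#' `N_H(d0) = N_H(d_l) - N_l`. For noise-free categorical annotations this
#' reduces to the minimum distance to a `category` observation; for an
#' observation annotated `category` everywhere around it, `d0` is 0.
#' Self-pairs are excluded.
#'
#' @param positions Observations x 2 coordinate matrix.
#' @param anno Composition matrix (obs x categories) or categorical vector.
#' @param category Target category name.
#' @param threshold Occurrence threshold `N_l` (> 0).
#' @param bin_width Histogram bin width in coordinate units.
#' @return Numeric vector of distances `d0` per observation; `Inf` where
#'   the total occurrence of `category` is below the threshold.
#' @export
annotation_coordinate <- function(positions, anno, category, threshold = 1,
                                  bin_width = 1) {
  stopifnot(threshold > 0, bin_width > 0)
  obs <- rownames(positions)
  if (is.null(obs)) obs <- rownames(positions) <- paste0("obs", seq_len(nrow(positions)))
  A <- .as_composition(anno, obs)
  if (!category %in% colnames(A)) stop("unknown category: ", category)
  w <- A[, category]
  D <- as.matrix(dist(positions))
  n <- nrow(D)
  nb <- ceiling(max(D) / bin_width) + 1
  edges <- seq_len(nb) * bin_width
  d0 <- numeric(n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    bin <- pmin(floor(d / bin_width) + 1, nb)
    NA_cum <- cumsum(.bincount(bin, w[-i], nb))
    if (NA_cum[nb] < threshold) { d0[i] <- Inf; next }
    NH_cum <- cumsum(.bincount(bin, rep(1, n - 1), nb))
    d_l <- .interp_inverse(edges, NA_cum, threshold)
    NH_at_dl <- .interp_forward(edges, NH_cum, d_l)
    target <- NH_at_dl - threshold
    d0[i] <- if (target <= 0) 0 else .interp_inverse(edges, NH_cum, target)
  }
  names(d0) <- obs
  d0
}

.bincount <- function(bin, w, nb) {
  out <- numeric(nb)
  agg <- tapply(w, bin, sum)
  out[as.integer(names(agg))] <- agg
  out
}

# piecewise-linear cumulative curve through (0, 0), (edges, cum)
.interp_forward <- function(edges, cum, d) {
  stats::approx(c(0, edges), c(0, cum), xout = d, rule = 2)$y
}

# smallest d with interpolated curve >= value
.interp_inverse <- function(edges, cum, value) {
  x <- c(0, edges)
  y <- c(0, cum)
  k <- which(y >= value)[1]
  if (is.na(k)) return(Inf)
  if (k == 1) return(0)
  if (y[k] == y[k - 1]) return(x[k])
  x[k - 1] + (value - y[k - 1]) / (y[k] - y[k - 1]) * (x[k] - x[k - 1])
}
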