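#' Simulate spatial bead mixtures from annotated reference cells
#'
#' Cells and beads are placed uniformly on the unit square with periodic
#' boundary conditions (a torus); the minimal Euclidean distance between
#' cell `c` and bead `b` enters a Gaussian kernel
#' `w[c, b] = r * exp(-1/2 * (d / l)^2)` with
#' `l = 1/2 * bead_size * sqrt(1 / n_cells)`, so `bead_size = 1` means
#' beads and cells have comparable size and `r` is the capture rate at
#' distance zero. Every count of every cell is allocated multinomially
#' over the beads and an explicit "uncaptured" slot with probabilities
#' `(w[c, 1], ..., w[c, B], 1 - sum_b w[c, b])` (renormalized when the
#' bead weights exceed 1), which conserves counts exactly.
#'
#' Two ground truths are returned per bead: cell-number fractions
#' (normalized kernel weight per type) and count fractions (normalized
#' allocated counts per type).
#'
#' @param ref_counts Reference cells x genes count matrix.
#' @param ref_anno Named type labels per reference cell.
#' @param n_beads Number of beads.
#' @param bead_size Bead diameter relative to the mean cell spacing.
#' @param capture_rate Capture rate `r` at distance zero (default 1).
#' @param seed Integer seed.
#' @return List with `counts` (beads x genes), `cell_fractions` and
#'   `count_fractions` (beads x types, unit row sums where defined),
#'   `positions` (bead coordinates) and `cell_positions`.
#' @export
simulate_mixtures <- function(ref_counts, ref_anno, n_beads,
                              bead_size = 1, capture_rate = 1, seed = 42) {
  stopifnot(bead_size > 0, capture_rate > 0, capture_rate <= 1)
  ref_counts <- .check_counts(ref_counts)
  ref_anno <- .check_annotation(ref_anno, rownames(ref_counts))
  n <- nrow(ref_counts)
  types <- sort(unique(ref_anno))
  l <- 0.5 * bead_size * sqrt(1 / n)
  .with_seed(seed, {
    cell_xy <- cbind(runif(n), runif(n))
    bead_xy <- cbind(runif(n_beads), runif(n_beads))
    # torus minimal distance, vectorized per coordinate
    dx <- abs(outer(cell_xy[, 1], bead_xy[, 1], "-")); dx <- pmin(dx, 1 - dx)
    dy <- abs(outer(cell_xy[, 2], bead_xy[, 2], "-")); dy <- pmin(dy, 1 - dy)
    w <- capture_rate * exp(-0.5 * (dx^2 + dy^2) / l^2)
    w[w < capture_rate * 1e-8] <- 0

    dense <- .as_dense(ref_counts)
    genes <- colnames(ref_counts)
    bead_counts <- matrix(0, n_beads, ncol(ref_counts),
                          dimnames = list(sprintf("bead%05d", seq_len(n_beads)), genes))
    count_frac <- matrix(0, n_beads, length(types),
                         dimnames = list(rownames(bead_counts), types))
    for (c_i in seq_len(n)) {
      wc <- w[c_i, ]
      cand <- which(wc > 0)
      s <- sum(wc[cand])
      probs <- if (s > 1) c(wc[cand] / s, 0) else c(wc[cand], 1 - s)
      ti <- match(ref_anno[c_i], types)
      gz <- which(dense[c_i, ] > 0)
      for (g in gz) {
        alloc <- as.vector(rmultinom(1, dense[c_i, g], probs))
        if (length(cand)) {
          got <- alloc[seq_along(cand)]
          nz <- got > 0
          if (any(nz)) {
            bead_counts[cand[nz], g] <- bead_counts[cand[nz], g] + got[nz]
            count_frac[cand[nz], ti] <- count_frac[cand[nz], ti] + got[nz]
          }
        }
      }
    }
    type_w <- rowsum(w, ref_anno)          # types x beads kernel weight
    cell_frac <- t(type_w)[, types, drop = FALSE]
    cell_frac <- .row_normalize(cell_frac, 1)
    count_frac <- .row_normalize(count_frac, 1)
    list(counts = .as_sparse(bead_counts),
         cell_fractions = cell_frac,
         count_fractions = count_frac,
         positions = bead_xy, cell_positions = cell_xy)
  })
}
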