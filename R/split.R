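#' Split one observation's counts across categories
#'
#' Models the joint molecule distribution `p(g, t)` for a single observation
#' as the reference profile matrix rescaled by free per-gene and
#' per-category factors (a product ansatz), fixed by requiring both
#' marginals: the per-gene marginal must equal the observed counts and the
#' per-category marginal must equal the compositional annotation times the
#' total counts. This is a matrix equivalence scaling problem, solved by
#' iterative proportional fitting (RAS); a small pseudocount makes the
#' problem well posed.
#'
#' @param counts_row Named gene count vector of the observation.
#' @param composition_row Category weights, summing to 1.
#' @param profiles Genes x categories profile matrix (unit column sums).
#' @param pseudocount Added to every profile entry (default
#'   `1e-12 * max(profiles)`).
#' @param max_iter,tol RAS iteration cap and relative marginal tolerance.
#' @return Genes x categories matrix of split counts (rows sum to
#'   `counts_row`, columns to `composition_row * sum(counts_row)`).
#' @export
split_observation <- function(counts_row, composition_row, profiles,
                              pseudocount = NULL, max_iter = 1000, tol = 1e-8) {
  stopifnot(length(counts_row) == nrow(profiles),
            length(composition_row) == ncol(profiles))
  if (is.null(pseudocount)) pseudocount <- 1e-12 * max(profiles)
  total <- sum(counts_row)
  out <- matrix(0, nrow(profiles), ncol(profiles), dimnames = dimnames(profiles))
  if (total == 0) return(out)
  ct <- composition_row * total
  nz <- which(counts_row > 0)
  S <- profiles[nz, , drop = FALSE] + pseudocount
  x <- counts_row[nz]
  a <- rep(1, length(nz))
  b <- rep(1, ncol(S))
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    Sb <- as.vector(S %*% b)
    a <- x / pmax(Sb, .Machine$double.xmin)
    cstar <- b * as.vector(crossprod(S, a))
    err <- max(abs(cstar - ct) / pmax(ct, total * 1e-12))
    b <- b * ct / pmax(cstar, .Machine$double.xmin)
    if (err < tol) { ok <- TRUE; break }
  }
  if (!ok) {
    # final row rescale keeps the gene marginal exact
    warning("RAS did not converge; residual category-marginal mismatch ", signif(err, 3))
  }
  m <- (a * S) * rep(b, each = length(nz))
  m <- m * (x / pmax(rowSums(m), .Machine$double.xmin))
  out[nz, ] <- m
  out
}

#' Split an annotated count matrix into pure per-category counts
#'
#' Applies [split_observation()] independently per observation. With
#' `round = TRUE` every entry is floored and the per-(observation, gene)
#' leftover reads are assigned by multinomial sampling with probabilities
#' proportional to the fractional remainders, so gene totals per observation
#' are conserved exactly and the result is an integer count stack.
#'
#' @param counts Observations x genes count matrix.
#' @param composition Observations x categories matrix, unit row sums.
#' @param profiles Genes x categories profile matrix (unit column sums).
#' @param round Return integer counts (see above)?
#' @param seed Seed for the multinomial rounding; each observation uses a
#'   sub-stream derived from `(seed, observation index)` so results do not
#'   depend on execution order.
#' @param pseudocount,max_iter,tol Passed to [split_observation()].
#' @return Named list (one sparse observations x genes matrix per category).
#' @export
split_counts <- function(counts, composition, profiles, round = FALSE, seed = 42,
                         pseudocount = NULL, max_iter = 1000, tol = 1e-8) {
  counts <- .check_counts(counts)
  if (nrow(counts) != nrow(composition) ||
      !all(rownames(counts) == rownames(composition)))
    stop("counts and composition observations do not match")
  if (!all(colnames(counts) == rownames(profiles)))
    stop("counts and profiles gene spaces do not match")
  cats <- colnames(profiles)
  dense <- .as_dense(counts)
  triplets <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    m <- split_observation(dense[i, ], composition[i, ], profiles,
                           pseudocount = pseudocount, max_iter = max_iter, tol = tol)
    if (round) m <- .round_split(m, dense[i, ], .sub_seed(seed, i))
    nz <- which(m > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      triplets[[i]] <- cbind(obs = i, gene = nz[, 1], cat = nz[, 2],
                             x = m[nz])
    }
  }
  tr <- do.call(rbind, triplets)
  out <- list()
  for (j in seq_along(cats)) {
    sel <- tr[tr[, "cat"] == j, , drop = FALSE]
    out[[cats[j]]] <- Matrix::sparseMatrix(
      i = sel[, "obs"], j = sel[, "gene"], x = sel[, "x"],
      dims = dim(counts), dimnames = dimnames(counts)
    )
  }
  out
}

# Floor a split matrix and redistribute per-gene leftover reads
# multinomially over categories, proportional to fractional remainders.
.round_split <- function(m, counts_row, seed) {
  fl <- floor(m)
  frac <- m - fl
  leftover <- round(counts_row - rowSums(fl))
  todo <- which(leftover > 0)
  if (length(todo)) {
    .with_seed(seed, {
      for (g in todo) {
        p <- frac[g, ]
        if (sum(p) <= 0) p <- rep(1, ncol(m))
        fl[g, ] <- fl[g, ] + as.vector(rmultinom(1, leftover[g], p))
      }
    })
  }
  fl
}
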