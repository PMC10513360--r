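# Symmetric binary k-nearest-neighbor adjacency from a feature matrix,
# restricted to the given candidate index sets (list of row index vectors).
.knn_adjacency <- function(x, k, groups = NULL) {
  n <- nrow(x)
  if (is.null(groups)) groups <- list(seq_len(n))
  i <- integer(0); j <- integer(0)
  for (g in groups) {
    if (length(g) < 2) next
    D <- as.matrix(dist(x[g, , drop = FALSE]))
    diag(D) <- Inf
    kk <- min(k, length(g) - 1)
    for (a in seq_along(g)) {
      nb <- order(D[a, ])[seq_len(kk)]
      i <- c(i, rep(g[a], kk))
      j <- c(j, g[nb])
    }
  }
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  A@x[] <- 1   # symmetrized union, binary
  A
}

#' Define spatial regions jointly from annotation and position space
#'
#' Builds one k-nearest-neighbor graph in expression/annotation space
#' (across all samples) and one in position space (within samples),
#' combines them as `(1 - position_weight) * A_feat + position_weight *
#' A_pos` after rescaling the feature adjacency to the total weight of the
#' position adjacency, up-weights cross-sample feature edges by the ratio
#' of within- to cross-sample feature edge weight (so samples stay
#' connected), and clusters the combined graph by the Leiden algorithm.
#' Region labels are thereby consistent across samples.
#'
#' @param x Observations x features matrix (annotation composition or
#'   expression).
#' @param positions Observations x 2 coordinate matrix.
#' @param sample_labels Sample id per observation.
#' @param position_weight Weight of the position graph in `[0, 1]`.
#' @param k_neighbors Neighbors per graph.
#' @param resolution Leiden resolution (modularity objective).
#' @param seed Clustering seed.
#' @return Integer region label per observation.
#' @export
define_regions <- function(x, positions, sample_labels = NULL,
                           position_weight = 0.5, k_neighbors = 10,
                           resolution = 1, seed = 42) {
  stopifnot(position_weight >= 0, position_weight <= 1, k_neighbors >= 1)
  x <- .as_dense(x)
  n <- nrow(x)
  if (is.null(sample_labels)) sample_labels <- rep("s1", n)
  samples <- split(seq_len(n), sample_labels)

  A_feat <- .knn_adjacency(x, k_neighbors)
  A_pos <- .knn_adjacency(positions, k_neighbors, groups = samples)

  if (length(samples) > 1) {
    same <- outer(sample_labels, sample_labels, "==")
    tr <- Matrix::summary(.as_sparse(A_feat))
    cross <- !same[cbind(tr$i, tr$j)]
    w_in <- sum(tr$x[!cross])
    w_cross <- sum(tr$x[cross])
    if (w_cross > 0 && w_in > 0) {
      tr$x[cross] <- tr$x[cross] * (w_in / w_cross)
      A_feat <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
    }
  }
  tot_pos <- sum(A_pos)
  tot_feat <- sum(A_feat)
  if (tot_feat > 0 && tot_pos > 0) A_feat <- A_feat * (tot_pos / tot_feat)
  A <- (1 - position_weight) * A_feat + position_weight * A_pos

  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- .with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 5)$membership
  })
  as.integer(memb)
}
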