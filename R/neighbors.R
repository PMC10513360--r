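#' Sparse Euclidean distance matrix within a cutoff
#'
#' Computes all and only the point pairs at Euclidean distance
#' `<= max_distance`, using spatial hashing on a grid of cell size
#' `max_distance` so only points in adjacent cells are compared.
#'
#' @param points Numeric n x 2 coordinate matrix.
#' @param max_distance Neighborhood cutoff (same units as `points`).
#' @return Sparse symmetric `dgCMatrix` of distances; absent entries mean
#'   "farther than the cutoff" (exact-zero distances between distinct
#'   points are stored explicitly).
#' @export
sparse_spatial_distances <- function(points, max_distance) {
  stopifnot(max_distance > 0, ncol(points) == 2)
  n <- nrow(points)
  h <- max_distance
  cx <- floor(points[, 1] / h)
  cy <- floor(points[, 2] / h)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  cell_xy <- do.call(rbind, lapply(strsplit(names(cells), " "), as.numeric))
  cell_key <- names(cells)
  offsets <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  ii <- list(); jj <- list(); xx <- list(); k <- 0
  for (ci in seq_along(cells)) {
    a <- cells[[ci]]
    for (o in seq_len(nrow(offsets))) {
      if (o == 1) {
        b <- a
      } else {
        nb <- paste(cell_xy[ci, 1] + offsets[o, 1], cell_xy[ci, 2] + offsets[o, 2])
        pos <- match(nb, cell_key)
        if (is.na(pos)) next
        b <- cells[[pos]]
      }
      dx <- outer(points[a, 1], points[b, 1], "-")
      dy <- outer(points[a, 2], points[b, 2], "-")
      d <- sqrt(dx^2 + dy^2)
      sel <- which(d <= max_distance, arr.ind = TRUE)
      if (o == 1) sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]
      if (nrow(sel)) {
        k <- k + 1
        ii[[k]] <- a[sel[, 1]]
        jj[[k]] <- b[sel[, 2]]
        xx[[k]] <- d[sel]
      }
    }
  }
  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
  # encode exact-zero distances as a negligible positive value so they are
  # retained by the sparse representation
  x[x == 0] <- .Machine$double.xmin
  m <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(x, x), dims = c(n, n),
                            dimnames = list(rownames(points), rownames(points)))
  .as_sparse(m)
}
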