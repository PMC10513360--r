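#' Segmentation configuration
#'
#' @param distance_scale Gaussian affinity kernel width in micrometres
#'   (subcellular; default 3).
#' @param max_distance Neighbor cutoff for the sparse distance computation
#'   (default `4 * distance_scale`).
#' @param annotation_distance `"infinite"` (molecules of different
#'   categories are never joined), `"auto"` (category-pair distance
#'   `(1 - BC)` between expression profiles, scaled by `distance_scale`,
#'   added in quadrature), or a symmetric categories x categories matrix of
#'   distances in micrometres.
#' @param min_molecules Minimum molecules per accepted segment (default 20).
#' @param supernode_size Grid spacing used to pre-aggregate molecules into
#'   supernodes before spectral clustering (default 20, i.e. twice the
#'   default molecule bin size).
#' @param seed Seed for the empirical homogeneous-bulk cut calibration.
#' @return List of class `segmentation_config`.
#' @export
segmentation_config <- function(distance_scale = 3,
                                max_distance = 4 * distance_scale,
                                annotation_distance = "infinite",
                                min_molecules = 20, supernode_size = 20,
                                seed = 42) {
  stopifnot(distance_scale > 0, max_distance > 0, min_molecules >= 1)
  structure(list(distance_scale = distance_scale, max_distance = max_distance,
                 annotation_distance = annotation_distance,
                 min_molecules = min_molecules, supernode_size = supernode_size,
                 seed = seed),
            class = "segmentation_config")
}

#' Image-free segmentation of annotated molecules
#'
#' Builds a sparse affinity graph on the molecules, combining spatial
#' distance and an annotation distance in quadrature
#' (`d_total = sqrt(d_spatial^2 + d_annotation^2)`), with Gaussian affinity
#' `exp(-d_total^2 / (2 * distance_scale^2))`. With the default infinite
#' annotation distance, molecules of different categories get zero
#' affinity, so no segment mixes categories. Molecules are pre-aggregated
#' into grid supernodes, and each connected component is recursively
#' bipartitioned by a normalized cut (spectral relaxation with a sweep over
#' the Fiedler vector). A proposed cut is accepted only when both parts
#' contain at least `min_molecules` molecules and its normalized-cut cost is
#' below the expected cost of cutting a homogeneous bulk point set of the
#' same size and density (calibrated empirically by Monte-Carlo on uniform
#' point sets and cached).
#'
#' @param mol Molecule table with `x`, `y`, `gene` and `category` columns.
#' @param config A [segmentation_config()].
#' @param profiles Optional genes x categories profiles, required for
#'   `annotation_distance = "auto"`.
#' @return `mol` with an integer `segment_id` column and a logical
#'   `segment_small` flag for molecules in segments below `min_molecules`.
#' @export
segment_molecules <- function(mol, config = segmentation_config(), profiles = NULL) {
  if (is.null(mol$category)) stop("molecules must carry a category column")
  n <- nrow(mol)
  pts <- cbind(mol$x, mol$y)
  cats <- sort(unique(mol$category))
  ci <- match(mol$category, cats)

  ann_d <- .annotation_distance_matrix(config, cats, profiles)

  # supernodes: occupied grid cells, kept pure in category when the
  # annotation distance is infinite
  gx <- floor(mol$x / config$supernode_size)
  gy <- floor(mol$y / config$supernode_size)
  sn_key <- if (is.null(ann_d)) paste(gx, gy, ci) else paste(gx, gy)
  sn_ids <- unique(sn_key)
  sn <- match(sn_key, sn_ids)
  n_sn <- length(sn_ids)

  D <- sparse_spatial_distances(pts, config$max_distance)
  T_ <- .as_sparse(Matrix::triu(D))
  trip <- Matrix::summary(T_)
  i <- trip$i; j <- trip$j; d <- trip$x
  d[d <= .Machine$double.xmin] <- 0
  if (is.null(ann_d)) {
    keep <- ci[i] == ci[j]
    i <- i[keep]; j <- j[keep]; d <- d[keep]
  } else {
    d <- sqrt(d^2 + ann_d[cbind(ci[i], ci[j])]^2)
  }
  w <- exp(-0.5 * (d / config$distance_scale)^2)

  # aggregate molecule affinities onto the supernode graph (diagonal keeps
  # internal association)
  W <- Matrix::sparseMatrix(i = c(sn[i], sn[j]), j = c(sn[j], sn[i]),
                            x = c(w, w) / 2, dims = c(n_sn, n_sn))
  W <- W + Matrix::t(W)
  sn_mol <- tabulate(sn, n_sn)

  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  seg_of_sn <- integer(n_sn)
  next_id <- 0
  calib <- new.env(parent = emptyenv())
  dens <- n / max(diff(range(mol$x)) * diff(range(mol$y)), 1e-9)
  for (cmp in unique(comp)) {
    nodes <- which(comp == cmp)
    parts <- .recursive_ncut(W, nodes, sn_mol, config, dens, calib)
    for (p in parts) {
      next_id <- next_id + 1
      seg_of_sn[p] <- next_id
    }
  }
  mol$segment_id <- seg_of_sn[sn]
  seg_sizes <- tabulate(mol$segment_id, next_id)
  mol$segment_small <- seg_sizes[mol$segment_id] < config$min_molecules
  mol
}

.annotation_distance_matrix <- function(config, cats, profiles) {
  ad <- config$annotation_distance
  if (is.character(ad) && ad == "infinite") return(NULL)
  if (is.character(ad) && ad == "auto") {
    if (is.null(profiles)) stop("annotation_distance 'auto' needs profiles")
    p <- profiles[, cats, drop = FALSE]
    bc <- crossprod(sqrt(p))
    return((1 - bc) * config$distance_scale)
  }
  .as_dense(ad)[cats, cats]
}

# Recursive binary normalized cuts on the supernode graph.
.recursive_ncut <- function(W, nodes, sn_mol, config, dens, calib) {
  n_mol <- sum(sn_mol[nodes])
  if (length(nodes) < 2 || n_mol < 2 * config$min_molecules) return(list(nodes))
  cut <- .best_ncut(W[nodes, nodes, drop = FALSE])
  if (is.null(cut)) return(list(nodes))
  left <- nodes[cut$left]
  right <- nodes[cut$right]
  if (sum(sn_mol[left]) < config$min_molecules ||
      sum(sn_mol[right]) < config$min_molecules) return(list(nodes))
  ref <- .homogeneous_ncut_reference(n_mol, dens, config, calib)
  if (!is.finite(ref) || cut$value >= ref) return(list(nodes))
  c(.recursive_ncut(W, left, sn_mol, config, dens, calib),
    .recursive_ncut(W, right, sn_mol, config, dens, calib))
}

# Spectral two-way normalized cut: Fiedler vector of the normalized
# Laplacian, then a sweep over its order to minimize the ncut objective.
.best_ncut <- function(W) {
  n <- nrow(W)
  if (n < 2) return(NULL)
  Wd <- .as_dense(W)
  deg <- rowSums(Wd)
  if (any(deg <= 0)) deg[deg <= 0] <- min(deg[deg > 0], 1e-12)
  s <- 1 / sqrt(deg)
  L <- diag(n) - (s * Wd) * rep(s, each = n)
  ev <- eigen(L, symmetric = TRUE)
  f <- ev$vectors[, n - 1] * s
  ord <- order(f)
  # sweep: evaluate ncut for every prefix split of the sorted Fiedler vector
  Wo <- Wd[ord, ord, drop = FALSE]
  dego <- deg[ord]
  total <- sum(dego)
  best_val <- Inf
  best_k <- NULL
  cut_w <- 0
  assoc <- 0
  row_in <- rep(0, n)  # affinity of each node to the current left set
  for (k in seq_len(n - 1)) {
    cut_w <- cut_w + sum(Wo[k, ]) - 2 * row_in[k] - Wo[k, k]
    row_in <- row_in + Wo[, k]
    assoc <- assoc + dego[k]
    a2 <- total - assoc
    if (assoc > 0 && a2 > 0) {
      val <- cut_w / assoc + cut_w / a2
      if (val < best_val) { best_val <- val; best_k <- k }
    }
  }
  if (is.null(best_k)) return(NULL)
  left_ord <- ord[seq_len(best_k)]
  list(left = left_ord, right = setdiff(seq_len(n), left_ord), value = best_val)
}

# Expected normalized-cut cost for a homogeneous uniform point set of the
# same size and density, estimated by Monte-Carlo and cached.
.homogeneous_ncut_reference <- function(n_mol, dens, config, calib) {
  n_sim <- min(max(n_mol, 10), 600)
  key <- paste0(round(log2(n_sim), 1), "_", signif(dens * config$distance_scale^2, 2))
  if (!is.null(calib[[key]])) return(calib[[key]])
  side <- sqrt(n_sim / dens)
  vals <- numeric(3)
  .with_seed(.sub_seed(config$seed, n_sim), {
    for (r in 1:3) {
      pts <- cbind(runif(n_sim, 0, side), runif(n_sim, 0, side))
      D <- sparse_spatial_distances(pts, config$max_distance)
      S <- .as_sparse(D)
      S@x <- exp(-0.5 * (S@x / config$distance_scale)^2)
      cut <- tryCatch(.best_ncut(S), error = function(e) NULL)
      vals[r] <- if (is.null(cut)) Inf else cut$value
    }
  })
  ref <- mean(vals[is.finite(vals)])
  if (!is.finite(ref)) ref <- Inf
  calib[[key]] <- ref
  ref
}
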