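# k-means++ seeding: spread initial centers with probability proportional
# to squared distance from the nearest chosen center.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, x[centers[1], ], "-")^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
      centers[j] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j], ], "-")^2))
    }
  }
  x[centers, , drop = FALSE]
}

.kmeans_pp <- function(x, k, nstart = 3) {
  uni <- unique(x)
  k <- min(k, nrow(uni))
  if (k <= 1) return(rep(1L, nrow(x)))
  if (k == nrow(uni)) {
    # every distinct point is its own center
    key <- apply(x, 1, paste, collapse = "\r")
    return(match(key, unique(key)))
  }
  best <- NULL
  for (s in seq_len(nstart)) {
    init <- .kmeanspp_centers(x, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = init, iter.max = 50)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  if (is.null(best)) return(rep(1L, nrow(x)))
  best$cluster
}

#' Multi-center reference profiles by within-category subclustering
#'
#' To capture within-category heterogeneity while keeping the speed of
#' profile-based transport, the observations of each category are
#' subclustered by k-means (k-means++ seeding) on log1p-normalized
#' expression, and one normalized mean raw-count profile is kept per
#' subcluster. Downstream annotation runs against the sub-profiles and is
#' summed back to the parent categories via the attached `parent_map`.
#'
#' @param counts Reference observations x genes count matrix.
#' @param anno Named category labels per observation.
#' @param k Subclusters per category (clamped to the category size).
#' @param seed Integer seed for the clustering.
#' @return Genes x sub-categories profile matrix (unit column sums) with
#'   attributes `parent_map` (named character: sub-category -> category) and
#'   `sizes` (observations per sub-category).
#' @export
multi_center_split <- function(counts, anno, k, seed = 42) {
  stopifnot(k >= 1)
  counts <- .check_counts(counts)
  anno <- .check_annotation(anno, rownames(counts))
  if (k == 1) {
    prof <- mean_profiles(counts, anno)
    attr(prof, "parent_map") <- setNames(colnames(prof), colnames(prof))
    attr(prof, "sizes") <- setNames(as.vector(table(anno)[colnames(prof)]), colnames(prof))
    return(prof)
  }
  norm <- log1p_normalize(counts)
  cats <- sort(unique(anno))
  sub_labels <- character(length(anno))
  .with_seed(seed, {
    for (cat in cats) {
      idx <- which(anno == cat)
      cl <- .kmeans_pp(.as_dense(norm[idx, , drop = FALSE]), k)
      sub_labels[idx] <- paste0(cat, "#", cl)
    }
  })
  names(sub_labels) <- rownames(counts)
  prof <- mean_profiles(counts, sub_labels)
  attr(prof, "parent_map") <- setNames(sub("#[0-9]+$", "", colnames(prof)), colnames(prof))
  attr(prof, "sizes") <- setNames(as.vector(table(sub_labels)[colnames(prof)]), colnames(prof))
  prof
}
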