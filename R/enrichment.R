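#' Enrichment of composition between groups across ensemble units
#'
#' Single cells or beads within one sample are not independent, so testing
#' across observations inflates significance. Instead, the ensemble units
#' are whole samples, or spatial sub-blocks of samples when
#' `n_splits_per_axis` is given (each sample is cut into an equal-width
#' grid along its coordinate axes; increasing the number of splits
#' interpolates toward treating observations as independent). Per unit the
#' mean composition is taken; per category a two-sided Welch t-test
#' compares the two groups across units, with Benjamini-Hochberg
#' correction over categories.
#'
#' @param compositions Observations x categories matrix (unit row sums).
#' @param group_labels Two-level group label per observation.
#' @param sample_labels Sample id per observation.
#' @param n_splits_per_axis Optional integer: sub-blocks per coordinate
#'   axis within each sample (requires `positions`).
#' @param positions Observations x 2 coordinates, needed for splitting.
#' @return `data.frame` with category, per-group unit counts and means,
#'   `effect` (log2 ratio of group means), `p` and BH-adjusted `q`.
#' @export
enrichment_test <- function(compositions, group_labels, sample_labels,
                            n_splits_per_axis = NULL, positions = NULL) {
  compositions <- .as_dense(compositions)
  groups <- unique(group_labels)
  if (length(groups) != 2) stop("exactly two groups are required")
  unit <- as.character(sample_labels)
  if (!is.null(n_splits_per_axis)) {
    if (is.null(positions)) stop("positions needed for spatial splitting")
    for (s in unique(sample_labels)) {
      idx <- which(sample_labels == s)
      for (ax in 1:2) {
        r <- range(positions[idx, ax])
        cutp <- findInterval(positions[idx, ax],
                             seq(r[1], r[2], length.out = n_splits_per_axis + 1),
                             rightmost.closed = TRUE)
        unit[idx] <- paste(unit[idx], cutp, sep = "_")
      }
    }
  }
  units <- unique(unit)
  unit_group <- vapply(units, function(u) {
    g <- unique(group_labels[unit == u])
    if (length(g) > 1) stop("ensemble unit spans both groups: ", u)
    as.character(g)
  }, character(1))
  unit_means <- t(vapply(units, function(u) {
    colMeans(compositions[unit == u, , drop = FALSE])
  }, numeric(ncol(compositions))))
  colnames(unit_means) <- colnames(compositions)

  n1 <- sum(unit_group == groups[1])
  n2 <- sum(unit_group == groups[2])
  if (n1 < 2 || n2 < 2)
    warning("a group has fewer than 2 ensemble units; p-values are NaN")
  res <- data.frame(category = colnames(compositions),
                    n_units_1 = n1, n_units_2 = n2,
                    mean_1 = NA_real_, mean_2 = NA_real_,
                    effect = NA_real_, p = NA_real_)
  for (k in seq_len(ncol(compositions))) {
    x1 <- unit_means[unit_group == groups[1], k]
    x2 <- unit_means[unit_group == groups[2], k]
    res$mean_1[k] <- mean(x1)
    res$mean_2[k] <- mean(x2)
    res$effect[k] <- log2((mean(x1) + 1e-12) / (mean(x2) + 1e-12))
    if (n1 >= 2 && n2 >= 2 && (sd(x1) > 0 || sd(x2) > 0)) {
      res$p[k] <- tryCatch(t.test(x1, x2)$p.value, error = function(e) NaN)
    } else if (n1 >= 2 && n2 >= 2) {
      res$p[k] <- 1  # identical constant compositions: no evidence
    } else {
      res$p[k] <- NaN
    }
  }
  res$q <- p.adjust(res$p, method = "BH")
  res
}
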