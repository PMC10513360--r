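#' Simulate a clonal fate-bias dataset
#'
#' Emulates clone-barcoded differentiation experiments: distinct late
#' (differentiated) fate profiles are generated with
#' [simulate_scrnaseq()]; every clone draws a fate bias (Dirichlet, or
#' one-hot when `bias = "onehot"`); late cells of a clone sample their
#' fate from the clone bias and express the pure fate profile; early
#' (progenitor) cells of the clone express Poisson counts around the
#' bias-weighted convex combination of the fate mean profiles. The truth
#' is the clone bias per early cell (rows sum to 1).
#'
#' @param n_fates Number of terminal fates (>= 2).
#' @param n_clones Number of clones.
#' @param cells_per_clone Early and late cells per clone (length-2 vector
#'   or scalar used for both).
#' @param bias `"dirichlet"` (concentration `alpha`) or `"onehot"`.
#' @param alpha Dirichlet concentration (default 1).
#' @param n_genes,de_loc,lib_loc,lib_scale Passed to the expression model.
#' @param seed Integer seed.
#' @return List with `late` (`counts`, `fates`), `early` (`counts`,
#'   `clone`), `bias` (early cells x fates truth matrix).
#' @export
simulate_fate_data <- function(n_fates = 4, n_clones = 50, cells_per_clone = c(4, 8),
                               bias = c("dirichlet", "onehot"), alpha = 1,
                               n_genes = 2000, de_loc = 3,
                               lib_loc = 7.64, lib_scale = 0.78, seed = 42) {
  bias <- match.arg(bias)
  stopifnot(n_fates >= 2)
  if (length(cells_per_clone) == 1) cells_per_clone <- rep(cells_per_clone, 2)
  base <- simulate_scrnaseq(n_cells = n_fates, n_genes = n_genes,
                            n_types = n_fates, de_loc = de_loc,
                            lib_loc = lib_loc, lib_scale = lib_scale,
                            seed = .sub_seed(seed, 1))
  profiles <- base$profiles
  fates <- colnames(profiles)
  .with_seed(.sub_seed(seed, 2), {
    clone_bias <- if (bias == "onehot") {
      b <- matrix(0, n_clones, n_fates)
      b[cbind(seq_len(n_clones), rep_len(seq_len(n_fates), n_clones))] <- 1
      b
    } else {
      g <- matrix(rgamma(n_clones * n_fates, shape = alpha), n_clones)
      g / rowSums(g)
    }
    colnames(clone_bias) <- fates

    n_early <- n_clones * cells_per_clone[1]
    n_late <- n_clones * cells_per_clone[2]
    clone_early <- rep(seq_len(n_clones), each = cells_per_clone[1])
    clone_late <- rep(seq_len(n_clones), each = cells_per_clone[2])

    late_fate <- vapply(clone_late, function(cl)
      sample.int(n_fates, 1, prob = clone_bias[cl, ]), integer(1))
    lib_late <- rlnorm(n_late, lib_loc, lib_scale)
    late_mu <- lib_late * t(profiles[, late_fate, drop = FALSE])
    late_counts <- .as_sparse(matrix(rpois(length(late_mu), late_mu), nrow = n_late))
    dimnames(late_counts) <- list(sprintf("late%05d", seq_len(n_late)),
                                  rownames(profiles))

    lib_early <- rlnorm(n_early, lib_loc, lib_scale)
    early_profiles <- profiles %*% t(clone_bias[clone_early, , drop = FALSE])
    early_mu <- lib_early * t(early_profiles)
    early_counts <- .as_sparse(matrix(rpois(length(early_mu), early_mu), nrow = n_early))
    dimnames(early_counts) <- list(sprintf("early%05d", seq_len(n_early)),
                                   rownames(profiles))

    truth <- clone_bias[clone_early, , drop = FALSE]
    rownames(truth) <- rownames(early_counts)
    list(late = list(counts = late_counts,
                     fates = setNames(fates[late_fate], rownames(late_counts))),
         early = list(counts = early_counts,
                      clone = setNames(clone_early, rownames(early_counts))),
         bias = truth)
  })
}
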