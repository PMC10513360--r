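#' Simulate single-cell RNA-seq counts with distinct cell types
#'
#' Splatter-style generative model: per-gene base means from a gamma
#' distribution (with rare expression-outlier genes), per-type
#' differential-expression factors applied to a random gene subset,
#' log-normal library sizes, a per-entry biological-coefficient-of-
#' variation (BCV) noise stage that produces the final mean matrix
#' `lambda[n, g]`, and Poisson sampling of counts. The default
#' hyperparameters emulate droplet scRNA-seq at desk scale and are the
#' package's declared study conditions (see the methods vignette);
#' `de_loc = 5` gives strongly separated cell types.
#'
#' @param n_cells,n_genes,n_types Problem size (default 1000 x 3000 x 10).
#' @param de_prob Probability a gene is differentially expressed in a type.
#' @param de_loc,de_scale Log-normal meanlog/sdlog of DE factors.
#' @param de_downprob Probability a DE factor is inverted (down-regulation).
#' @param mean_shape,mean_rate Gamma parameters of gene base means.
#' @param out_prob,out_loc,out_scale Expression-outlier gene probability
#'   and log-normal factor applied to the median base mean.
#' @param lib_loc,lib_scale Log-normal meanlog/sdlog of library sizes.
#' @param bcv_common,bcv_dof BCV dispersion and degrees of freedom.
#' @param return_means Also return the dense mean matrix `lambda` (needed
#'   for the ambient-RNA model; costs `n_cells * n_genes` doubles).
#' @param seed Integer seed.
#' @return List with `counts` (sparse cells x genes), `types` (named
#'   labels), `profiles` (genes x types normalized true mean profiles) and,
#'   if requested, `lambda`.
#' @export
simulate_scrnaseq <- function(n_cells = 1000, n_genes = 3000, n_types = 10,
                              de_prob = 0.025, de_loc = 5, de_scale = 1,
                              de_downprob = 0,
                              mean_shape = 0.34, mean_rate = 7.68,
                              out_prob = 0.00286, out_loc = 4, out_scale = 0.5,
                              lib_loc = 7.64, lib_scale = 0.78,
                              bcv_common = 0.448, bcv_dof = 22.087,
                              return_means = FALSE, seed = 42) {
  stopifnot(n_types >= 1, n_cells >= n_types)
  .with_seed(seed, {
    base <- rgamma(n_genes, shape = mean_shape, rate = mean_rate)
    outlier <- runif(n_genes) < out_prob
    if (any(outlier))
      base[outlier] <- stats::median(base) * rlnorm(sum(outlier), out_loc, out_scale)

    type_mean <- matrix(base, n_genes, n_types)
    for (t in seq_len(n_types)) {
      de <- runif(n_genes) < de_prob
      fac <- rlnorm(sum(de), de_loc, de_scale)
      down <- runif(sum(de)) < de_downprob
      fac[down] <- 1 / fac[down]
      type_mean[de, t] <- type_mean[de, t] * fac
    }
    profiles <- sweep(type_mean, 2, colSums(type_mean), "/")
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    type_ids <- sprintf("type%02d", seq_len(n_types))
    dimnames(profiles) <- list(gene_ids, type_ids)

    types <- type_ids[rep_len(seq_len(n_types), n_cells)]
    libsize <- rlnorm(n_cells, lib_loc, lib_scale)
    gene_chisq <- stats::rchisq(n_genes, df = bcv_dof)

    cell_ids <- sprintf("c%05d", seq_len(n_cells))
    chunks <- split(seq_len(n_cells), ceiling(seq_len(n_cells) / 512))
    blocks <- vector("list", length(chunks))
    lambda <- if (return_means) matrix(0, n_cells, n_genes,
                                       dimnames = list(cell_ids, gene_ids)) else NULL
    for (ci in seq_along(chunks)) {
      idx <- chunks[[ci]]
      mu0 <- libsize[idx] * t(profiles[, match(types[idx], type_ids), drop = FALSE])
      bcv <- sweep(bcv_common + 1 / sqrt(pmax(mu0, 1e-12)), 2,
                   sqrt(bcv_dof / gene_chisq), "*")
      lam <- matrix(rgamma(length(mu0), shape = 1 / bcv^2, scale = mu0 * bcv^2),
                    nrow = length(idx))
      lam[mu0 == 0] <- 0
      if (return_means) lambda[idx, ] <- lam
      cnt <- matrix(rpois(length(lam), lam), nrow = length(idx))
      blocks[[ci]] <- .as_sparse(cnt)
    }
    counts <- do.call(rbind, blocks)
    dimnames(counts) <- list(cell_ids, gene_ids)
    names(types) <- cell_ids
    out <- list(counts = counts, types = types, profiles = profiles)
    if (return_means) out$lambda <- lambda
    out
  })
}

#' Enhance dropout by shifting the fitted detection sigmoid
#'
#' Fits a logistic curve `p0(x) = 1 / (1 + exp(shape * (x - mid)))` through
#' the genes' log mean count `x` and their fraction of cells with zero
#' reads, then evaluates the curve with every gene's log mean shifted by
#' `midpoint_shift` (a negative shift treats each gene as if it were
#' expressed lower, i.e. enhances dropout). The extra dropout probability
#' `q_g = clip((p1 - p0) / (1 - p0), 0, 1)` is applied by binomial
#' thinning of the observed counts, entry-wise with probability `1 - q_g`.
#'
#' @param counts Cells x genes count matrix.
#' @param midpoint_shift Sigmoid shift; 0 leaves counts unchanged, -1 is a
#'   mild enhancement.
#' @param seed Seed for the binomial thinning.
#' @return List with `counts` (thinned, same shape), `q` (per-gene extra
#'   dropout probability) and `fit` (shape, midpoint).
#' @export
apply_dropout <- function(counts, midpoint_shift = -1, seed = 42) {
  mean_g <- Matrix::colMeans(counts)
  zero_g <- 1 - Matrix::colMeans(counts > 0)
  use <- mean_g > 0
  x <- log(mean_g[use])
  y <- zero_g[use]
  fit <- optim(c(shape = 1, mid = stats::median(x)), function(par) {
    p <- 1 / (1 + exp(par[1] * (x - par[2])))
    sum((p - y)^2)
  }, method = "Nelder-Mead")$par
  p_at <- function(lx) 1 / (1 + exp(fit[1] * (lx - fit[2])))
  p0 <- p_at(x)
  p1 <- p_at(x + midpoint_shift)
  q <- rep(0, length(mean_g))
  q[use] <- pmin(pmax((p1 - p0) / pmax(1 - p0, 1e-12), 0), 1)
  names(q) <- colnames(counts)

  out <- .as_sparse(counts)
  .with_seed(seed, {
    trip <- Matrix::summary(out)
    keepp <- 1 - q[trip$j]
    trip$x <- rbinom(nrow(trip), size = round(trip$x), prob = keepp)
    out <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                                dims = dim(counts), dimnames = dimnames(counts))
  })
  list(counts = Matrix::drop0(out), q = q,
       fit = c(shape = unname(fit[1]), midpoint = unname(fit[2])))
}

#' Add ambient RNA contamination to a mean expression matrix
#'
#' Implements a droplet contamination model: each droplet receives, on top
#' of its cell's mean expression `lambda[n, g]`, an ambient pseudobulk
#' contribution `d_drop[n] * chi_a[g]`, where `chi_a` is the normalized
#' average of `lambda` over cells and the per-droplet ambient size
#' `d_drop ~ logNormal(d_mu + log(f_drop), d_sigma)` reuses the cell-size
#' log-normal. Counts are sampled from a negative binomial with mean
#' `mu = lambda + d_drop * chi_a` and variance `mu + phi * mu^2`. With
#' `f_drop = 0` this is the uncontaminated negative-binomial counterpart
#' (used for the matched reference).
#'
#' @param lambda Dense cells x genes matrix of true means.
#' @param f_drop Ambient fraction (0 = none).
#' @param d_mu,d_sigma Cell-size log-normal parameters (defaults match
#'   [simulate_scrnaseq()]).
#' @param phi Negative-binomial dispersion (default 0.3).
#' @param seed Integer seed.
#' @return Sparse cells x genes count matrix.
#' @export
add_ambient <- function(lambda, f_drop, d_mu = 7.64, d_sigma = 0.78,
                        phi = 0.3, seed = 42) {
  stopifnot(f_drop >= 0, phi > 0)
  lambda <- .as_dense(lambda)
  chi_a <- colMeans(lambda)
  chi_a <- chi_a / sum(chi_a)
  .with_seed(seed, {
    d_drop <- if (f_drop > 0)
      rlnorm(nrow(lambda), d_mu + log(f_drop), d_sigma) else rep(0, nrow(lambda))
    mu <- lambda + outer(d_drop, chi_a)
    cnt <- matrix(rnbinom(length(mu), size = 1 / phi, mu = mu), nrow = nrow(lambda))
    dimnames(cnt) <- dimnames(lambda)
    .as_sparse(cnt)
  })
}
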