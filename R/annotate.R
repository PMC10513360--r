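# Single entropic OT pass: data -> probability composition over profile columns.
# Zero-count observations are excluded from the solve and receive the prior.
.ot_core <- function(data, profiles, prior_t = NULL,
                     epsilon = 0.005, lambda = 0.1, metric = "bc",
                     max_iter = 10000, tol = 1e-8) {
  if (is.null(prior_t)) prior_t <- rep(1, ncol(profiles))
  prior_t <- prior_t / sum(prior_t)
  rho_b <- Matrix::rowSums(data)
  comp <- matrix(rep(prior_t, each = nrow(data)), nrow = nrow(data),
                 dimnames = list(rownames(data), colnames(profiles)))
  live <- rho_b > 0
  if (any(live)) {
    M <- cost_matrix(profiles, data[live, , drop = FALSE], metric = metric)
    plan <- sinkhorn_semi_unbalanced(M, c_b = rho_b[live],
                                     c_t = prior_t * sum(rho_b[live]),
                                     epsilon = epsilon, lambda = lambda,
                                     max_iter = max_iter, tol = tol)
    comp[live, ] <- plan_to_composition(plan)
  }
  comp
}

#' Bisectioned (recursive residual) annotation
#'
#' Adapts an annotation method that is biased toward dominant categories to
#' additive mixtures: in each of `bisections` steps only the fraction
#' `phi = (divisor - 1) / divisor` of the current annotation is committed,
#' the corresponding reconstruction (`profiles %*% annotation`, scaled to
#' the removed counts) is subtracted from the residual (clipped at zero),
#' and the next step annotates the residual. The final pass commits the
#' remaining fraction, so the accumulated fractions sum to 1 per
#' observation exactly.
#'
#' @param core_fn Function `(counts) -> obs x categories` probability
#'   composition over the columns of `profiles`.
#' @param data Observations x genes count matrix.
#' @param profiles Genes x categories profiles (unit column sums) used for
#'   the reconstruction step.
#' @param bisections Number of partial steps (0 = a single plain call).
#' @param divisor Per-step divisor; values below 3 can introduce sizable
#'   reconstruction artifacts.
#' @return Observations x categories matrix with unit row sums.
#' @export
bisection_annotate <- function(core_fn, data, profiles, bisections = 4, divisor = 3) {
  stopifnot(bisections >= 0, divisor >= 2)
  if (bisections == 0) return(core_fn(data))
  phi <- (divisor - 1) / divisor
  R <- .as_dense(data)
  rho_b <- rowSums(R)
  acc <- matrix(0, nrow(R), ncol(profiles),
                dimnames = list(rownames(data), colnames(profiles)))
  remaining <- 1
  comp <- NULL
  for (i in seq_len(bisections)) {
    if (all(R == 0)) break
    comp <- core_fn(R)
    w <- phi * remaining
    acc <- acc + w * comp
    # reconstruction of the removed counts in gene space
    removed <- (w * rho_b * comp) %*% t(profiles)
    R <- pmax(R - removed, 0)
    remaining <- remaining - w
  }
  last <- if (any(R > 0)) core_fn(R) else comp
  if (is.null(last)) last <- core_fn(data)
  acc <- acc + remaining * last
  acc
}

#' Annotation pipeline configuration
#'
#' Bundles the tunable parameters of [annotate()]. Defaults follow the
#' general-purpose configuration used throughout the package: entropic
#' regularization `epsilon = 0.005` (just large enough for numerical
#' stability; larger values push every observation toward the prior),
#' marginal relaxation `lambda = 0.1` (a compromise between trusting the
#' reference category proportions and fully data-driven marginals), four
#' bisection steps with divisor 3, and 10 representative means per category.
#'
#' @param epsilon Entropy regularization weight (>= 0.005 recommended).
#' @param lambda KL weight on the category-marginal relaxation.
#' @param metric Dissimilarity: `"bc"`, `"cos"` or `"cos-log1p"`.
#' @param max_iter,tol Sinkhorn iteration cap and tolerance.
#' @param platform_iterations Platform-normalization passes (0 disables;
#'   1 performs the single reference-marginal pass).
#' @param multi_center Representative means per category (0 or 1 = plain
#'   category means).
#' @param bisections,divisor Bisectioning booster parameters.
#' @param max_annotation Keep only the top-k weights per observation and
#'   renormalize (`NULL` = full composition; 1 = categorical).
#' @param seed Integer seed for the stochastic components (subclustering).
#' @return List of class `annotate_config`.
#' @export
annotate_config <- function(epsilon = 0.005, lambda = 0.1, metric = "bc",
                            max_iter = 10000, tol = 1e-8,
                            platform_iterations = 1, multi_center = 10,
                            bisections = 4, divisor = 3,
                            max_annotation = NULL, seed = 42) {
  stopifnot(epsilon > 0, lambda > 0, multi_center >= 0, bisections >= 0)
  structure(list(epsilon = epsilon, lambda = lambda, metric = metric,
                 max_iter = max_iter, tol = tol,
                 platform_iterations = platform_iterations,
                 multi_center = multi_center, bisections = bisections,
                 divisor = divisor, max_annotation = max_annotation,
                 seed = seed),
            class = "annotate_config")
}

# Keep the k largest weights per row, renormalize to the simplex.
.truncate_annotation <- function(comp, k) {
  if (is.null(k) || k >= ncol(comp)) return(comp)
  out <- comp
  for (i in seq_len(nrow(comp))) {
    keep <- order(comp[i, ], decreasing = TRUE)[seq_len(k)]
    row <- rep(0, ncol(comp))
    row[keep] <- comp[i, keep]
    s <- sum(row)
    out[i, ] <- if (s > 0) row / s else replace(row, keep[1], 1)
  }
  out
}

#' Transfer compositional annotations from a reference
#'
#' Full annotation pipeline: gene-space intersection, (multi-center)
#' reference profiles, platform normalization, bisectioned entropic
#' semi-unbalanced optimal transport, summation of sub-category weights to
#' their parent categories, and optional top-k truncation. The category
#' marginal prior is the reference category frequency.
#'
#' @param data Target observations x genes count matrix.
#' @param ref Reference observations x genes count matrix.
#' @param ref_anno Named category labels for the reference observations.
#' @param config An [annotate_config()].
#' @return Observations x categories matrix of annotation fractions with
#'   unit row sums.
#' @export
annotate <- function(data, ref, ref_anno, config = annotate_config()) {
  stopifnot(inherits(config, "annotate_config"))
  shared <- intersect_genes(data, ref)
  data <- shared$a
  ref <- shared$b
  ref_anno <- .check_annotation(ref_anno, rownames(ref))

  k <- max(1, config$multi_center)
  profiles <- multi_center_split(ref, ref_anno, k = k, seed = config$seed)
  parent <- attr(profiles, "parent_map")
  prior_t <- attr(profiles, "sizes")
  prior_t <- prior_t / sum(prior_t)

  if (config$platform_iterations > 0) {
    pn <- platform_normalize_iterative(
      data, profiles, type_prior = prior_t,
      iterations = config$platform_iterations,
      epsilon = config$epsilon, lambda = config$lambda, metric = config$metric
    )
    profiles <- pn$profiles
  }

  core <- function(x) .ot_core(x, profiles, prior_t = prior_t,
                               epsilon = config$epsilon, lambda = config$lambda,
                               metric = config$metric,
                               max_iter = config$max_iter, tol = config$tol)
  sub <- bisection_annotate(core, data, profiles,
                            bisections = config$bisections,
                            divisor = config$divisor)

  cats <- sort(unique(parent))
  comp <- matrix(0, nrow(sub), length(cats),
                 dimnames = list(rownames(sub), cats))
  for (cat in cats) {
    cols <- names(parent)[parent == cat]
    comp[, cat] <- rowSums(sub[, cols, drop = FALSE])
  }
  comp <- .truncate_annotation(comp, config$max_annotation)
  comp / rowSums(comp)
}
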