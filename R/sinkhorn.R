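#' Entropic semi-unbalanced optimal transport by Sinkhorn scaling
#'
#' Solves
#' \deqn{\min_{\gamma \ge 0} \sum_{tb} \gamma_{tb} M_{tb}
#'   + \epsilon \sum_{tb} \gamma_{tb} \log \gamma_{tb}
#'   + \lambda\, \mathrm{KL}(\gamma \mathbf{1} \,\|\, c_t)}
#' subject to the exact observation marginal
#' \eqn{\sum_t \gamma_{tb} = c_b}. The observation side is enforced exactly
#' (its update is applied last); the category side is relaxed through a
#' Kullback-Leibler penalty, which in the scaling iteration becomes the
#' damped exponent \eqn{\lambda / (\lambda + \epsilon)}. As
#' \eqn{\lambda \to \infty} the balanced problem is recovered.
#'
#' Marginals are rescaled internally to unit total mass so that `epsilon`
#' and `lambda` act on the probability scale regardless of count depth; the
#' returned plan is rescaled back to the units of `c_b`. A per-observation
#' shift of the minimal cost is absorbed into the scaling vectors for
#' numerical stability (the fixed point is unchanged).
#'
#' @param M Categories x observations cost matrix, finite, non-negative.
#' @param c_b Positive observation marginal (e.g. counts per observation).
#' @param c_t Positive category marginal prior; rescaled to `sum(c_b)`.
#' @param epsilon Entropy regularization weight (default 0.005). Values much
#'   below 0.005 make the scaling numerically unstable.
#' @param lambda KL marginal-relaxation weight (default 0.1).
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   maximum relative change of the scaling vectors.
#' @return Object of class `transport_plan`: list with `gamma` (categories x
#'   observations), `obs_marginal`, `type_prior`, `converged`, `iterations`.
#' @export
sinkhorn_semi_unbalanced <- function(M, c_b, c_t, epsilon = 0.005, lambda = 0.1,
                                     max_iter = 10000, tol = 1e-8) {
  M <- .as_dense(M)
  if (!all(is.finite(M))) stop("cost matrix must be finite")
  if (any(c_b <= 0) || any(c_t <= 0)) stop("marginals must be positive")
  stopifnot(epsilon > 0, lambda > 0, nrow(M) == length(c_t), ncol(M) == length(c_b))
  total <- sum(c_b)
  cb <- c_b / total
  ct <- c_t / sum(c_t)

  shift <- apply(M, 2, min)
  K <- exp(-sweep(M, 2, shift, "-") / epsilon)
  damp <- lambda / (lambda + epsilon)
  u <- rep(1, nrow(M))
  v <- cb / colSums(K)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    u_old <- u
    Kv <- as.vector(K %*% v)
    u <- (ct / pmax(Kv, .Machine$double.xmin))^damp
    v <- cb / pmax(as.vector(crossprod(K, u)), .Machine$double.xmin)
    if (max(abs(u - u_old) / pmax(abs(u_old), 1e-300)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("Sinkhorn scaling did not converge in ", max_iter, " iterations")
  gamma <- sweep(u * K, 2, v * total, "*")
  dimnames(gamma) <- dimnames(M)
  structure(list(gamma = gamma, obs_marginal = c_b, type_prior = c_t,
                 converged = converged, iterations = it),
            class = "transport_plan")
}

#' Compositional annotation from a transport plan
#'
#' Normalizes each observation's column of the coupling to unit sum,
#' giving the probability-unit composition `rho'`; the counts-unit view is
#' `rho' * rho_b`.
#'
#' @param plan A `transport_plan` (or bare categories x observations matrix).
#' @return Observations x categories matrix with unit row sums.
#' @export
plan_to_composition <- function(plan) {
  gamma <- if (inherits(plan, "transport_plan")) plan$gamma else .as_dense(plan)
  cs <- colSums(gamma)
  zero <- cs == 0
  if (any(zero)) {
    warning(sum(zero), " observations with empty transport column get a uniform composition")
    gamma[, zero] <- 1
    cs[zero] <- nrow(gamma)
  }
  t(sweep(gamma, 2, cs, "/"))
}

#' @export
print.transport_plan <- function(x, ...) {
  cat("transport plan:", nrow(x$gamma), "categories x", ncol(x$gamma), "observations;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations\n")
  invisible(x)
}
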