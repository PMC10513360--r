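# Independent convex-solver oracle for the semi-unbalanced transport
# objective: a per-observation softmax parametrization keeps the exact
# observation marginal; generic quasi-Newton plus simplex polish.
# Row-by-row brute-force pair-weight sums (independent of the array code
# path in the package, which batches whole distance-bin masks).
cooc_oracle_fast <- function(positions, A, C, bins) {
  n <- nrow(positions)
  nb <- length(bins) - 1
  S <- array(0, dim = c(ncol(A), ncol(C), nb))
  for (i in seq_len(n)) {
    d <- sqrt((positions[, 1] - positions[i, 1])^2 +
                (positions[, 2] - positions[i, 2])^2)
    for (k in seq_len(nb)) {
      sel <- which(d >= bins[k] & d < bins[k + 1])
      sel <- sel[sel != i]
      if (length(sel))
        S[, , k] <- S[, , k] + outer(colSums(A[sel, , drop = FALSE]), C[i, ])
    }
  }
  S
}

ot_oracle <- function(M, cb, ct, eps, lam) {
  nt <- nrow(M); nb <- ncol(M)
  unpack <- function(th) {
    G <- matrix(0, nt, nb)
    for (b in seq_len(nb)) {
      p <- exp(c(th[((b - 1) * (nt - 1) + 1):(b * (nt - 1))], 0))
      G[, b] <- cb[b] * p / sum(p)
    }
    G
  }
  obj <- function(th) {
    G <- unpack(th)
    rowm <- rowSums(G)
    sum(G * M) + eps * sum(G * log(G)) + lam * sum(rowm * log(rowm / ct))
  }
  th0 <- rep(0, (nt - 1) * nb)
  o <- optim(th0, obj, method = "BFGS", control = list(reltol = 1e-16, maxit = 5000))
  o <- optim(o$par, obj, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 50000))
  unpack(o$par)
}
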