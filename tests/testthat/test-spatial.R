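# brute-force co-occurrence oracle: explicit double loop over ordered pairs
cooc_oracle <- function(positions, A, C, bins) {
  n <- nrow(positions)
  nb <- length(bins) - 1
  S <- array(0, dim = c(ncol(A), ncol(C), nb))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((positions[i, ] - positions[j, ])^2))
    k <- findInterval(d, bins, rightmost.closed = FALSE)
    if (k >= 1 && k <= nb && d < bins[k + 1]) {
      S[, , k] <- S[, , k] + outer(A[j, ], C[i, ])
    }
  }
  S
}

layered_positions <- function(n = 120, seed = 3) {
  set.seed(seed)
  pos <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  rownames(pos) <- paste0("o", seq_len(n))
  labels <- ifelse(pos[, 1] < 50, "L", "R")
  names(labels) <- rownames(pos)
  list(pos = pos, labels = labels)
}

test_that("co-occurrence is 1 everywhere for homogeneous annotations", {
  set.seed(2)
  pos <- cbind(runif(80), runif(80))
  rownames(pos) <- paste0("o", 1:80)
  anno <- matrix(c(0.5, 0.5), 80, 2, byrow = TRUE,
                 dimnames = list(rownames(pos), c("A", "B")))
  cc <- co_occurrence(pos, anno, bins = c(0, 0.3, 0.6, 1.5))
  vals <- cc$values[!is.nan(cc$values)]
  expect_equal(vals, rep(1, length(vals)), tolerance = 1e-9)
})

test_that("segregated categories co-occur with themselves at short range", {
  lay <- layered_positions()
  cc <- co_occurrence(lay$pos, lay$labels, bins = c(0, 10, 200))
  expect_gt(cc$values["L", "L", 1], 1)
  expect_lt(cc$values["L", "R", 1], 1)
})

test_that("co-occurrence matches the brute-force double loop", {
  set.seed(5)
  n <- 200
  pos <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  rownames(pos) <- paste0("o", seq_len(n))
  A <- matrix(rgamma(n * 3, 1), n); A <- A / rowSums(A)
  C <- matrix(rgamma(n * 2, 1), n); C <- C / rowSums(C)
  dimnames(A) <- list(rownames(pos), c("a1", "a2", "a3"))
  dimnames(C) <- list(rownames(pos), c("c1", "c2"))
  bins <- c(0, 5, 10, 20, 40)
  cc <- co_occurrence(pos, A, C, bins)
  S <- cooc_oracle(pos, A, C, bins)
  expect_equal(unname(cc$counts), S, tolerance = 1e-10)
  p_anno <- colSums(A) / n
  for (k in 1:4) for (c_ in 1:2) {
    tot <- sum(S[, c_, k])
    if (tot > 0)
      expect_equal(unname(cc$values[, c_, k]),
                   unname((S[, c_, k] / tot) / p_anno), tolerance = 1e-10)
  }
})

test_that("z-scores vanish for constant annotations and detect planted structure", {
  lay <- layered_positions()
  const <- matrix(1, nrow(lay$pos), 1,
                  dimnames = list(rownames(lay$pos), "only"))
  z0 <- neighborhood_zscores(lay$pos, const, const, bins = c(0, 20, 100),
                             n_perm = 30, seed = 1)
  expect_true(all(z0 == 0))

  z <- neighborhood_zscores(lay$pos, lay$labels, lay$labels, bins = c(0, 15, 200),
                            n_perm = 100, seed = 2)
  expect_gt(z["L", "L", 1], 3)
  expect_gt(z["R", "R", 1], 3)
  expect_lt(z["L", "R", 1], -3)
})

test_that("z-scores calibrate to mean 0, sd 1 under the random-label null", {
  set.seed(11)
  zs <- numeric(0)
  for (rep in 1:50) {
    n <- 60
    pos <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    rownames(pos) <- paste0("o", seq_len(n))
    labels <- setNames(sample(c("A", "B"), n, TRUE), rownames(pos))
    z <- neighborhood_zscores(pos, labels, labels, bins = c(0, 10, 25),
                              n_perm = 100, seed = rep)
    zs <- c(zs, as.vector(z))
  }
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.25)
})

test_that("regions follow positions at weight 1 and link strata across samples", {
  set.seed(13)
  # two spatial clusters
  pos <- rbind(cbind(rnorm(40, 0, 1), rnorm(40, 0, 1)),
               cbind(rnorm(40, 20, 1), rnorm(40, 20, 1)))
  x <- matrix(rnorm(80 * 3), 80)
  reg <- define_regions(x, pos, position_weight = 1, k_neighbors = 10,
                        resolution = 0.2, seed = 1)
  truth <- rep(1:2, each = 40)
  expect_equal(length(unique(reg)), 2)
  agreement <- max(mean(reg == truth), mean(reg == 3 - truth))
  expect_equal(agreement, 1)

  # two samples, each with the same two expression strata
  strata <- rep(rep(1:2, each = 20), 2)
  xs <- matrix(rnorm(80 * 4, mean = 3 * strata), 80)
  poss <- rbind(cbind(runif(40), strata[1:40] * 5),
                cbind(runif(40), strata[41:80] * 5))
  samp <- rep(c("s1", "s2"), each = 40)
  reg2 <- define_regions(xs, poss, samp, position_weight = 0.5,
                         k_neighbors = 8, resolution = 0.5, seed = 2)
  # strata must share labels across samples
  for (s in 1:2) {
    l1 <- unique(reg2[samp == "s1" & strata == s])
    l2 <- unique(reg2[samp == "s2" & strata == s])
    expect_equal(length(l1), 1)
    expect_equal(l1, l2)
  }

  # permuting observation order only renames labels
  perm <- sample(80)
  reg3 <- define_regions(xs[perm, ], poss[perm, ], samp[perm],
                         position_weight = 0.5, k_neighbors = 8,
                         resolution = 0.5, seed = 2)
  tab <- table(reg2[perm], reg3)
  expect_equal(sum(tab > 0), length(unique(reg2)))
})

test_that("annotation coordinate equals the minimum distance on noise-free labels", {
  # 1-D lattice: cumulative occurrence curves are exactly piecewise linear
  # at the bin resolution, so the homogeneous correction is exact
  pos <- cbind(x = 0:19, y = 0)
  rownames(pos) <- paste0("o", 1:20)
  labels <- setNames(rep("bg", 20), rownames(pos))
  labels[20] <- "A"
  d0 <- annotation_coordinate(pos, labels, "A", threshold = 1, bin_width = 1)
  D2 <- as.matrix(dist(pos)); diag(D2) <- Inf
  mind <- apply(D2[, labels == "A", drop = FALSE], 1, min)
  # observers whose distance to A shares no histogram bin with another
  # observation: the homogeneous correction is exact there
  clean <- 1:10
  expect_equal(unname(d0[clean]), unname(mind[clean]), tolerance = 1e-9)

  # general 2-D geometry: equality within one bin width
  set.seed(23)
  pos2 <- cbind(runif(100, 0, 30), runif(100, 0, 30))
  rownames(pos2) <- paste0("p", 1:100)
  lab2 <- setNames(c(rep("A", 10), rep("bg", 90)), rownames(pos2))
  d02 <- annotation_coordinate(pos2, lab2, "A", threshold = 1, bin_width = 2)
  Dd <- as.matrix(dist(pos2)); diag(Dd) <- Inf
  mind2 <- apply(Dd[, lab2 == "A", drop = FALSE], 1, min)
  expect_lt(max(abs(d02 - mind2)), 2)
})

test_that("annotation coordinate is ~0 for ubiquitous categories and monotone in the threshold", {
  pos <- as.matrix(expand.grid(x = 0:7, y = 0:7))
  rownames(pos) <- paste0("o", seq_len(nrow(pos)))
  labels <- setNames(rep("A", nrow(pos)), rownames(pos))
  d0 <- annotation_coordinate(pos, labels, "A", threshold = 1, bin_width = 1)
  expect_true(all(d0 < 1))

  lay <- layered_positions(n = 80, seed = 7)
  d1 <- annotation_coordinate(lay$pos, lay$labels, "L", threshold = 1, bin_width = 5)
  d2 <- annotation_coordinate(lay$pos, lay$labels, "L", threshold = 2, bin_width = 5)
  expect_true(all(d2 - d1 >= -1e-9))
})

test_that("annotation coordinate flags insufficient occurrence as infinite", {
  pos <- cbind(c(0, 1, 2), c(0, 0, 0))
  rownames(pos) <- paste0("o", 1:3)
  labels <- setNames(c("A", "B", "B"), rownames(pos))
  d0 <- annotation_coordinate(pos, labels, "A", threshold = 2, bin_width = 1)
  expect_true(all(is.infinite(d0)))
})

test_that("enrichment: identical compositions give p = 1 and zero effect", {
  comp <- matrix(0.25, 40, 4,
                 dimnames = list(paste0("o", 1:40), paste0("t", 1:4)))
  res <- enrichment_test(comp, group_labels = rep(c("g1", "g2"), each = 20),
                         sample_labels = rep(paste0("s", 1:8), each = 5))
  expect_true(all(res$p == 1))
  expect_true(all(res$effect == 0))
})

test_that("a planted two-fold enrichment is detected across units", {
  set.seed(17)
  hits <- 0
  for (rep in 1:20) {
    units <- 10
    per_unit <- 5
    mk <- function(boost) {
      t(vapply(seq_len(units * per_unit), function(i) {
        m <- c(0.2 * boost, 0.4, 0.4)
        m <- pmax(m * (1 + stats::rnorm(3, 0, 0.1)), 0.01)
        m / sum(m)
      }, numeric(3)))
    }
    comp <- rbind(mk(2), mk(1))
    dimnames(comp) <- list(paste0("o", seq_len(nrow(comp))), c("up", "b", "c"))
    groups <- rep(c("case", "ctrl"), each = units * per_unit)
    samples <- rep(paste0(rep(c("case", "ctrl"), each = units), "_",
                          rep(seq_len(units), 2)), each = per_unit)
    res <- enrichment_test(comp, groups, samples)
    if (res$q[res$category == "up"] < 0.05 && res$effect[res$category == "up"] > 0)
      hits <- hits + 1
  }
  expect_gte(hits, 18)

  # null calibration: without a planted effect, detections are rare
  set.seed(18)
  false_pos <- 0
  for (rep in 1:20) {
    comp <- matrix(rgamma(100 * 3, 20), 100)
    comp <- comp / rowSums(comp)
    dimnames(comp) <- list(paste0("o", 1:100), c("a", "b", "c"))
    groups <- rep(c("g1", "g2"), each = 50)
    samples <- rep(paste0("u", 1:20), each = 5)
    res <- enrichment_test(comp, groups, samples)
    if (any(res$q < 0.05, na.rm = TRUE)) false_pos <- false_pos + 1
  }
  expect_lte(false_pos, 4)
})

test_that("spatial sub-block splitting multiplies the ensemble", {
  set.seed(19)
  n <- 200
  pos <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  comp <- matrix(rgamma(n * 2, 2), n); comp <- comp / rowSums(comp)
  dimnames(comp) <- list(paste0("o", 1:n), c("A", "B"))
  groups <- rep(c("g1", "g2"), each = n / 2)
  samples <- rep(c("s1", "s2"), each = n / 2)
  expect_warning(res1 <- enrichment_test(comp, groups, samples),
                 "fewer than 2")
  expect_true(all(is.nan(res1$p) | is.na(res1$p)))  # one unit per group
  res2 <- enrichment_test(comp, groups, samples, n_splits_per_axis = 3,
                          positions = pos)
  expect_true(all(is.finite(res2$p)))
  expect_gt(res2$n_units_1[1], 2)
})
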