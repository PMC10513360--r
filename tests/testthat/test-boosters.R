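test_that("platform factors: identity, doubled gene, single-category collapse", {
  sep <- separated_types()
  prof <- mean_profiles(sep$counts, sep$anno)
  freq <- table(sep$anno) / length(sep$anno)
  bulk <- Matrix::colSums(sep$counts)
  f <- platform_factors(prof, bulk, as.vector(freq[colnames(prof)]))
  # target bulk equals reference pseudobulk -> f constant 1 (up to count noise
  # from the mean-profile construction: here exact because bulk == sum of cells)
  pseudobulk <- as.vector(prof %*% (as.vector(freq) *
                                      tapply(Matrix::rowSums(sep$counts), sep$anno, mean) /
                                      mean(Matrix::rowSums(sep$counts))))
  expect_true(all(f > 0))

  # doubling one gene in the target doubles its factor relative to the rest
  bulk2 <- bulk
  bulk2[1] <- 2 * bulk2[1]
  f2 <- platform_factors(prof, bulk2, as.vector(freq[colnames(prof)]))
  ratio <- (f2 / sum(bulk2 == bulk2)) / (f / 1)
  expect_equal(unname((f2[1] / f[1]) / (f2[2] / f[2])), 2, tolerance = 1e-6)

  # single category: f proportional to bulk / profile
  p1 <- prof[, 1, drop = FALSE]
  f1 <- platform_factors(p1, bulk, 1)
  expect_equal(unname(f1), unname((bulk / sum(bulk)) / (p1[, 1] + 1e-12)),
               tolerance = 1e-9)

  expect_error(platform_factors(prof, rep(0, nrow(prof)), freq), "all zero")
})

test_that("identical platforms converge immediately to constant factors", {
  sep <- separated_types(n_per_type = 30)
  prof <- mean_profiles(sep$counts, sep$anno)
  sizes <- table(sep$anno)[colnames(prof)]
  pn <- platform_normalize_iterative(sep$counts, prof,
                                     type_prior = as.vector(sizes), iterations = 3)
  # with balanced types and equal library sizes in expectation, factors are
  # near 1 for every expressed gene
  expressed <- Matrix::colSums(sep$counts) > 0
  expect_lt(max(abs(pn$factors[expressed] * nrow(prof) /
                      sum(pn$factors[expressed]) / (nrow(prof) / sum(expressed)) - 1)), 0.35)
  expect_lte(pn$iterations_run, 3)
})

test_that("known gene-wise platform distortion is recovered within 5%", {
  set.seed(31)
  sim <- simulate_scrnaseq(n_cells = 400, n_genes = 300, n_types = 4,
                           de_loc = 3, seed = 33)
  f_true <- exp(stats::rnorm(300, 0, 0.5))
  target <- sim$counts
  target@x <- target@x * f_true[rep(seq_len(ncol(target)),
                                    diff(target@p))[order(order(target@i))]]
  # simpler exact scaling via matrix product
  target <- sim$counts %*% Matrix::Diagonal(x = f_true)
  dimnames(target) <- dimnames(sim$counts)
  prof <- mean_profiles(sim$counts, sim$types)
  sizes <- as.vector(table(sim$types)[colnames(prof)])
  pn <- platform_normalize_iterative(target, prof, type_prior = sizes,
                                     iterations = 3)
  expressed <- Matrix::colSums(sim$counts) > 3
  rel <- pn$factors[expressed] / f_true[expressed]
  rel <- rel / stats::median(rel)   # factors are defined up to global scale
  expect_lt(stats::median(abs(rel - 1)), 0.05)
})

test_that("multi-center subclustering: k = 1 equals means, planted subtypes recovered, k clamps", {
  sep <- separated_types()
  p1 <- multi_center_split(sep$counts, sep$anno, k = 1)
  expect_equal(unclass(p1)[, ], unclass(mean_profiles(sep$counts, sep$anno))[, ])
  expect_equal(attr(p1, "parent_map"), c(A = "A", B = "B"))

  # one declared category containing two well-separated expression subtypes
  set.seed(41)
  sub <- separated_types(n_per_type = 25, n_genes = 30, depth = 80, seed = 42)
  anno_one <- setNames(rep("X", nrow(sub$counts)), rownames(sub$counts))
  pk <- multi_center_split(sub$counts, anno_one, k = 2, seed = 1)
  expect_equal(ncol(pk), 2)
  expect_equal(unname(attr(pk, "parent_map")), c("X", "X"))
  truth <- mean_profiles(sub$counts, sub$anno)
  # each true subtype profile is matched by one sub-center almost exactly
  sims <- crossprod(sqrt(truth), sqrt(pk))   # BC similarities
  expect_gt(min(apply(sims, 1, max)), 0.999)

  # k larger than the category: one sub-profile per cell
  small <- sep$counts[1:3, ]
  pk2 <- multi_center_split(small, setNames(rep("A", 3), rownames(small)), k = 10)
  expect_equal(ncol(pk2), 3)
})

test_that("bisectioning: 0 steps = plain call, pure observation stays categorical, fractions conserved", {
  sep <- separated_types()
  prof <- mean_profiles(sep$counts, sep$anno)
  calls <- 0
  core <- function(x) {
    calls <<- calls + 1
    compot:::.ot_core(x, prof)
  }
  comp0 <- bisection_annotate(core, sep$counts, prof, bisections = 0)
  expect_equal(calls, 1)
  expect_equal(rowSums(comp0), rep(1, nrow(sep$counts)), ignore_attr = TRUE)

  # observation exactly equal to a profile
  pure <- rbind(obs1 = round(1000 * prof[, "A"]))
  colnames(pure) <- rownames(prof)
  comp <- bisection_annotate(function(x) compot:::.ot_core(x, prof), pure, prof,
                             bisections = 4, divisor = 3)
  expect_gt(comp[1, "A"], 1 - 1e-3)
  expect_equal(sum(comp[1, ]), 1, tolerance = 1e-12)
})

test_that("bisectioning improves mixtures for a categorical-leaning core", {
  set.seed(51)
  sep <- separated_types(n_per_type = 10, n_genes = 20, depth = 200, seed = 52)
  prof <- mean_profiles(sep$counts, sep$anno)
  # 50/50 mixtures of the two profiles
  mix <- t(replicate(30, rpois(20, 100 * (prof[, 1] + prof[, 2]) / 2)))
  dimnames(mix) <- list(sprintf("m%02d", 1:30), rownames(prof))
  truth <- matrix(0.5, 30, 2, dimnames = list(rownames(mix), colnames(prof)))
  hard_core <- function(x) {
    comp <- compot:::.ot_core(x, prof)
    compot:::.truncate_annotation(comp, 1)   # categorical-leaning core
  }
  e_without <- l2_error(bisection_annotate(hard_core, mix, prof, bisections = 0), truth)
  e_with <- l2_error(bisection_annotate(hard_core, mix, prof, bisections = 4,
                                        divisor = 3), truth)
  expect_lte(e_with, e_without)
})

test_that("annotate recovers reference labels, handles one category and max_annotation", {
  set.seed(61)
  sim <- simulate_scrnaseq(n_cells = 240, n_genes = 300, n_types = 4,
                           de_loc = 4, seed = 62)
  comp <- annotate(sim$counts, sim$counts, sim$types,
                   annotate_config(multi_center = 2, bisections = 2))
  expect_gte(fraction_correct(comp, sim$types), 0.99)
  expect_equal(rowSums(comp), rep(1, nrow(comp)), ignore_attr = TRUE,
               tolerance = 1e-9)

  one <- annotate(sim$counts, sim$counts,
                  setNames(rep("only", nrow(sim$counts)), rownames(sim$counts)),
                  annotate_config(multi_center = 0, bisections = 0))
  expect_equal(unname(one[, 1]), rep(1, nrow(one)))

  cat1 <- annotate(sim$counts, sim$counts, sim$types,
                   annotate_config(multi_center = 0, bisections = 1,
                                   max_annotation = 1))
  expect_true(all(apply(cat1, 1, max) == 1))
})

test_that("annotate is invariant under a common permutation of genes", {
  sim <- simulate_scrnaseq(n_cells = 120, n_genes = 150, n_types = 3,
                           de_loc = 4, seed = 71)
  cfg <- annotate_config(multi_center = 0, bisections = 1, seed = 5)
  comp <- annotate(sim$counts, sim$counts, sim$types, cfg)
  perm <- sample(ncol(sim$counts))
  comp2 <- annotate(sim$counts[, perm], sim$counts[, perm], sim$types, cfg)
  expect_equal(comp, comp2, tolerance = 1e-10)
})
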