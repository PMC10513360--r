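#' Run a desk-scale annotation benchmark
#'
#' Generates benchmark inputs with the package simulators, runs the
#' requested annotation methods and scores them. Tasks:
#' \describe{
#'   \item{mixture}{Bead mixtures over a `bead_size` grid; metric: mean L2
#'     error against the count-fraction truth.}
#'   \item{dropout}{Cell typing under enhanced dropout over a
#'     `midpoint_shift` grid; metric: fraction of correctly classified
#'     cells (argmax).}
#'   \item{ambient}{Cell typing under ambient contamination over an
#'     `f_drop` grid; metric: fraction correct.}
#'   \item{fates}{Clonal fate prediction; metric: Pearson correlation of
#'     predicted and true fate biases.}
#' }
#' Reference and test data are independent draws from the same generative
#' parameters; the perturbation (dropout/ambient) is applied to the test
#' data only.
#'
#' @param task One of `"mixture"`, `"dropout"`, `"ambient"`, `"fates"`.
#' @param grid Numeric parameter grid (ignored for `"fates"`).
#' @param seeds Integer vector of replicate seeds.
#' @param methods Subset of `c("ot", "svm")` (`"svm"` is categorical and
#'   not scored on the mixture/fates tasks).
#' @param n_ref,n_test,n_genes,n_types Problem sizes.
#' @param config [annotate_config()] for the `"ot"` method.
#' @return `data.frame` with method, task, parameter, metric, value, seed.
#' @export
run_benchmark <- function(task = c("mixture", "dropout", "ambient", "fates"),
                          grid = NULL, seeds = 1L, methods = c("ot", "svm"),
                          n_ref = 1000, n_test = 1000, n_genes = 1000,
                          n_types = 5, config = annotate_config()) {
  task <- match.arg(task)
  if (is.null(grid))
    grid <- switch(task, mixture = c(0.5, 1, 1.5), dropout = c(0, -1, -2),
                   ambient = c(0, 0.2, 0.5), fates = NA_real_)
  rows <- list()
  for (seed in seeds) for (par in grid) {
    res <- switch(
      task,
      mixture = .bench_mixture(par, seed, methods, n_ref, n_test, n_genes, n_types, config),
      dropout = .bench_dropout(par, seed, methods, n_ref, n_test, n_genes, n_types, config),
      ambient = .bench_ambient(par, seed, methods, n_ref, n_test, n_genes, n_types, config),
      fates = .bench_fates(seed, methods, n_genes, n_types, config)
    )
    res$task <- task
    res$parameter <- par
    res$seed <- seed
    rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("method", "task", "parameter", "metric", "value", "seed")]
}

.bench_mixture <- function(bead_size, seed, methods, n_ref, n_test, n_genes,
                           n_types, config) {
  sim <- simulate_scrnaseq(n_cells = n_ref, n_genes = n_genes, n_types = n_types,
                           seed = .sub_seed(seed, 11))
  mix <- simulate_mixtures(sim$counts, sim$types, n_beads = n_test,
                           bead_size = bead_size, seed = .sub_seed(seed, 12))
  keep <- Matrix::rowSums(mix$counts) > 0
  comp <- annotate(mix$counts[keep, ], sim$counts, sim$types, config)
  data.frame(method = "ot", metric = "l2_error",
             value = l2_error(comp, mix$count_fractions[keep, , drop = FALSE]))
}

.bench_dropout <- function(shift, seed, methods, n_ref, n_test, n_genes,
                           n_types, config) {
  sim <- simulate_scrnaseq(n_cells = n_ref + n_test, n_genes = n_genes,
                           n_types = n_types, seed = .sub_seed(seed, 21))
  idx_ref <- seq_len(n_ref)
  ref <- sim$counts[idx_ref, ]
  ref_anno <- sim$types[idx_ref]
  test <- sim$counts[-idx_ref, ]
  truth <- sim$types[-idx_ref]
  if (shift != 0)
    test <- apply_dropout(test, midpoint_shift = shift,
                          seed = .sub_seed(seed, 22))$counts
  .classify_and_score(ref, ref_anno, test, truth, methods, config)
}

.bench_ambient <- function(f_drop, seed, methods, n_ref, n_test, n_genes,
                           n_types, config) {
  sim <- simulate_scrnaseq(n_cells = n_ref + n_test, n_genes = n_genes,
                           n_types = n_types, return_means = TRUE,
                           seed = .sub_seed(seed, 31))
  idx_ref <- seq_len(n_ref)
  ref <- add_ambient(sim$lambda[idx_ref, ], f_drop = 0, seed = .sub_seed(seed, 32))
  test <- add_ambient(sim$lambda[-idx_ref, ], f_drop = f_drop, seed = .sub_seed(seed, 33))
  .classify_and_score(ref, sim$types[idx_ref], test, sim$types[-idx_ref],
                      methods, config)
}

.bench_fates <- function(seed, methods, n_genes, n_types, config) {
  sim <- simulate_fate_data(n_fates = n_types, n_genes = n_genes,
                            seed = .sub_seed(seed, 41))
  comp <- annotate(sim$early$counts, sim$late$counts, sim$late$fates, config)
  data.frame(method = "ot", metric = "fate_correlation",
             value = fate_correlation(comp, sim$bias))
}

.classify_and_score <- function(ref, ref_anno, test, truth, methods, config) {
  out <- list()
  if ("ot" %in% methods) {
    comp <- annotate(test, ref, ref_anno, config)
    out[[length(out) + 1]] <- data.frame(method = "ot", metric = "fraction_correct",
                                         value = fraction_correct(comp, truth))
  }
  if ("svm" %in% methods) {
    pred <- svm_baseline(ref, ref_anno, test)
    out[[length(out) + 1]] <- data.frame(method = "svm", metric = "fraction_correct",
                                         value = mean(pred == truth[names(pred)]))
  }
  do.call(rbind, out)
}
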