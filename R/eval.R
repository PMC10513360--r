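#' Mean L2 error between predicted and true compositions
#'
#' Mean over observations of the Euclidean norm of the difference of the
#' probability-unit composition rows.
#'
#' @param pred,truth Observations x categories matrices with matching ids.
#' @return Non-negative scalar.
#' @export
l2_error <- function(pred, truth) {
  pred <- .as_dense(pred)
  truth <- .as_dense(truth)
  if (!all(colnames(pred) == colnames(truth)) ||
      !all(rownames(pred) == rownames(truth)))
    stop("pred and truth ids do not match")
  mean(sqrt(rowSums((pred - truth)^2)))
}

#' Fraction of observations whose argmax composition matches the truth
#'
#' Argmax ties are broken by the first (lexicographically smallest)
#' category, which counts as correct only if it matches the true label.
#'
#' @param pred Observations x categories composition matrix.
#' @param truth Named categorical labels.
#' @return Scalar in `[0, 1]`.
#' @export
fraction_correct <- function(pred, truth) {
  pred <- .as_dense(pred)
  truth <- .check_annotation(truth, rownames(pred))
  called <- colnames(pred)[apply(pred, 1, which.max)]
  mean(called == truth)
}

#' Pearson correlation between predicted and true fate biases
#'
#' Correlation over the flattened cells x fates matrices.
#'
#' @param pred,truth Cells x fates matrices with matching ids.
#' @return Pearson r.
#' @export
fate_correlation <- function(pred, truth) {
  pred <- .as_dense(pred)
  truth <- .as_dense(truth)
  if (!all(dim(pred) == dim(truth))) stop("dimension mismatch")
  if (!is.null(colnames(pred)) && !is.null(colnames(truth)))
    truth <- truth[rownames(pred), colnames(pred), drop = FALSE]
  cor(as.vector(pred), as.vector(truth))
}

#' Linear support-vector classifier baseline
#'
#' Trains a linear SVM (library defaults, no feature standardization, as in
#' the common scientific-python usage of a default linear SVC) on
#' log1p-normalized reference expression and predicts categorical labels
#' for the test observations.
#'
#' @param ref Reference cells x genes counts.
#' @param ref_anno Named labels per reference cell.
#' @param test Test observations x genes counts.
#' @return Named character vector of predicted labels.
#' @export
svm_baseline <- function(ref, ref_anno, test) {
  shared <- intersect_genes(test, ref)
  test <- shared$a
  ref <- shared$b
  ref_anno <- .check_annotation(ref_anno, rownames(ref))
  xtr <- .as_dense(log1p_normalize(ref))
  xte <- .as_dense(log1p_normalize(test))
  fit <- e1071::svm(xtr, factor(ref_anno), kernel = "linear", scale = FALSE)
  pred <- stats::predict(fit, xte)
  setNames(as.character(pred), rownames(test))
}
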