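# Test-set metrics: Pearson correlation for regression tasks and area under
# the precision-recall curve for (typically heavily imbalanced) binary
# tasks.

#' Pearson correlation coefficient
#'
#' @param pred,obs Equal-length numeric vectors. Either vector being
#'   constant is an error (the correlation is undefined).
#' @return A number in `[-1, 1]`.
#' @export
pcc <- function(pred, obs) {
  stopifnot(is.numeric(pred), is.numeric(obs))
  if (length(pred) != length(obs)) rlang::abort("`pred` and `obs` must have equal length")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    rlang::abort("correlation undefined for a constant vector")
  }
  stats::cor(pred, obs)
}

#' Area under the precision-recall curve
#'
#' Computed by step-wise integration of the precision-recall curve: scores
#' are swept from high to low, tied scores are treated as a single
#' threshold, and the area is the sum of `precision * delta-recall` over
#' thresholds. A perfect ranking gives 1; a random ranking concentrates
#' around the positive-class prevalence.
#'
#' @param scores Numeric vector of predicted scores (larger = more
#'   positive).
#' @param labels 0/1 vector of true classes; both classes must be present.
#' @return A number in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(is.numeric(scores))
  if (length(scores) != length(labels)) rlang::abort("`scores` and `labels` must have equal length")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) rlang::abort("`labels` must be 0/1")
  P <- sum(labels)
  if (P == 0 || P == length(labels)) {
    rlang::abort("auprc undefined when only one class is present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # collapse tied scores to one operating point (the last index of each tie)
  last_of_tie <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- tp[last_of_tie]
  fp <- fp[last_of_tie]
  precision <- tp / (tp + fp)
  recall <- tp / P
  sum(diff(c(0, recall)) * precision)
}

#' @rdname auprc
#' @param scores_mat,labels_mat Matrices `(n, n_tasks)`; the average is the
#'   unweighted mean of per-task AUPRC values.
#' @export
avg_auprc <- function(scores_mat, labels_mat) {
  stopifnot(is.matrix(scores_mat), ncol(scores_mat) == ncol(labels_mat))
  mean(vapply(seq_len(ncol(scores_mat)),
              function(j) auprc(scores_mat[, j], labels_mat[, j]),
              numeric(1L)))
}
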