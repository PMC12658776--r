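#' Confusion-matrix metric suite
#'
#' With the positive class coded 1: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), balanced accuracy = their mean,
#' F-score = 2 TP / (2 TP + FP + FN), accuracy = (TP + TN) / n, and AUC as
#' the Mann-Whitney rank statistic of the positive-class score.
#'
#' @param truth01 integer 0/1 truth labels.
#' @param pred01 integer 0/1 predicted labels.
#' @param score_pos optional numeric score for the positive class (needed
#'   for AUC; both classes must be present in `truth01`).
#' @return list of metrics, proportions in [0, 1].
#' @export
classification_metrics <- function(truth01, pred01, score_pos = NULL) {
  stopifnot(length(truth01) == length(pred01),
            all(truth01 %in% 0:1), all(pred01 %in% 0:1))
  tp <- sum(pred01 == 1 & truth01 == 1)
  tn <- sum(pred01 == 0 & truth01 == 0)
  fp <- sum(pred01 == 1 & truth01 == 0)
  fn <- sum(pred01 == 0 & truth01 == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  out <- list(
    accuracy = (tp + tn) / length(truth01),
    sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    f_score = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
      else NA_real_)
  if (!is.null(score_pos)) {
    n1 <- sum(truth01 == 1); n0 <- sum(truth01 == 0)
    if (n1 == 0 || n0 == 0)
      stop("AUC is undefined when the test set holds a single class")
    r <- rank(score_pos)
    out$auc <- (sum(r[truth01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out
}

#' Permutation test of classification accuracy
#'
#' The test-set labels are shuffled `n_perm` times, the accuracy of the
#' fixed predictions recomputed each time, and the add-one estimator
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)` returned, so p can never
#' be exactly zero and is bounded below by `1 / (n_perm + 1)`.
#'
#' @param pred01 fixed predicted labels.
#' @param truth01 true labels to shuffle.
#' @param n_perm number of shuffles (1000 by default).
#' @param rng_seed integer seed.
#' @return list: `p`, `observed` accuracy, `perm_acc` vector.
#' @export
permutation_test_acc <- function(pred01, truth01, n_perm = 1000L,
                                 rng_seed = 1L) {
  stopifnot(length(pred01) == length(truth01), n_perm >= 1)
  set.seed(rng_seed)
  observed <- mean(pred01 == truth01)
  perm_acc <- vapply(seq_len(n_perm), function(i)
    mean(pred01 == sample(truth01)), numeric(1))
  p <- (1 + sum(perm_acc >= observed)) / (1 + n_perm)
  list(p = p, observed = observed, perm_acc = perm_acc)
}
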