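## Multi-label evaluation: macro-AUC (rank-based, midrank ties), sensitivity
## (macro recall at a fixed threshold), macro F1, per-label accuracy, macro
## average precision; and the confounder-shift robustness protocol.

#' Rank-based AUC for one class (midrank tie handling)
#' @param scores numeric vector.
#' @param labels 0/1 vector.
#' @return AUC in [0, 1], or `NA` if only one label value is present.
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## average precision for one class (AP = mean of precision at each positive,
## scores sorted decreasing; midpoint-free standard definition)
average_precision <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab == 1]) / n1
}

#' Multi-label classification metrics
#'
#' Macro-AUC averages the rank-based AUC over classes whose label column
#' contains both values (single-valued columns are excluded and counted).
#' Sensitivity (= macro recall), macro F1 and macro average precision are
#' computed over classes with at least one positive label; accuracy is
#' per-label accuracy macro-averaged over all classes. Thresholded metrics
#' use `score >= threshold`.
#'
#' @param scores n x K score matrix.
#' @param labels n x K 0/1 matrix.
#' @param threshold decision threshold for SEN/F1/recall/accuracy.
#' @return a `metrics_report`: list with `macro_auc`, `sen`, `f1`, `recall`,
#'   `accuracy`, `map` (all in [0, 1]), `threshold`, `excluded_auc` (number
#'   of classes without both label values), `per_class` data frame.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L)
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1L)
  if (!all(dim(scores) == dim(labels)))
    stop("scores and labels must have identical shape", call. = FALSE)
  if (nrow(scores) < 2L)
    stop("need at least 2 samples", call. = FALSE)
  K <- ncol(scores)
  pred <- scores >= threshold
  per <- lapply(seq_len(K), function(k) {
    y <- labels[, k]; s <- scores[, k]; p <- pred[, k]
    tp <- sum(p & y == 1); fn <- sum(!p & y == 1); fp <- sum(p & y == 0)
    data.frame(
      class = k,
      auc = auc_rank(s, y),
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      f1 = if (tp + fn > 0) 2 * tp / max(2 * tp + fp + fn, 1) else NA_real_,
      accuracy = mean(p == (y == 1)),
      ap = average_precision(s, y))
  })
  per <- do.call(rbind, per)
  aucs <- per$auc[!is.na(per$auc)]
  if (length(aucs) == 0L)
    stop("every class column has a single label value; AUC undefined",
         call. = FALSE)
  structure(list(
    macro_auc = mean(aucs),
    sen = mean(per$recall, na.rm = TRUE),
    f1 = mean(per$f1, na.rm = TRUE),
    recall = mean(per$recall, na.rm = TRUE),
    accuracy = mean(per$accuracy),
    map = mean(per$ap, na.rm = TRUE),
    threshold = threshold,
    excluded_auc = sum(is.na(per$auc)),
    per_class = per), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("macro-AUC %.2f%%  SEN %.2f%%  F1 %.2f%%  ",
                     "recall %.2f%%  acc %.2f%%  mAP %.2f%% ",
                     "(threshold %.2f, %d class(es) excluded from AUC)\n"),
              100 * x$macro_auc, 100 * x$sen, 100 * x$f1, 100 * x$recall,
              100 * x$accuracy, 100 * x$map, x$threshold, x$excluded_auc))
  invisible(x)
}

#' Confounder-shift robustness protocol
#'
#' Evaluates a frozen model on freshly generated test sets whose
#' label-confounder correlation differs from the training one: an
#' in-distribution test set at `rho_train` and one shifted set per entry of
#' `rho_test_list` (e.g. `-rho_train` reverses the spurious association).
#' Reports per-metric drops (in-distribution minus shifted).
#'
#' @param state a trained `model_state`.
#' @param config a [synth_config()] describing the population.
#' @param rho_train the correlation the model was trained under.
#' @param rho_test_list numeric vector of shifted correlations.
#' @param n_test records per test set.
#' @param seed integer seed (paired across rho values: the same record seeds
#'   are reused so only the coupling changes).
#' @return list of `shift_report`s (one per `rho_test`): each has
#'   `rho_test`, `metrics_in_distribution`, `metrics_shifted`, `drop`.
#' @export
shift_protocol <- function(state, config, rho_train, rho_test_list,
                           n_test = 100L, seed = 1L) {
  stopifnot(inherits(state, "model_state"))
  if (state$epoch == 0L)
    stop("model is untrained; train it before the shift protocol",
         call. = FALSE)
  eval_at <- function(rho) {
    ds <- generate_dataset(config, n_test, rho = rho,
                           seed = derive_seed(seed, 555L))
    sc <- predict_model(state, ds$records)
    y <- do.call(rbind, lapply(ds$records, `[[`, "labels"))
    compute_metrics(sc, y)
  }
  m_in <- eval_at(rho_train)
  lapply(rho_test_list, function(rt) {
    m_sh <- eval_at(rt)
    keys <- c("macro_auc", "sen", "f1", "recall", "accuracy", "map")
    drop <- setNames(vapply(keys, function(k) m_in[[k]] - m_sh[[k]],
                            numeric(1)), keys)
    structure(list(rho_test = rt, metrics_in_distribution = m_in,
                   metrics_shifted = m_sh, drop = drop),
              class = "shift_report")
  })
}
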