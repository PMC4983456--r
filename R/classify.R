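#' Train a max-margin classifier on a precomputed Gram matrix
#'
#' Fits a C-SVC support vector machine in precomputed-kernel mode
#' (delegated to `kernlab::ksvm`).  When `derived_C` is set in the config,
#' the misclassification penalty is derived from the training labels as
#' `C = #negatives / #positives`, which counteracts class imbalance.
#'
#' @param gram Square kernel matrix over the training candidates.
#' @param labels Training labels, +1/-1 (numeric) or logical.
#' @param config A [ppi_config()].
#' @return A list of class `ppi_model`.
#' @export
ppi_train <- function(gram, labels, config = ppi_config()) {
  y <- ifelse(as_positive(labels), 1, -1)
  if (length(unique(y)) < 2L) {
    stop("training set must contain both classes")
  }
  stopifnot(nrow(gram) == length(y), ncol(gram) == length(y))
  C <- if (config$derived_C) sum(y < 0) / sum(y > 0) else config$C
  yf <- factor(ifelse(y > 0, "pos", "neg"), levels = c("neg", "pos"))
  K <- kernlab::as.kernelMatrix(unclass(gram))
  fit <- kernlab::ksvm(K, yf, type = "C-svc", C = C, prob.model = FALSE)
  sv <- kernlab::SVindex(fit)
  # orient the decision values so positive values mean the positive class
  d_train <- as.numeric(kernlab::predict(
    fit, kernlab::as.kernelMatrix(unclass(gram)[, sv, drop = FALSE]),
    type = "decision"
  ))
  acc_pos <- mean((d_train >= 0) == (y > 0))
  acc_neg <- mean((-d_train >= 0) == (y > 0))
  structure(
    list(
      fit = fit, sv = sv, orientation = if (acc_pos >= acc_neg) 1 else -1,
      C = C, n_train = length(y), train_labels = y
    ),
    class = "ppi_model"
  )
}

#' Predict labels from kernel rows
#'
#' @param model A `ppi_model`.
#' @param kernel_rows Matrix of kernel values, test candidates in rows and
#'   the model's training candidates in columns.
#' @param decision Also return decision values (default `FALSE`).
#' @return Integer vector of +1/-1 predictions (ties at decision value 0 go
#'   to +1), or a tibble with `pred` and `decision` columns.
#' @export
ppi_predict <- function(model, kernel_rows, decision = FALSE) {
  stopifnot(inherits(model, "ppi_model"))
  kernel_rows <- rbind(kernel_rows)
  if (ncol(kernel_rows) != model$n_train) {
    stop("kernel_rows must have one column per training candidate (",
         model$n_train, "), got ", ncol(kernel_rows))
  }
  d <- as.numeric(kernlab::predict(
    model$fit,
    kernlab::as.kernelMatrix(
      unclass(kernel_rows)[, model$sv, drop = FALSE]
    ),
    type = "decision"
  )) * model$orientation
  # decisions within solver tolerance of zero count as ties and go positive
  pred <- ifelse(d >= -1e-6, 1L, -1L)
  if (decision) {
    return(tibble::tibble(pred = pred, decision = d))
  }
  pred
}

#' Confusion counts and P/R/F1
#'
#' Computes the contingency counts of predictions against gold labels and
#' the derived precision, recall and F1.  A 0/0 precision or recall
#' (no positive predictions / no positive golds) is reported as 0 and
#' flagged in `precision_defined` / `recall_defined`.
#'
#' @param pred,gold Vectors of +1/-1 (or logical) labels, equal length.
#' @return One-row tibble of class `ppi_metrics` with columns `tp`, `fp`,
#'   `tn`, `fn`, `precision`, `recall`, `f1`, `precision_defined`,
#'   `recall_defined`.
#' @export
compute_metrics <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  p <- as_positive(pred)
  g <- as_positive(gold)
  tp <- sum(p & g)
  fp <- sum(p & !g)
  tn <- sum(!p & !g)
  fn <- sum(!p & g)
  metrics_from_counts(tp, fp, tn, fn)
}

metrics_from_counts <- function(tp, fp, tn, fn) {
  p_def <- (tp + fp) > 0
  r_def <- (tp + fn) > 0
  precision <- if (p_def) tp / (tp + fp) else 0
  recall <- if (r_def) tp / (tp + fn) else 0
  out <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    precision = precision, recall = recall,
    f1 = f1_from_pr(precision, recall),
    precision_defined = p_def, recall_defined = r_def
  )
  structure(out, class = c("ppi_metrics", class(out)))
}

#' F1 from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; accepts fractions or percentages and
#' returns the same scale.  0 when both inputs are 0.
#'
#' @param precision,recall Numeric vectors.
#' @return Numeric vector of F1 values.
#' @examples
#' f1_from_pr(73.2, 89.6) # 80.6 to one decimal
#' @export
f1_from_pr <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Micro-averaged F1 over corpora
#'
#' Two aggregation modes: `"pooled"` (default) sums TP/FP/FN over the
#' corpora and computes F1 from the pooled counts; `"printed"` evaluates
#' `sum_k 2 P_k R_k / sum_k (P_k + R_k)` on the per-corpus precision/recall
#' values.  The two agree on a single corpus and on identical corpora but
#' differ in general.
#'
#' @param per_corpus List (or tibble row-bound) of `ppi_metrics`.
#' @param mode `"pooled"` or `"printed"`.
#' @return Single numeric micro-average F1.
#' @export
micro_average <- function(per_corpus, mode = c("pooled", "printed")) {
  mode <- match.arg(mode)
  m <- if (is.data.frame(per_corpus)) per_corpus else dplyr::bind_rows(per_corpus)
  stopifnot(nrow(m) >= 1L)
  if (mode == "pooled") {
    pooled <- metrics_from_counts(sum(m$tp), sum(m$fp), sum(m$tn), sum(m$fn))
    return(pooled$f1)
  }
  sum(2 * m$precision * m$recall) / sum(m$precision + m$recall)
}
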