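#' Assemble a candidate-level corpus
#'
#' Bundles the candidate table with the per-sentence parse trees and
#' dependency graphs into the container the training and evaluation
#' functions consume.
#'
#' @param candidates Tibble with one row per candidate pair; required
#'   columns: `cand_id`, `sentence_id`, `text`, `tokens` (list of
#'   [tokenize_text()] tibbles), `p1`, `p2`, `m1`, `m2` (list-columns of
#'   token spans `c(start, end)`), `other_mentions` (list of span lists),
#'   `normalized` (list of character vectors), `label` (+1/-1, may be `NA`
#'   for unlabeled data).
#' @param trees List of `parse_node`, indexed by `sentence_id`.
#' @param deps List of `dependency_graph` (or `NULL`s), same indexing.
#' @param collection Optional source `bioc_collection`.
#' @return A list of class `ppi_corpus`.
#' @export
ppi_corpus <- function(candidates, trees, deps = NULL, collection = NULL) {
  needed <- c("cand_id", "sentence_id", "text", "tokens", "p1", "p2",
              "m1", "m2", "other_mentions", "normalized", "label")
  missing <- setdiff(needed, names(candidates))
  if (length(missing)) {
    stop("candidates is missing column(s): ", paste(missing, collapse = ", "))
  }
  structure(
    list(candidates = tibble::as_tibble(candidates), trees = trees,
         deps = deps, collection = collection),
    class = "ppi_corpus"
  )
}

#' @export
print.ppi_corpus <- function(x, ...) {
  lab <- x$candidates$label
  cat("<ppi_corpus> ", nrow(x$candidates), " candidates (",
      sum(lab > 0, na.rm = TRUE), " positive, ",
      sum(lab < 0, na.rm = TRUE), " negative) over ",
      length(x$trees), " sentences\n", sep = "")
  invisible(x)
}

corpus_sequences <- function(corpus, idx, lexicon) {
  lapply(idx, function(i) {
    label_semantic_classes(corpus$candidates$normalized[[i]], lexicon)
  })
}

corpus_stopwords <- function(corpus, idx, config) {
  sids <- unique(corpus$candidates$sentence_id[idx])
  pos_tab <- dplyr::bind_rows(lapply(corpus$trees[sids], tree_pos_tokens))
  prot <- unique(c(corpus$candidates$p1[idx], corpus$candidates$p2[idx]))
  build_stopword_list(pos_tab$word, pos_tab$pos, config,
                      protein_names = prot)
}

corpus_ipts <- function(corpus, idx, sequences, patterns, stopwords) {
  lapply(seq_along(idx), function(k) {
    i <- idx[k]
    row <- corpus$candidates[i, ]
    sid <- row$sentence_id
    construct_ipt(
      tree = corpus$trees[[sid]],
      m1 = row$m1[[1]], m2 = row$m2[[1]],
      deps = if (!is.null(corpus$deps)) corpus$deps[[sid]] else NULL,
      sc_seq = sequences[[k]],
      patterns = patterns, stopwords = stopwords,
      other_mentions = row$other_mentions[[1]]
    )
  })
}

#' Fit the full PPI extraction pipeline
#'
#' Runs every training-side stage on the selected candidates: semantic
#' class labeling, pattern mining, stop-word compilation, IPT construction,
#' Gram-matrix assembly and SVM training.  Only the selected (training)
#' candidates contribute to the mined patterns, the stop-word list and the
#' penalty C, so held-out data never leaks into the model.
#'
#' @param corpus A `ppi_corpus` with gold labels.
#' @param idx Integer indices of the training candidates (default: all).
#' @param config A [ppi_config()].
#' @param lexicon A `trigger_lexicon` (default: the shipped one).
#' @return A list of class `ppi_fit` carrying the model and every fitted
#'   artifact (patterns, stopwords, training IPTs).
#' @export
ppi_fit <- function(corpus, idx = NULL, config = ppi_config(),
                    lexicon = default_trigger_lexicon()) {
  stopifnot(inherits(corpus, "ppi_corpus"))
  if (is.null(idx)) idx <- seq_len(nrow(corpus$candidates))
  labels <- corpus$candidates$label[idx]
  sequences <- corpus_sequences(corpus, idx, lexicon)
  patterns <- mine_patterns(sequences, labels, config)
  stopwords <- corpus_stopwords(corpus, idx, config)
  ipts <- corpus_ipts(corpus, idx, sequences, patterns, stopwords)
  K <- gram_matrix(ipts, lambda = config$lambda_decay,
                   normalize = config$normalize_kernel)
  model <- ppi_train(K, labels, config)
  structure(
    list(model = model, patterns = patterns, stopwords = stopwords,
         lexicon = lexicon, config = config, idx = idx,
         ipts_train = ipts, gram_train = K),
    class = "ppi_fit"
  )
}

#' @export
print.ppi_fit <- function(x, ...) {
  cat("<ppi_fit> ", length(x$idx), " training candidates, ",
      nrow(x$patterns), " patterns, C = ",
      format(x$model$C, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict candidate labels with a fitted pipeline
#'
#' Builds test-side IPTs with the training-side patterns and stop words,
#' computes the cross kernel against the training IPTs and applies the SVM.
#'
#' @param fitted A `ppi_fit`.
#' @param corpus A `ppi_corpus` holding the test candidates (may be the
#'   training corpus).
#' @param idx Integer indices of the candidates to predict (default: all).
#' @return Tibble with `cand_id`, `pred` and `decision`.
#' @export
ppi_predict_corpus <- function(fitted, corpus, idx = NULL) {
  stopifnot(inherits(fitted, "ppi_fit"), inherits(corpus, "ppi_corpus"))
  if (is.null(idx)) idx <- seq_len(nrow(corpus$candidates))
  sequences <- corpus_sequences(corpus, idx, fitted$lexicon)
  ipts <- corpus_ipts(corpus, idx, sequences, fitted$patterns,
                      fitted$stopwords)
  K <- gram_cross(ipts, fitted$ipts_train,
                  lambda = fitted$config$lambda_decay,
                  normalize = fitted$config$normalize_kernel)
  out <- ppi_predict(fitted$model, K, decision = TRUE)
  out$cand_id <- corpus$candidates$cand_id[idx]
  out[, c("cand_id", "pred", "decision")]
}

stratified_folds <- function(labels, folds, seed) {
  y <- as_positive(labels)
  n <- length(y)
  assign <- integer(n)
  withr::local_seed(seed)
  if (min(sum(y), sum(!y)) < folds) {
    warning("a class has fewer members than folds; using plain folds")
    assign <- sample(rep_len(seq_len(folds), n))
  } else {
    for (cls in c(TRUE, FALSE)) {
      i <- which(y == cls)
      assign[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
  }
  assign
}

#' Cross-validation within a corpus
#'
#' Stratified, seeded k-fold cross-validation of the full pipeline.  Each
#' fold re-mines patterns and stop words from its training split only;
#' metrics are pooled over the held-out predictions of all folds.
#'
#' @param corpus A labeled `ppi_corpus`.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment (defaults to the config
#'   seed).
#' @param config A [ppi_config()].
#' @param lexicon A `trigger_lexicon`.
#' @return A list of class `ppi_eval`: pooled `metrics`, `per_fold`
#'   metrics, the fold assignment and the held-out `predictions`.
#' @export
ppi_cross_validate <- function(corpus, folds = 10, seed = NULL,
                               config = ppi_config(),
                               lexicon = default_trigger_lexicon()) {
  stopifnot(inherits(corpus, "ppi_corpus"))
  if (is.null(seed)) seed <- config$seed
  labels <- corpus$candidates$label
  assign <- stratified_folds(labels, folds, seed)
  preds <- vector("list", folds)
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(assign == f)
    train_idx <- which(assign != f)
    fitted <- ppi_fit(corpus, train_idx, config, lexicon)
    p <- ppi_predict_corpus(fitted, corpus, test_idx)
    p$gold <- labels[test_idx]
    p$fold <- f
    preds[[f]] <- p
    per_fold[[f]] <- dplyr::mutate(compute_metrics(p$pred, p$gold),
                                   fold = f, .before = 1L)
  }
  predictions <- dplyr::bind_rows(preds)
  structure(
    list(
      protocol = "cv",
      metrics = compute_metrics(predictions$pred, predictions$gold),
      per_fold = dplyr::bind_rows(per_fold),
      folds = assign,
      predictions = predictions
    ),
    class = "ppi_eval"
  )
}

#' Combine corpora into one
#'
#' @param corpora List of `ppi_corpus` objects.
#' @return A single `ppi_corpus` with re-indexed sentences and candidates.
#' @export
combine_corpora <- function(corpora) {
  stopifnot(length(corpora) >= 1L)
  trees <- list()
  deps <- list()
  cands <- list()
  offset <- 0L
  for (co in corpora) {
    cc <- co$candidates
    cc$sentence_id <- cc$sentence_id + offset
    cands[[length(cands) + 1L]] <- cc
    trees <- c(trees, co$trees)
    deps <- c(deps, if (is.null(co$deps)) {
      vector("list", length(co$trees))
    } else {
      co$deps
    })
    offset <- offset + length(co$trees)
  }
  cands <- dplyr::bind_rows(cands)
  cands$cand_id <- seq_len(nrow(cands))
  ppi_corpus(cands, trees, deps)
}

#' Cross-learning evaluation
#'
#' Holds out each corpus in turn and trains the full pipeline on the union
#' of the remaining corpora; patterns and stop words are re-mined from the
#' training union only.
#'
#' @param corpora Named list of labeled `ppi_corpus` objects (>= 2).
#' @param config A [ppi_config()].
#' @param lexicon A `trigger_lexicon`.
#' @return A `ppi_eval` with `per_corpus` metrics and pooled `metrics`.
#' @export
ppi_cross_learn <- function(corpora, config = ppi_config(),
                            lexicon = default_trigger_lexicon()) {
  stopifnot(length(corpora) >= 2L)
  nms <- names(corpora) %||% as.character(seq_along(corpora))
  per_corpus <- list()
  preds <- list()
  for (k in seq_along(corpora)) {
    train <- combine_corpora(corpora[-k])
    fitted <- ppi_fit(train, config = config, lexicon = lexicon)
    p <- ppi_predict_corpus(fitted, corpora[[k]])
    p$gold <- corpora[[k]]$candidates$label
    p$corpus <- nms[k]
    preds[[k]] <- p
    per_corpus[[k]] <- dplyr::mutate(compute_metrics(p$pred, p$gold),
                                     corpus = nms[k], .before = 1L)
  }
  predictions <- dplyr::bind_rows(preds)
  structure(
    list(
      protocol = "cl",
      metrics = compute_metrics(predictions$pred, predictions$gold),
      per_corpus = dplyr::bind_rows(per_corpus),
      predictions = predictions
    ),
    class = "ppi_eval"
  )
}

#' Cross-corpus evaluation
#'
#' Trains on each corpus alone and tests on every other corpus, giving the
#' full off-diagonal train-by-test matrix; diagonal cells can optionally be
#' filled with within-corpus cross-validation results.
#'
#' @param corpora Named list of labeled `ppi_corpus` objects (>= 2).
#' @param config A [ppi_config()].
#' @param lexicon A `trigger_lexicon`.
#' @param cv_diagonal Fill the diagonal with `folds`-fold CV F1 values
#'   (default `FALSE`, diagonal left `NA`).
#' @param folds Folds for the diagonal CV.
#' @return A list of class `ppi_eval` with an `f1` train-by-test matrix and
#'   a long `cells` tibble of per-cell metrics.
#' @export
ppi_cross_corpus <- function(corpora, config = ppi_config(),
                             lexicon = default_trigger_lexicon(),
                             cv_diagonal = FALSE, folds = 10) {
  stopifnot(length(corpora) >= 2L)
  nms <- names(corpora) %||% as.character(seq_along(corpora))
  n <- length(corpora)
  f1 <- matrix(NA_real_, n, n, dimnames = list(train = nms, test = nms))
  cells <- list()
  for (a in seq_len(n)) {
    fitted <- ppi_fit(corpora[[a]], config = config, lexicon = lexicon)
    for (b in seq_len(n)) {
      if (a == b) next
      p <- ppi_predict_corpus(fitted, corpora[[b]])
      m <- compute_metrics(p$pred, corpora[[b]]$candidates$label)
      f1[a, b] <- m$f1
      cells[[length(cells) + 1L]] <-
        dplyr::mutate(m, train = nms[a], test = nms[b], .before = 1L)
    }
  }
  if (cv_diagonal) {
    for (a in seq_len(n)) {
      cv <- ppi_cross_validate(corpora[[a]], folds = folds, config = config,
                               lexicon = lexicon)
      f1[a, a] <- cv$metrics$f1
    }
  }
  structure(
    list(protocol = "cc", f1 = f1, cells = dplyr::bind_rows(cells)),
    class = "ppi_eval"
  )
}

#' @export
print.ppi_eval <- function(x, ...) {
  cat("<ppi_eval> protocol: ", x$protocol, "\n", sep = "")
  if (x$protocol == "cc") {
    print(round(x$f1, 3))
  } else {
    m <- x$metrics
    cat(sprintf("  P = %.3f  R = %.3f  F1 = %.3f  (tp %d fp %d tn %d fn %d)\n",
                m$precision, m$recall, m$f1, m$tp, m$fp, m$tn, m$fn))
  }
  invisible(x)
}
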