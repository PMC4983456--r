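test_that("derived penalty is the negative/positive ratio", {
  # LLL-shaped labels: 164 positives, 166 negatives
  y <- c(rep(1, 164), rep(-1, 166))
  K <- diag(length(y))
  m <- ppi_train(K, y, ppi_config(derived_C = TRUE))
  expect_equal(m$C, 166 / 164, tolerance = 1e-12)

  yb <- rep(c(1, -1), 20)
  mb <- ppi_train(diag(length(yb)), yb, ppi_config(derived_C = TRUE))
  expect_equal(mb$C, 1.0)

  expect_error(ppi_train(diag(4), rep(1, 4), ppi_config()), "both classes")
})

make_separable <- function(n = 40, seed = 3) {
  # two tight kernel clusters: block-structured normalized Gram
  y <- rep(c(1, -1), each = n / 2)
  K <- outer(y, y, function(a, b) ifelse(a == b, 0.9, 0.1))
  diag(K) <- 1
  list(K = K, y = y)
}

test_that("separable Gram matrices give perfect training accuracy", {
  d <- make_separable()
  m <- ppi_train(d$K, d$y, ppi_config())
  pred <- ppi_predict(m, d$K)
  expect_identical(as.integer(pred), as.integer(d$y))
})

test_that("predictions are invariant to training order and break ties up", {
  d <- make_separable()
  m <- ppi_train(d$K, d$y, ppi_config())
  perm <- sample(seq_along(d$y))
  m2 <- ppi_train(d$K[perm, perm], d$y[perm], ppi_config())
  rows <- d$K[1:10, , drop = FALSE]
  expect_identical(
    ppi_predict(m, rows),
    ppi_predict(m2, rows[, perm, drop = FALSE])
  )
  # an all-zero kernel row on a symmetric balanced model: decision 0, tie
  # resolved to the positive class
  zrow <- matrix(0, 1, length(d$y))
  out <- ppi_predict(m, zrow, decision = TRUE)
  expect_equal(out$decision, 0, tolerance = 1e-6)
  expect_equal(out$pred, 1L)

  expect_error(ppi_predict(m, matrix(0, 1, 3)), "one column per")
})

test_that("metrics follow the printed formulas on random confusion tables", {
  m <- compute_metrics(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(m$tp, 1)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 1)
  expect_equal(m$tn, 1)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)

  withr::local_seed(17)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    pred <- sample(c(1, -1), n, replace = TRUE)
    gold <- sample(c(1, -1), n, replace = TRUE)
    mm <- compute_metrics(pred, gold)
    # harmonic-mean identity
    if (mm$precision + mm$recall > 0) {
      expect_equal(
        mm$f1,
        2 * mm$precision * mm$recall / (mm$precision + mm$recall),
        tolerance = 1e-12
      )
    }
    expect_equal(mm$tp + mm$fp + mm$tn + mm$fn, n)
  }

  perfect <- compute_metrics(c(1, -1, 1), c(1, -1, 1))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  none <- compute_metrics(c(-1, -1), c(1, -1))
  expect_equal(none$precision, 0)
  expect_false(none$precision_defined)
  expect_equal(none$recall, 0)
})

test_that("published precision/recall pairs recompute to the printed F1", {
  expect_equal(round(f1_from_pr(73.2, 89.6), 1), 80.6)
  expect_equal(round(f1_from_pr(62.5, 83.3), 1), 71.4)
  expect_equal(round(f1_from_pr(68.6, 70.3), 1), 69.4)
})

test_that("micro-average modes agree on single and identical corpora", {
  m1 <- compute_metrics(c(1, 1, -1, -1, 1), c(1, -1, -1, 1, 1))
  expect_equal(micro_average(list(m1), "pooled"), m1$f1)
  expect_equal(micro_average(list(m1), "printed"), m1$f1)
  expect_equal(micro_average(list(m1, m1), "pooled"), m1$f1)
  expect_equal(micro_average(list(m1, m1), "printed"), m1$f1)

  # pooled micro-average lies between the per-corpus extremes
  m2 <- compute_metrics(c(1, -1, -1, -1), c(1, 1, -1, -1))
  pooled <- micro_average(list(m1, m2), "pooled")
  expect_gte(pooled, min(m1$f1, m2$f1) - 1e-12)
  expect_lte(pooled, max(m1$f1, m2$f1))
})

test_that("cross-validation folds are disjoint, exhaustive, reproducible", {
  corpus <- tiny_corpus(n = 40, seed = 23)
  cfg <- ppi_config(seed = 23, support_min = 2)
  cv1 <- ppi_cross_validate(corpus, folds = 4, seed = 23, config = cfg)
  cv2 <- ppi_cross_validate(corpus, folds = 4, seed = 23, config = cfg)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$predictions$pred, cv2$predictions$pred)
  expect_setequal(unique(cv1$folds), 1:4)
  expect_length(cv1$folds, nrow(corpus$candidates))
  expect_setequal(cv1$predictions$cand_id, corpus$candidates$cand_id)
  expect_s3_class(tidy(cv1), "tbl_df")
  expect_equal(nrow(tidy(cv1)), 4L)
  # stratification keeps class mix in every fold
  for (f in 1:4) {
    lab <- corpus$candidates$label[cv1$folds == f]
    expect_true(any(lab > 0) && any(lab < 0))
  }
})

test_that("a class smaller than the fold count degrades with a warning", {
  corpus <- tiny_corpus(n = 24, seed = 29)
  keep_pos <- which(corpus$candidates$label > 0)[1:3]
  keep <- sort(c(keep_pos, which(corpus$candidates$label < 0)))
  corpus$candidates <- corpus$candidates[keep, ]
  corpus$candidates$cand_id <- seq_len(nrow(corpus$candidates))
  expect_warning(
    stratified_folds(corpus$candidates$label, folds = 8, seed = 1),
    "fewer members than folds"
  )
})

test_that("cross-learning trains on the union of the other corpora", {
  corpora <- list(
    a = tiny_corpus(n = 40, seed = 31),
    b = tiny_corpus(n = 40, seed = 32),
    c = tiny_corpus(n = 40, seed = 33)
  )
  cfg <- ppi_config(seed = 31, support_min = 5)
  cl <- ppi_cross_learn(corpora, config = cfg)
  expect_equal(nrow(cl$per_corpus), 3L)
  # shared planted patterns transfer across synthetic corpora
  expect_true(all(cl$per_corpus$f1 >= 0.9))
  expect_error(ppi_cross_learn(corpora[1]), ">= 2")
})

test_that("cross-corpus evaluation fills the off-diagonal matrix", {
  corpora <- list(
    a = tiny_corpus(n = 40, seed = 41),
    b = tiny_corpus(n = 40, seed = 42)
  )
  cfg <- ppi_config(seed = 41, support_min = 5)
  cc <- ppi_cross_corpus(corpora, config = cfg)
  expect_equal(dim(cc$f1), c(2L, 2L))
  expect_equal(sum(!is.na(cc$f1)), 2L) # the two off-diagonal cells
  expect_true(all(is.na(diag(cc$f1))))
  expect_equal(nrow(cc$cells), 2L)
  # shared planted patterns: transfer works in both directions
  expect_true(all(cc$cells$f1 >= 0.9))
})

test_that("tidiers and plots expose the fitted objects", {
  corpus <- tiny_corpus(n = 40, seed = 51)
  cfg <- ppi_config(seed = 51, support_min = 5)
  fit <- ppi_fit(corpus, config = cfg)
  g <- glance(fit)
  expect_equal(g$n_train, 40L)
  expect_gt(g$n_patterns, 0L)
  tp <- tidy(fit$patterns)
  expect_true(all(grepl("->", tp$pattern)))
  cv <- ppi_cross_validate(corpus, folds = 4, config = cfg)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(fit$patterns), "ggplot")
  expect_s3_class(autoplot(fit$gram_train), "ggplot")
})
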