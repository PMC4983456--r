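# direct evaluation of the printed four-factor likelihood-ratio expression;
# independent of the package's pooled/conditional log-likelihood route
llr_oracle <- function(n1, n2, k1, k2, eps = 1e-9) {
  clamp <- function(x) min(max(x, eps), 1 - eps)
  p <- clamp((k1 + k2) / (n1 + n2))
  p1 <- clamp(k1 / n1)
  p2 <- clamp(k2 / n2)
  num <- p^k1 * (1 - p)^(n1 - k1) * p^k2 * (1 - p)^(n2 - k2)
  den <- p1^k1 * (1 - p1)^(n1 - k1) * p2^k2 * (1 - p2)^(n2 - k2)
  -2 * log(num / den)
}

test_that("frequent-SC selection applies the cumulative and support rules", {
  seqs <- c(
    rep(list(c("A", "B")), 30),
    rep(list(c("A", "C")), 20),
    rep(list("A"), 0)
  )
  # frequencies in positives: A 50, B 30, C 20 (total 100)
  labels <- rep(1, length(seqs))
  got <- select_frequent_scs(seqs, labels, ppi_config())
  expect_identical(got, c("A", "B")) # A+B = 80% > 70%; C fails "more than 20"

  expect_identical(
    select_frequent_scs(rep(list("Z"), 100), rep(1, 100)), "Z"
  )
  # nothing above the support threshold
  expect_length(
    select_frequent_scs(rep(list(c("A", "B")), 10), rep(1, 10)), 0L
  )
  expect_error(select_frequent_scs(list(c("A")), -1), "no positive")
})

test_that("graph edges follow the confidence formula and thresholds", {
  cfg <- ppi_config()
  # 30 sequences with adjacent (A, B): confidence 1.0
  g1 <- build_semantic_graph(rep(list(c("A", "B")), 30), rep(1, 30),
                             c("A", "B"), cfg)
  expect_equal(nrow(g1$edges), 1L)
  expect_equal(g1$edges$support, 30L)
  expect_equal(g1$edges$confidence, 1.0)

  # support(A u B) = 20, support(A) = 40: confidence 0.5 kept (inclusive)
  seqs <- c(rep(list(c("A", "B")), 20), rep(list(c("A", "C")), 20))
  g2 <- build_semantic_graph(seqs, rep(1, 40), c("A", "B", "C"), cfg)
  ab <- g2$edges[g2$edges$to == "B", ]
  expect_equal(ab$confidence, 0.5)
  expect_equal(nrow(g2$edges), 2L)

  # support 19 is dropped regardless of confidence
  g3 <- build_semantic_graph(rep(list(c("A", "B")), 19), rep(1, 19),
                             c("A", "B"), cfg)
  expect_equal(nrow(g3$edges), 0L)
})

test_that("retained transition weights are row-stochastic", {
  withr::local_seed(11)
  for (rep in 1:10) {
    n_seq <- 60
    seqs <- replicate(n_seq, sample(LETTERS[1:4], sample(2:4, 1),
                                    replace = TRUE), simplify = FALSE)
    g <- build_semantic_graph(seqs, rep(1, n_seq), LETTERS[1:4],
                              ppi_config(support_min = 1,
                                         confidence_min = 0.1))
    if (!nrow(g$edges)) next
    sums <- tapply(g$edges$weight, g$edges$from, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("random walks enumerate chain paths and are seed-deterministic", {
  # deterministic chain A -> B -> C
  seqs <- rep(list(c("A", "B", "C")), 30)
  g <- build_semantic_graph(seqs, rep(1, 30), c("A", "B", "C"))
  pats <- random_walk_patterns(g, seed = 1)
  keys <- vapply(pats, paste, character(1), collapse = ">")
  expect_setequal(keys, c("A>B", "A>B>C", "B>C"))

  pats2 <- random_walk_patterns(g, seed = 1)
  expect_identical(pats, pats2)

  empty_graph <- build_semantic_graph(list(c("A")), 1, "A")
  expect_length(random_walk_patterns(empty_graph, seed = 1), 0L)
})

test_that("random walks cover the full path set of small DAGs", {
  # branching DAG with all-retained edges; oracle = exhaustive enumeration
  seqs <- c(
    rep(list(c("A", "B", "D")), 25),
    rep(list(c("A", "C", "D")), 25)
  )
  g <- build_semantic_graph(seqs, rep(1, 50), c("A", "B", "C", "D"))
  enumerate_paths <- function(edges) {
    out <- list()
    grow <- function(path) {
      nxt <- edges$to[edges$from == path[length(path)]]
      for (v in nxt) {
        out[[length(out) + 1L]] <<- c(path, v)
        grow(c(path, v))
      }
    }
    for (v in unique(c(edges$from, edges$to))) grow(v)
    out
  }
  oracle <- enumerate_paths(g$edges)
  got <- random_walk_patterns(g, seed = 4)
  okeys <- sort(vapply(oracle, paste, character(1), collapse = ">"))
  gkeys <- sort(vapply(got, paste, character(1), collapse = ">"))
  expect_identical(gkeys, unique(okeys))
})

test_that("pattern merging reproduces the two worked examples", {
  m1 <- merge_patterns(list(
    c("PROTEIN1", "Binding"),
    c("PROTEIN1", "Binding", "Regulation", "Transcription", "PROTEIN2")
  ))
  expect_length(m1, 1L)
  expect_identical(
    m1[[1]],
    c("PROTEIN1", "Binding", "Regulation", "Transcription", "PROTEIN2")
  )

  m2 <- merge_patterns(list(
    c("Positive_regulation", "Regulation"),
    c("Regulation", "Gene_expression", "PROTEIN1")
  ))
  expect_length(m2, 1L)
  expect_identical(
    m2[[1]],
    c("Positive_regulation", "Regulation", "Gene_expression", "PROTEIN1")
  )

  single <- list(c("A", "B", "C"))
  expect_identical(merge_patterns(single), single)
})

test_that("pattern merging is idempotent on random pattern sets", {
  withr::local_seed(21)
  for (rep in 1:20) {
    pats <- replicate(6, sample(LETTERS[1:5], sample(2:4, 1),
                                replace = TRUE), simplify = FALSE)
    once <- merge_patterns(pats)
    expect_identical(merge_patterns(once), once)
  }
})

test_that("LLR is zero at equal rates and matches the printed expression", {
  expect_equal(llr_score(10, 10, 5, 5), 0)
  expect_equal(llr_score(20, 10, 10, 5), 0, tolerance = 1e-12)

  expect_equal(llr_score(10, 10, 8, 2), llr_oracle(10, 10, 8, 2),
               tolerance = 1e-9)
  for (k in c(1, 3, 7, 9)) {
    expect_equal(llr_score(10, 12, k, 12 - k), llr_oracle(10, 12, k, 12 - k),
                 tolerance = 1e-9)
  }
  expect_error(llr_score(0, 0, 0, 0), "at least one")
})

test_that("LLR grows with rate separation and with evidence", {
  # separation sweep at fixed margins
  vals <- vapply(0:5, function(d) llr_score(10, 10, 5 + d, 5 - d), numeric(1))
  expect_true(all(diff(vals) > 0))
  # all-positive occurrence with smoothing: large and monotone in n
  vals2 <- vapply(2:20, function(n) llr_score(n, n, n, 0), numeric(1))
  expect_true(all(vals2 > 0))
  expect_true(all(diff(vals2) > 0))
})

test_that("pattern ranking keeps top k with the documented tie-breaks", {
  llr <- tibble::tibble(label = c("A", "B", "C"), llr = c(3, 2, 1))
  pats <- c(
    replicate(25, sample(c("A", "B", "C"), 2), simplify = FALSE)
  )
  got <- rank_and_select_patterns(unique(pats), llr, k = 20)
  expect_lte(nrow(got), 20L)
  expect_true(all(diff(got$score) <= 0))

  few <- rank_and_select_patterns(list(c("A", "B"), c("B", "C")), llr, k = 20)
  expect_equal(nrow(few), 2L)

  # equal score: longer pattern ranks first
  llr2 <- tibble::tibble(label = c("A", "B", "Z"), llr = c(2, 2, 0))
  tie <- rank_and_select_patterns(
    list(c("A", "B"), c("A", "Z", "Z", "B")), llr2, k = 20
  )
  expect_length(tie$labels[[1]], 4L)
  # unknown labels contribute zero, not NA
  expect_true(all(is.finite(tie$score)))
})

test_that("pattern matching is ordered-subsequence containment", {
  fig5 <- c("PROTEIN1", "Binding", "PROTEIN2", "Antagonist")
  expect_true(match_pattern(c("PROTEIN1", "Binding", "PROTEIN2"), fig5))
  expect_false(match_pattern(c(fig5, "Extra"), fig5))
  # dynamic-programming subsequence oracle on random cases
  is_subseq <- function(p, s) {
    i <- 1L
    j <- 1L
    while (i <= length(p) && j <= length(s)) {
      if (p[i] == s[j]) i <- i + 1L
      j <- j + 1L
    }
    i > length(p)
  }
  withr::local_seed(9)
  for (rep in 1:100) {
    s <- sample(LETTERS[1:4], sample(3:8, 1), replace = TRUE)
    p <- sample(LETTERS[1:4], sample(1:4, 1), replace = TRUE)
    expect_identical(match_pattern(p, s), is_subseq(p, s))
  }
})

test_that("mined top patterns cover planted patterns on synthetic corpora", {
  corpus <- tiny_corpus(n = 300, seed = 13)
  lex <- default_trigger_lexicon()
  seqs <- lapply(corpus$candidates$normalized, label_semantic_classes,
                 lexicon = lex)
  pats <- mine_patterns(seqs, corpus$candidates$label, ppi_config(seed = 13))
  expect_gt(nrow(pats), 0L)
  for (p in fixture_spec()$planted_patterns) {
    expect_true(any(vapply(
      pats$labels, function(b) pattern_contained(p, b), logical(1)
    )))
  }
})
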