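creb <- worked_example_fixtures()$creb_cbp

test_that("SPET is the mention-bounded lowest-common-ancestor subtree", {
  spet <- extract_spet(creb$tree, creb$m1, creb$m2)
  leaves <- tree_leaves(spet)
  expect_false("tightened" %in% leaves) # follows CBP, outside the span
  expect_false("Active" %in% leaves) # precedes CREB
  # leaf set = exactly the tokens between and including the two mentions
  all_tokens <- tree_leaves(creb$tree)
  expect_identical(leaves, all_tokens[(creb$m1[1] + 1):creb$m2[2]])

  # both mentions under one NP: that subtree comes back
  t <- read_bracketed_tree("(S (NP (NN A) (CC and) (NN B)) (VP (VB act)))")
  spet2 <- extract_spet(t, c(0L, 1L), c(2L, 3L))
  expect_equal(spet2$label, "NP")
  expect_identical(tree_leaves(spet2), c("A", "and", "B"))

  expect_error(extract_spet(t, c(5L, 6L), c(7L, 8L)), "not found")
})

test_that("branching appends a trailing verb that shares a covering VP", {
  spet <- extract_spet(creb$tree, creb$m1, creb$m2)
  branched <- ipt_branch(spet, creb$tree, creb$m2)
  expect_true("tightened" %in% tree_leaves(branched))

  # sentence ending at the second mention: identity
  t <- read_bracketed_tree("(S (NP (NN A)) (VP (VB binds) (NP (NN B))))")
  spet2 <- extract_spet(t, c(0L, 1L), c(2L, 3L))
  expect_identical(
    write_bracketed_tree(ipt_branch(spet2, t, c(2L, 3L))),
    write_bracketed_tree(spet2)
  )

  # verb after the mention but in a clause whose VP does not cover it
  t2 <- read_bracketed_tree(paste0(
    "(S (S (NP (NN A)) (VP (VB binds) (NP (NN B)))) (CC but)",
    " (S (NP (NN C)) (VP (VB left))))"
  ))
  spet3 <- extract_spet(t2, c(0L, 1L), c(2L, 3L))
  expect_identical(
    write_bracketed_tree(ipt_branch(spet3, t2, c(2L, 3L))),
    write_bracketed_tree(spet3)
  )
})

test_that("protein dependency path matches the worked example", {
  path <- protein_dependency_path(creb$deps, creb$m1, creb$m2)
  expect_identical(
    creb$deps$tokens[path + 1],
    c("CREB", "effects", "genes", "interaction", "CBP")
  )

  g <- read_dependency_graph("A\tbinds\tB\nnsubj\t1\t0\ndobj\t1\t2\n")
  expect_identical(protein_dependency_path(g, 0L, 1L), c(0L, 1L))
  g2 <- dependency_graph(c("A", "B"), tibble::tibble(
    relation = character(), governor = integer(), dependent = integer()
  ))
  expect_length(protein_dependency_path(g2, 0L, 1L), 0L)
})

test_that("middle clauses off the dependency path are pruned", {
  spet <- extract_spet(creb$tree, creb$m1, creb$m2)
  path <- protein_dependency_path(creb$deps, creb$m1, creb$m2)
  pruned <- prune_middle_clauses(spet, path, creb$m1, creb$m2)
  expect_false("important" %in% tree_leaves(pruned))
  expect_false("development" %in% tree_leaves(pruned))
  # tokens on the path always survive
  expect_true(all(c("CREB", "effects", "genes", "interaction", "CBP") %in%
                    tree_leaves(pruned)))

  # a clause containing a dep-path token is retained: reuse the tree with a
  # path running through the clause's span
  fake_path <- c(creb$m1[1], 7L, creb$m2[1])
  kept <- prune_middle_clauses(spet, fake_path, creb$m1, creb$m2)
  expect_true("important" %in% tree_leaves(kept))

  # empty path disables the operator
  same <- prune_middle_clauses(spet, integer(0), creb$m1, creb$m2)
  expect_identical(write_bracketed_tree(same), write_bracketed_tree(spet))
})

test_that("stop-word list: cumulative cutoff, verb and protein exclusion", {
  tokens <- c(rep("the", 50), rep("of", 30), rep("binds", 15),
              rep("PROTEIN1", 5))
  pos <- c(rep("DT", 50), rep("IN", 30), rep("VBZ", 15), rep("NN", 5))
  sw <- build_stopword_list(tokens, pos, ppi_config())
  expect_setequal(unclass(sw), c("the", "of"))

  # every word a verb: empty list
  sw2 <- build_stopword_list(c("binds", "binds"), c("VBZ", "VBZ"),
                             ppi_config())
  expect_length(sw2, 0L)

  # 'with' is listed when frequent in the fixture-derived corpus
  pos_tab <- tree_pos_tokens(creb$tree)
  many <- dplyr::bind_rows(
    pos_tab,
    tibble::tibble(word = rep("with", 5), pos = rep("IN", 5))
  )
  sw3 <- build_stopword_list(many$word, many$pos, ppi_config())
  expect_true("with" %in% sw3)
})

test_that("stop-word pruning removes leaves and emptied ancestors only", {
  t <- read_bracketed_tree(
    "(NP (NP (NN interaction)) (PP (IN with) (NP (NN CBP))))"
  )
  out <- prune_stopwords(t, c("with"))
  expect_false("with" %in% tree_leaves(out))
  expect_false(grepl("(IN", write_bracketed_tree(out), fixed = TRUE))

  expect_identical(
    write_bracketed_tree(prune_stopwords(t, c("zebra"))),
    write_bracketed_tree(t)
  )

  # cascade never removes protein leaves, on random trees with protected
  # leaves spliced in
  withr::local_seed(15)
  for (i in 1:15) {
    t <- pn("S", pn("NP", pn("NN", "PROTEIN1")), random_tree(5),
            pn("NP", pn("NN", "PROTEIN2")))
    out <- prune_stopwords(t, c("a", "b", "to", "red", "binds"))
    expect_true(all(c("PROTEIN1", "PROTEIN2") %in% tree_leaves(out)))
  }
})

test_that("duplicate unary same-label chains collapse to a fixed point", {
  t <- read_bracketed_tree("(VP (VP (VB binds)))")
  expect_identical(
    write_bracketed_tree(remove_duplicate_nodes(t)), "(VP (VB binds))"
  )
  t2 <- read_bracketed_tree("(S (NP (NN a)) (VP (VB b)))")
  expect_identical(
    write_bracketed_tree(remove_duplicate_nodes(t2)),
    write_bracketed_tree(t2)
  )
  t3 <- read_bracketed_tree("(X (X (X leaf)))")
  expect_identical(
    write_bracketed_tree(remove_duplicate_nodes(t3)), "(X leaf)"
  )
  no_unary_same_label <- function(node) {
    if (pn_is_leaf(node)) return(TRUE)
    if (length(node$children) == 1L && !pn_is_leaf(node$children[[1]]) &&
        identical(node$children[[1]]$label, node$label)) {
      return(FALSE)
    }
    all(vapply(node$children, no_unary_same_label, logical(1)))
  }
  withr::local_seed(31)
  for (i in 1:20) {
    expect_true(no_unary_same_label(remove_duplicate_nodes(random_tree(8))))
  }
})

test_that("ornamenting appends one IP child per matched pattern, in order", {
  t <- read_bracketed_tree("(S (NP (NN PROTEIN1)) (VP (VB binds)))")
  o1 <- ornament(t, "1")
  expect_equal(sum(vapply(o1$children, function(ch) ch$label == "IP",
                          logical(1))), 1L)
  o0 <- ornament(t, character(0))
  expect_equal(sum(vapply(o0$children, function(ch) ch$label == "IP",
                          logical(1))), 0L)
  o3 <- ornament(t, c("1", "2", "3"))
  ips <- Filter(function(ch) ch$label == "IP", o3$children)
  expect_length(ips, 3L)
  expect_identical(
    vapply(ips, function(ch) ch$children[[1]]$word, character(1)),
    c("1", "2", "3")
  )
})

test_that("full IPT construction on the CREB/CBP sentence", {
  lex <- default_trigger_lexicon()
  toks <- tokenize_text(creb$text)
  m <- find_protein_mentions(list(text = creb$text, tokens = toks),
                             creb$proteins)
  norm <- normalize_candidate(toks, m, "CREB", "CBP")
  seq <- label_semantic_classes(norm, lex)
  pats <- structure(
    tibble::tibble(rank = 1L, score = 1,
                   labels = list(c("PROTEIN1", "Binding", "PROTEIN2"))),
    class = c("interaction_patterns", "tbl_df", "tbl", "data.frame")
  )
  ipt <- construct_ipt(
    creb$tree, creb$m1, creb$m2, deps = creb$deps, sc_seq = seq,
    patterns = pats, stopwords = c("with", "the", "to", "via", ","),
    other_mentions = list()
  )
  leaves <- tree_leaves(ipt)
  expect_true("tightened" %in% leaves) # branching
  expect_false("important" %in% leaves) # middle clause pruned
  expect_false("with" %in% leaves) # stop word pruned
  expect_true("PROTEIN1" %in% leaves && "PROTEIN2" %in% leaves)
  expect_identical(attr(ipt, "ip_tags"), "1") # ornament matched

  # deterministic: two runs byte-identical
  ipt2 <- construct_ipt(
    creb$tree, creb$m1, creb$m2, deps = creb$deps, sc_seq = seq,
    patterns = pats, stopwords = c("with", "the", "to", "via", ","),
    other_mentions = list()
  )
  expect_identical(write_bracketed_tree(ipt), write_bracketed_tree(ipt2))

  # minimal sentence passes through unchanged apart from normalization
  t <- read_bracketed_tree(
    "(S (NP (NN PROTEIN1)) (VP (VB binds) (NP (NN PROTEIN2))))"
  )
  ipt3 <- construct_ipt(t, c(0L, 1L), c(2L, 3L))
  expect_identical(write_bracketed_tree(ipt3), write_bracketed_tree(t))
})

test_that("pruning operators are idempotent and keep the protein pair", {
  spet <- extract_spet(creb$tree, creb$m1, creb$m2)
  path <- protein_dependency_path(creb$deps, creb$m1, creb$m2)
  p1 <- prune_middle_clauses(spet, path, creb$m1, creb$m2)
  expect_identical(
    write_bracketed_tree(prune_middle_clauses(p1, path, creb$m1, creb$m2)),
    write_bracketed_tree(p1)
  )
  sw <- c("with", "the")
  s1 <- prune_stopwords(p1, sw)
  expect_identical(
    write_bracketed_tree(prune_stopwords(s1, sw)),
    write_bracketed_tree(s1)
  )
  d1 <- remove_duplicate_nodes(s1)
  expect_identical(
    write_bracketed_tree(remove_duplicate_nodes(d1)),
    write_bracketed_tree(d1)
  )
  expect_true(all(c("CREB", "CBP") %in% tree_leaves(d1)))
})
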