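# Shared helpers: tiny XML fixtures and random tree generation for
# property-style tests.

bioc_xml_fixture <- function() {
  fx <- worked_example_fixtures()
  text <- fx$sec24p$text
  locs <- lapply(fx$sec24p$proteins, function(p) {
    s <- regexpr(p, text, fixed = TRUE)[1] - 1L
    c(s, s + nchar(p))
  })
  anns <- paste(vapply(seq_along(locs), function(i) {
    sprintf(
      paste0("<annotation id=\"a%d\"><infon key=\"type\">protein</infon>",
             "<location offset=\"%d\" length=\"%d\"/><text>%s</text>",
             "</annotation>"),
      i, locs[[i]][1], locs[[i]][2] - locs[[i]][1], fx$sec24p$proteins[i]
    )
  }, character(1)), collapse = "")
  sprintf(
    paste0("<collection><document><id>d1</id><passage><offset>0</offset>",
           "<text>%s</text>%s</passage></document></collection>"),
    text, anns
  )
}

# random small parse tree over a fixed grammar-ish vocabulary; leaves drawn
# from a small word set so random pairs share fragments
random_tree <- function(max_nodes = 8) {
  labels <- c("S", "NP", "VP", "PP")
  pos <- c("NN", "VB", "IN", "JJ")
  words <- c("a", "b", "binds", "to", "red")
  build <- function(budget, depth) {
    if (budget <= 1L || depth > 3L || stats::runif(1) < 0.4) {
      return(list(node = pn(sample(pos, 1), sample(words, 1)), used = 1L))
    }
    n_children <- sample(1:2, 1)
    used <- 1L
    kids <- list()
    for (i in seq_len(n_children)) {
      res <- build(budget - used - (n_children - i), depth + 1L)
      kids[[i]] <- res$node
      used <- used + res$used
    }
    list(node = do.call(pn, c(list(sample(labels, 1)), kids)), used = used)
  }
  repeat {
    t <- build(max_nodes, 1L)$node
    if (tree_size(t) <= max_nodes) {
      return(t)
    }
  }
}

tiny_corpus <- function(n = 60, seed = 42) {
  generate_corpus(fixture_spec(n_sentences = n, seed = seed))
}

# contiguous containment of a label sequence inside another
pattern_contained <- function(small, big) {
  grepl(
    paste0("\r", paste(small, collapse = "\r"), "\r"),
    paste0("\r", paste(big, collapse = "\r"), "\r"),
    fixed = TRUE
  )
}
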