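#' Specification of a synthetic corpus
#'
#' Describes a seeded synthetic PPI corpus: each sentence mentions two
#' distinct protein names; positives realize one of the planted interaction
#' patterns as ordered trigger words around the pair, negatives use
#' non-trigger verbs, so pattern presence separates the classes by
#' construction.  Parse trees and dependency graphs are derived
#' deterministically from the sentence templates, which removes any parser
#' dependency.
#'
#' @param n_sentences Number of sentences (ignored when `n_pos`/`n_neg` are
#'   given).
#' @param p_positive Probability that a sentence is positive.
#' @param n_protein_names Size of the protein name pool.
#' @param planted_patterns List of SC label sequences; each must start with
#'   `PROTEIN1`, contain `PROTEIN2` and at least one trigger class.  The
#'   defaults are two nested variants of a binding pattern with a skewed
#'   frequency split, emulating the Zipf-like rank-frequency distribution
#'   of interaction patterns in real corpora; the skew keeps every planted
#'   pattern's association-rule edges above the default support and
#'   confidence thresholds, so the mining stage can recover them.
#' @param pattern_weights Sampling weights over `planted_patterns`
#'   (normalized internally).
#' @param noise_word_rate Probability of decorating a sentence with an
#'   adverb and/or a trailing prepositional phrase.
#' @param context_trigger_rate Probability that a sentence opens with an
#'   unrelated event mention ("After transcription analysis, ...") drawn
#'   from trigger classes outside the planted patterns.  Biomedical prose
#'   is trigger-dense, and these context events give the semantic-class
#'   frequency distribution the heavy Zipf-like tail the frequent-SC
#'   selection rule assumes; without them a handful of universal classes
#'   would always absorb the whole cumulative-frequency budget.
#' @param seed Integer seed; the same spec always generates a byte-identical
#'   corpus.
#' @param n_pos,n_neg Exact class counts (optional); when given, the corpus
#'   has exactly these many positives and negatives.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_sentences = 100,
                         p_positive = 0.5,
                         n_protein_names = 20,
                         planted_patterns = list(
                           c("PROTEIN1", "Binding", "PROTEIN2"),
                           c("PROTEIN1", "Binding", "PROTEIN2",
                             "Localization")
                         ),
                         pattern_weights = NULL,
                         noise_word_rate = 0.3,
                         context_trigger_rate = 0.8,
                         seed = 1L,
                         n_pos = NULL, n_neg = NULL) {
  stopifnot(p_positive >= 0, p_positive <= 1, n_protein_names >= 2)
  if (is.null(pattern_weights)) {
    pattern_weights <- if (length(planted_patterns) == 2L) {
      c(0.4, 0.6)
    } else {
      rep(1, length(planted_patterns))
    }
  }
  stopifnot(length(pattern_weights) == length(planted_patterns))
  if ((p_positive > 0 || isTRUE(n_pos > 0)) && !length(planted_patterns)) {
    stop("planted_patterns must be nonempty when positives are requested")
  }
  for (p in planted_patterns) {
    if (p[1] != "PROTEIN1" || !"PROTEIN2" %in% p ||
        !length(setdiff(p, c("PROTEIN1", "PROTEIN2", "PROTEIN")))) {
      stop(
        "each planted pattern must start with PROTEIN1, contain PROTEIN2 ",
        "and at least one trigger class: ", paste(p, collapse = "->")
      )
    }
  }
  structure(
    list(
      n_sentences = n_sentences, p_positive = p_positive,
      n_protein_names = n_protein_names,
      planted_patterns = planted_patterns,
      pattern_weights = pattern_weights / sum(pattern_weights),
      noise_word_rate = noise_word_rate,
      context_trigger_rate = context_trigger_rate,
      seed = as.integer(seed),
      n_pos = n_pos, n_neg = n_neg
    ),
    class = "fixture_spec"
  )
}

# surface realizations of trigger classes: verbs for classes between the
# pair, nouns for classes after PROTEIN2; all stem onto the default lexicon
trigger_verbs <- list(
  Binding = c("binds", "interacts"),
  Regulation = c("regulates", "modulates"),
  Positive_regulation = c("activates", "stimulates"),
  Negative_regulation = c("inhibits", "reduces"),
  Gene_expression = c("expresses", "coexpresses"),
  Transcription = c("transcribes", "transcribes"),
  Localization = c("secretes", "releases"),
  Antagonist = c("antagonizes", "antagonizes")
)
trigger_nouns <- list(
  Binding = "binding", Regulation = "regulation",
  Positive_regulation = "activation", Negative_regulation = "inhibition",
  Gene_expression = "expression", Transcription = "transcription",
  Localization = "secretion", Antagonist = "antagonists"
)
negative_verbs <- c("resembles", "precedes", "accompanies", "follows")
noise_adverbs <- c("strongly", "rapidly", "weakly", "specifically")
noise_nouns <- c("liver", "muscle", "brain", "yeast")

# one template-derived sentence: tokens, bracketed tree and dependencies
synth_sentence <- function(positive, pattern, a, b, noise_rate,
                           context_class = NULL) {
  sep <- which(pattern == "PROTEIN2")[1]
  middle <- if (positive) {
    scs <- pattern[seq(2, sep - 1)]
    scs <- scs[!scs %in% c("PROTEIN", "PROTEIN1", "PROTEIN2")]
    unname(vapply(scs, function(sc) sample(trigger_verbs[[sc]], 1L),
                  character(1)))
  } else {
    sample(negative_verbs, 1L)
  }
  trailing <- if (positive && sep < length(pattern)) {
    scs <- pattern[seq(sep + 1, length(pattern))]
    scs <- scs[!scs %in% c("PROTEIN", "PROTEIN1", "PROTEIN2")]
    unname(vapply(scs, function(sc) trigger_nouns[[sc]], character(1)))
  } else {
    character(0)
  }
  adverb <- if (stats::runif(1) < noise_rate) sample(noise_adverbs, 1L)
  pp_noun <- if (stats::runif(1) < noise_rate) sample(noise_nouns, 1L)

  tokens <- character(0)
  s_kids <- list()
  dep <- list()
  if (!is.null(context_class)) {
    cn <- trigger_nouns[[context_class]]
    tokens <- c("After", cn, "analysis", ",")
    s_kids <- list(
      pn("PP", pn("IN", "After"),
         pn("NP", pn("NN", cn), pn("NN", "analysis"))),
      pn(",", ",")
    )
    dep <- list(c("case", 2L, 0L), c("compound", 2L, 1L))
  }
  a_idx <- length(tokens)
  tokens <- c(tokens, a)
  vp_kids <- list()
  v1 <- length(tokens) # 0-based index of the first verb
  for (vi in seq_along(middle)) {
    if (vi > 1L) {
      tokens <- c(tokens, "and")
      vp_kids <- c(vp_kids, list(pn("CC", "and")))
    }
    vp_kids <- c(vp_kids, list(pn("VBZ", middle[vi])))
    vidx <- length(tokens)
    tokens <- c(tokens, middle[vi])
    if (vi > 1L) {
      dep <- c(dep, list(c("conj", v1, vidx)))
    }
  }
  bidx <- length(tokens)
  tokens <- c(tokens, b)
  vp_kids <- c(vp_kids, list(pn("NP", pn("NN", b))))
  for (tn in trailing) {
    tidx <- length(tokens)
    tokens <- c(tokens, "via", tn)
    vp_kids <- c(vp_kids, list(
      pn("PP", pn("IN", "via"), pn("NP", pn("NN", tn)))
    ))
    dep <- c(dep, list(c("case", tidx + 1L, tidx),
                       c("nmod", v1, tidx + 1L)))
  }
  if (!is.null(adverb)) {
    aidx <- length(tokens)
    tokens <- c(tokens, adverb)
    vp_kids <- c(vp_kids, list(pn("ADVP", pn("RB", adverb))))
    dep <- c(dep, list(c("advmod", v1, aidx)))
  }
  if (!is.null(pp_noun)) {
    iidx <- length(tokens)
    tokens <- c(tokens, "in", pp_noun, "cells")
    vp_kids <- c(vp_kids, list(
      pn("PP", pn("IN", "in"),
         pn("NP", pn("NN", pp_noun), pn("NNS", "cells")))
    ))
    dep <- c(dep, list(
      c("case", iidx + 2L, iidx),
      c("compound", iidx + 2L, iidx + 1L),
      c("nmod", v1, iidx + 2L)
    ))
  }
  tokens <- c(tokens, ".")
  dep <- c(dep,
           list(c("nsubj", v1, a_idx), c("dobj", v1, bidx),
                c("punct", v1, length(tokens) - 1L)))
  if (!is.null(context_class)) {
    dep <- c(dep, list(c("nmod", v1, 2L), c("punct", v1, 3L)))
  }
  tree <- do.call(pn, c(
    list("S"), s_kids,
    list(pn("NP", pn("NN", a)),
         do.call(pn, c(list("VP"), vp_kids)),
         pn(".", "."))
  ))
  deps <- dependency_graph(
    tokens,
    tibble::tibble(
      relation = vapply(dep, `[[`, character(1), 1L),
      governor = as.integer(vapply(dep, `[[`, "0", 2L)),
      dependent = as.integer(vapply(dep, `[[`, "0", 3L))
    )
  )
  list(tokens = tokens, tree = tree, deps = deps,
       a = a, b = b, a_idx = 0L, b_idx = bidx)
}

#' Generate a synthetic labeled corpus
#'
#' Realizes a [fixture_spec()]: samples labels (Bernoulli with
#' `p_positive`, or exact counts), draws protein pairs and templates, and
#' emits the sentence text, a BioC-style collection with protein
#' annotations, gold labels, template-derived parse trees and dependency
#' graphs, assembled into a `ppi_corpus`.  Identical specs generate
#' identical corpora.
#'
#' @param spec A [fixture_spec()].
#' @return A `ppi_corpus`; candidate labels are +1 for planted-pattern
#'   sentences and -1 otherwise.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::local_seed(spec$seed)
  labels <- if (!is.null(spec$n_pos) && !is.null(spec$n_neg)) {
    sample(c(rep(1L, spec$n_pos), rep(-1L, spec$n_neg)))
  } else {
    ifelse(stats::runif(spec$n_sentences) < spec$p_positive, 1L, -1L)
  }
  names_pool <- sprintf("PROT%d", seq_len(spec$n_protein_names))
  n <- length(labels)
  trees <- vector("list", n)
  deps <- vector("list", n)
  cands <- vector("list", n)
  passages <- vector("list", n)
  annotations <- vector("list", n)
  for (i in seq_len(n)) {
    ab <- sample(names_pool, 2L)
    pattern <- spec$planted_patterns[[
      sample.int(length(spec$planted_patterns), 1L,
                 prob = spec$pattern_weights)
    ]]
    context_pool <- setdiff(names(trigger_nouns),
                            unlist(spec$planted_patterns))
    context_class <- if (length(context_pool) &&
                         stats::runif(1) < spec$context_trigger_rate) {
      sample(context_pool, 1L)
    }
    s <- synth_sentence(labels[i] > 0, pattern, ab[1], ab[2],
                        spec$noise_word_rate, context_class)
    text <- sub(" \\.$", ".", paste(s$tokens, collapse = " "))
    tokens <- tokenize_text(text)
    mentions <- find_protein_mentions(list(text = text, tokens = tokens),
                                      c(s$a, s$b))
    cand <- enumerate_candidates(list(text = text, tokens = tokens),
                                 mentions)
    normalized <- normalize_candidate(tokens, mentions, cand$p1[1],
                                      cand$p2[1])
    trees[[i]] <- s$tree
    deps[[i]] <- s$deps
    doc_id <- sprintf("synth%04d", i)
    passages[[i]] <- tibble::tibble(
      doc_id = doc_id, passage_index = 1L, offset = 0L, text = text
    )
    annotations[[i]] <- tibble::tibble(
      doc_id = doc_id, passage_index = 1L,
      ann_id = sprintf("%s.a%d", doc_id, seq_len(nrow(mentions))),
      surface = mentions$surface, start = mentions$start,
      end = mentions$end
    )
    cands[[i]] <- tibble::tibble(
      cand_id = i, sentence_id = i, text = text, tokens = list(tokens),
      p1 = cand$p1[1], p2 = cand$p2[1],
      m1 = list(c(cand$p1_token_start[1], cand$p1_token_end[1])),
      m2 = list(c(cand$p2_token_start[1], cand$p2_token_end[1])),
      other_mentions = list(list()),
      normalized = list(normalized),
      label = labels[i]
    )
  }
  ppi_corpus(
    dplyr::bind_rows(cands), trees, deps,
    collection = new_bioc_collection(
      dplyr::bind_rows(passages), dplyr::bind_rows(annotations)
    )
  )
}

#' Hand-authored worked-example fixtures
#'
#' Three small fixtures used throughout the documentation and tests:
#' `creb_cbp` (a two-clause sentence expressing a CREB/CBP interaction,
#' with its constituency parse and typed dependencies), `gp130_hlif` (the
#' gp130/hLIF binding-site sentence with three protein annotations) and
#' `sec24p` (a sentence mentioning Sec24p, Iss1p and Sec16p).
#'
#' @return Named list of fixtures; each holds `text`, `proteins` and where
#'   applicable `tree` (a `parse_node`), `deps` (a `dependency_graph`) and
#'   the target mention token spans `m1`, `m2`.
#' @export
worked_example_fixtures <- function() {
  creb_text <- paste0(
    "Active, phosphorylated CREB, which is important to brain development,",
    " effects CRE-dependent genes via interaction with CBP which tightened",
    " the connection between CREB and downstream components."
  )
  creb_tree <- read_bracketed_tree(paste0(
    "(S (NP (NP (JJ Active) (, ,) (JJ phosphorylated) (NN CREB) (, ,))",
    " (SBAR (WHNP (WDT which)) (S (VP (VBZ is) (ADJP (JJ important)",
    " (PP (TO to) (NP (NN brain) (NN development))))))) (, ,))",
    " (VP (VBZ effects) (NP (JJ CRE-dependent) (NNS genes))",
    " (PP (IN via) (NP (NP (NN interaction)) (PP (IN with)",
    " (NP (NP (NN CBP)) (SBAR (WHNP (WDT which)) (S (VP (VBD tightened)",
    " (NP (NP (DT the) (NN connection)) (PP (IN between)",
    " (NP (NN CREB) (CC and) (JJ downstream) (NNS components))))))))))))",
    " (. .))"
  ))
  creb_deps <- dependency_graph(
    tree_leaves(creb_tree),
    tibble::tribble(
      ~relation, ~governor, ~dependent,
      "amod", 3L, 0L,
      "amod", 3L, 2L,
      "ref", 3L, 5L,
      "nsubj", 7L, 5L,
      "cop", 7L, 6L,
      "acl:relcl", 3L, 7L,
      "case", 10L, 8L,
      "compound", 10L, 9L,
      "nmod", 7L, 10L,
      "conj", 3L, 12L,
      "amod", 14L, 13L,
      "dobj", 12L, 14L,
      "case", 16L, 15L,
      "nmod", 14L, 16L,
      "case", 18L, 17L,
      "nmod", 16L, 18L,
      "acl:relcl", 18L, 20L,
      "nsubj", 20L, 19L,
      "det", 22L, 21L,
      "dobj", 20L, 22L,
      "case", 24L, 23L,
      "nmod", 22L, 24L,
      "cc", 24L, 25L,
      "amod", 27L, 26L,
      "conj", 24L, 27L
    )
  )
  gp_text <- paste0(
    "Abolition of the gp130 binding site in hLIF created antagonists of",
    " LIF action"
  )
  sec_text <- paste0(
    "We have identified a third Sec24p family member, which we call Iss1p,",
    " as a protein that binds to Sec16p."
  )
  list(
    creb_cbp = list(
      text = creb_text,
      proteins = c("CREB", "CBP"),
      tree = creb_tree,
      deps = creb_deps,
      m1 = c(3L, 4L),
      m2 = c(18L, 19L)
    ),
    gp130_hlif = list(
      text = gp_text,
      proteins = c("gp130", "hLIF", "LIF")
    ),
    sec24p = list(
      text = sec_text,
      proteins = c("Sec24p", "Iss1p", "Sec16p")
    )
  )
}
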