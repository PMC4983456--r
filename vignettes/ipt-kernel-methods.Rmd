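---
title: "Interaction pattern trees and the convolution kernel: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction pattern trees and the convolution kernel: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipeppi)
```

## The task and the model

pipeppi treats PPI passage extraction as binary classification of
*candidate pairs*: a sentence together with one ordered pair of the
distinct protein names it mentions.  A sentence with `k` distinct names
contributes `choose(k, 2)` independent candidates, so a sentence can
assert an interaction for one pair and not another.  The model combines
three information sources:

* **Content** — the ordered sequence of semantic classes (SCs) obtained by
  Porter-stemming each token of the normalized sentence and looking the
  stem up in a trigger lexicon.  Stemming collapses inflectional synonyms
  ("binds", "binding" → class Binding), which is the assumption that makes
  frequency statistics over SCs meaningful at corpus sizes of a few
  hundred sentences.
* **Semantics** — interaction patterns: short SC sequences frequent in
  positive sentences.  Pattern mining assumes the rank-frequency
  distribution of SCs is Zipf-like, so a cumulative-frequency prefix
  captures the classes that matter.  The directed SC graph is built from
  *adjacent* precedence within positive sequences (association-rule bigrams);
  this is deliberately conservative — the later merging step is defined on
  bigrams, and skip-gram co-occurrence would double-count long-range pairs.
* **Syntax** — the interaction pattern tree: the shortest-path-enclosed
  subtree (SPET) of the constituency parse between the two mentions,
  repaired and condensed by four operators (branching, middle-clause
  pruning, stop-word pruning, duplicate-node collapsing) and decorated
  with `IP` tags for matched patterns.  Similarity between IPTs is the
  subset-tree convolution kernel, and a support vector machine in
  precomputed-kernel mode separates the classes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `support_min` | 20 | minimum association-rule support (sequence count); SCs must occur *strictly more* than this often |
| `confidence_min` | 0.5 | minimum rule confidence `support(SC_i ∪ SC_j) / support(SC_i)`; the threshold is inclusive |
| `sc_cumfreq` | 0.70 | cumulative-frequency cutoff for frequent SCs, over positive sentences |
| `stopword_cumfreq` | 0.80 | cumulative-frequency cutoff for the stop-word list, over the whole training corpus |
| `top_k_patterns` | 20 | mined patterns retained after LLR ranking |
| `lambda_decay` | 0.4 | kernel decay `λ`; larger fragments are damped by `λ^(#productions)` |
| `normalize_kernel` | TRUE | divide by `sqrt(K(T1,T1) K(T2,T2))` so self-similarity is 1 |
| `derived_C` | TRUE | SVM penalty `C = #neg/#pos` from the training labels |

The support/confidence pair, the two cumulative cutoffs, the top-20
retention and `λ = 0.4` are the published settings of the method this
package implements; they are exposed, not re-tuned.  `C = #neg/#pos`
counteracts class imbalance: corpora in this field range from balanced
(LLL-like, ratio ≈ 1.01) to heavily negative (AIMed-like, ratio ≈ 4.8).

Threshold boundary semantics deserve one note, because the package pins
them in tests: SC frequency must be *strictly greater* than
`support_min` ("more than 20"), edge support is `≥ support_min`,
confidence is `≥ confidence_min`, and the frequent-SC prefix is the
smallest one whose cumulative frequency *first exceeds* the cutoff while
the stop-word prefix *reaches* it.

## The kernel, precisely

For trees `T1, T2` with labeled node sets `N1, N2` (internal and
pre-terminal nodes; lexical leaves fold into their pre-terminal's
production),

```
K(T1, T2) = Σ_{n1 ∈ N1, n2 ∈ N2} Δ(n1, n2)
Δ(n1, n2) = 0                      if productions differ
          = λ                      if both are pre-terminals
          = λ Π_k (1 + Δ(ch_k, ch_k))   otherwise
```

The child product is only ever evaluated on equal-arity nodes: differing
child counts already imply differing productions, hence `Δ = 0`.  `Δ` is
evaluated once per node pair over a post-order flattening, giving the
`O(|N1|·|N2|)` cost; Gram assembly additionally deduplicates serialized
trees, which makes template-derived corpora cheap.  The package carries an
independent oracle, `enumerate_subset_trees()` plus
`subset_tree_inner_product()`: explicit enumeration of every
grammar-preserving fragment with weight `λ^(#productions)`.  The test
suite asserts exact agreement between the recursion and the oracle on
randomized small trees; that equivalence, not any single worked value, is
the kernel's correctness argument.

`IP` ornament nodes participate in the kernel as ordinary nodes — that is
the mechanism by which two candidates matching the same mined pattern
become more similar.  Kernel normalization defaults to on, the standard
control for sentence-length effects in tree kernels; the raw-value mode is
kept because the printed kernel equations are unnormalized.

## IPT operator order and degenerate inputs

The composition is fixed: SPET → branching → middle-clause pruning →
stop-word pruning → duplicate collapsing → ornamenting.  Branching must
precede pruning (the branched verb phrase is itself prunable); duplicate
collapsing must come after both pruning steps, which are what create
unary same-label chains; ornamenting is last so tags are never pruned.
Each pruning operator is idempotent, and none can remove the protein
pair: stop-word lists exclude protein labels by construction, and clause
pruning only deletes subtrees strictly between the mentions.

Degenerate inputs skip the affected operator instead of failing: a
missing or disconnected dependency graph disables middle-clause pruning
(an empty shortest path carries no evidence about which clause is
irrelevant), a sentence ending at the second mention leaves branching as
the identity, and an empty stop-word list or pattern set is legal.
Clause detection is structural: `SBAR`-labeled nodes.  Mention heads for
the dependency lookup are the last token of multi-token mentions.
The shortest dependency path is found by breadth-first search traversing
edges in both directions (typed-dependency arrows mix directions along
exactly the paths of interest), with ties broken toward the
lexicographically smallest token-index sequence — hence the hand-written
BFS with sorted adjacency rather than a generic graph library call.

One representational choice: the normalized token list must stay parallel
to the sentence tokens, so every token of a multi-token mention receives
the placeholder label and SCL collapses consecutive identical protein
placeholders into one label.

## The LLR statistic

Pattern ranking scores each SC by
`-2 log [ L(pooled) / L(conditional) ]`, the likelihood-ratio statistic
comparing a single occurrence rate `p(SC)` against separate rates
`p(SC|I)`, `p(SC|¬I)` in positive and negative sentences, all estimated
by maximum likelihood.  It is 0 exactly when the conditional rates are
equal and strictly increases with their separation.  Degenerate MLE rates
(0 or 1) are clamped to `[ε, 1-ε]` with `ε = 1e-9`, keeping the statistic
finite for classes that occur only in positives — which are precisely the
interesting ones.  A pattern's score is the sum of its member classes'
LLR values; classes unseen at scoring time contribute 0.  Ties are broken
toward longer patterns (more specific), then lexicographically.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` produces labeled corpora in which positives realize a
planted SC pattern as ordered trigger words around a protein pair and
negatives pair proteins with non-trigger verbs.  Design choices, made
once:

* **Study conditions.** The default corpus size used by the end-to-end
  checks is 400 sentences at `p_positive = 0.5` — the scale of the
  standard PPI benchmark corpora (LLL has 330 labeled pairs, IEPA 817),
  and comfortably above the mining thresholds.  An exact-count mode
  (`n_pos`, `n_neg`) reproduces specific corpus shapes.
* **Skewed nested patterns.** The default planted patterns are two nested
  variants, `[PROTEIN1, Binding, PROTEIN2]` and
  `[PROTEIN1, Binding, PROTEIN2, Localization]`, sampled 0.4/0.6.  Real
  pattern frequencies are Zipf-like, and the association-rule stage
  *requires* a dominant continuation at each graph vertex: a uniform mix
  of patterns with distinct first triggers splits
  `confidence(PROTEIN1 ⇒ ·)` below any threshold ≥ 0.5, making recovery
  of every pattern impossible for any implementation.  Nesting with a
  skewed split is the realistic construction under which the mining
  stage's own contract (every planted pattern, or a merged superpattern
  containing it, reaches the top-k) is satisfiable.
* **Context triggers.** Sentences open, at rate 0.8, with an unrelated
  leading event mention ("After transcription analysis, …") drawn from
  classes outside the planted patterns.  Biomedical prose is
  trigger-dense, and these context events give the SC frequency
  distribution the heavy tail the 70% cumulative rule assumes; with only
  the three universal classes present, no fourth class could ever enter
  the frequent prefix.  Because the context mention precedes `PROTEIN1`,
  it can never complete a planted pattern in a negative.
* **Deterministic template parses.** Trees and dependencies are derived
  from the sentence templates in code, so no parser is bundled and the
  same seed yields a byte-identical corpus.

What passing tests on this corpus do **not** show: robustness to parser
errors, to trigger-lexicon gaps, to coreferent mentions, to interactions
asserted across sentence boundaries, or to the annotation-policy
heterogeneity that makes real cross-corpus transfer hard.  The generator
is linearly separable by construction (the pattern-presence oracle
achieves F1 = 1), so cross-validated F1 near 1 validates the plumbing and
the leakage discipline — patterns, stop words and `C` re-derived per
training split — not the method's real-world accuracy.  Reproducing
published benchmark figures requires the original corpora, parser and
lexicon, which are out of scope here.

## Micro-averaging: two modes

`micro_average()` implements both the pooled-count definition (F1 from
summed TP/FP/FN) and the printed-formula variant
`Σ_k 2 P_k R_k / Σ_k (P_k + R_k)`.  The two agree on one corpus and on
identical corpora but diverge in general, and published per-corpus P/R
tables in this literature are not always consistent with their printed
micro-average column under either reading; both modes are therefore
exposed and the package takes no position on which a given table used.

## Known limitations

* Trigger lexicon: the shipped TSV is an illustrative unigram lexicon
  over the event classes the method names; it is user-replaceable and no
  claim of coverage is made.  Multi-word triggers are unsupported.
* Fig-style normalization: all non-pair protein mentions become
  `PROTEIN`, including in the semantic sequence; a candidate's sequence
  may therefore end in `PROTEIN` even when the pair pattern has matched.
* The random-walk harvest is stochastic; the `4u²` step budget with
  restarts at every frequent SC and its out-neighbours empirically covers
  small graphs' full path set (asserted against exhaustive enumeration on
  DAGs in the tests), but coverage on large cyclic graphs is
  probabilistic.
* Decision values within `1e-6` of zero are treated as ties and resolved
  to the positive class; this absorbs quadratic-programming solver noise
  around the documented all-zero-kernel-row tie case.
* Sentence splitting is rule-based (decimals, "et al.", initials, a fixed
  abbreviation list) and will over- or under-split on patterns outside
  those rules.
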