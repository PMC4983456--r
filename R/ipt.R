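#' Extract the shortest-path-enclosed tree (SPET)
#'
#' Returns the smallest subtree of a sentence's constituency parse that
#' links the two target protein mentions: the lowest common ancestor of the
#' mention leaves, restricted to the token interval
#' `[start(m1), end(m2))` — leaves before the first mention or after the
#' second are dropped, and internal nodes left without children disappear.
#' Token spans on the surviving nodes keep their original sentence indices.
#'
#' @param tree A `parse_node` for the full sentence.
#' @param m1,m2 Target mention token spans `c(start, end)` (0-based
#'   half-open), `m1` first in the text.
#' @return A `parse_node`.
#' @export
extract_spet <- function(tree, m1, m2) {
  stopifnot(inherits(tree, "parse_node"))
  s <- as.integer(m1[1])
  e <- as.integer(m2[2])
  if (s >= e || tree$start > s || tree$end < e) {
    stop("mention spans [", s, ", ", e, ") not found in the parse tree")
  }
  lca <- tree
  repeat {
    inside <- Filter(
      function(ch) ch$start <= s && ch$end >= e,
      lca$children
    )
    if (length(inside) == 1L && !pn_is_leaf(inside[[1]])) {
      lca <- inside[[1]]
    } else {
      break
    }
  }
  out <- pn_span_filter(lca, s, e)
  if (is.null(out)) {
    stop("SPET extraction removed every leaf; invalid mention spans")
  }
  out
}

# keep only leaves inside [s, e); drop emptied nodes
pn_span_filter <- function(node, s, e) {
  if (pn_is_leaf(node)) {
    if (node$start >= s && node$end <= e) {
      return(node)
    }
    return(NULL)
  }
  kept <- Filter(Negate(is.null), lapply(node$children, pn_span_filter, s, e))
  if (!length(kept)) {
    return(NULL)
  }
  node$children <- kept
  node$start <- kept[[1]]$start
  node$end <- kept[[length(kept)]]$end
  node
}

#' Branch a trailing verb onto the IPT
#'
#' The SPET stops at the second mention, which can cut off a verb that
#' carries the interaction ("... with CBP which tightened ...").  The
#' branching operator looks for the first verb (POS tag starting `VB`) after
#' the last target protein that shares a `VP` ancestor covering the mention
#' in the full parse; if found, the verb's pre-terminal, wrapped in its `VP`
#' spine, is appended as a final child of the IPT root.  Otherwise the IPT
#' is returned unchanged.
#'
#' @param ipt The SPET `parse_node`.
#' @param full_tree The full sentence `parse_node`.
#' @param m2 Second mention token span `c(start, end)`.
#' @return A `parse_node`.
#' @export
ipt_branch <- function(ipt, full_tree, m2) {
  verbs <- pn_preterminals_with_ancestors(full_tree)
  for (v in verbs) {
    node <- v$node
    if (node$start < m2[2]) next
    if (!startsWith(node$label, "VB")) next
    covers <- any(vapply(v$ancestors, function(a) {
      a$label == "VP" && a$start <= m2[1] && a$end >= m2[2]
    }, logical(1)))
    if (covers) {
      wrap <- structure(
        list(label = "VP", children = list(node), word = NULL,
             start = node$start, end = node$end),
        class = "parse_node"
      )
      ipt$children <- c(ipt$children, list(wrap))
      ipt$end <- max(ipt$end, node$end)
      return(ipt)
    }
  }
  ipt
}

# pre-terminals in leaf order, each with its ancestor chain (root first)
pn_preterminals_with_ancestors <- function(node, ancestors = list()) {
  if (pn_is_leaf(node)) {
    return(list())
  }
  if (pn_is_preterminal(node)) {
    return(list(list(node = node, ancestors = ancestors)))
  }
  unlist(
    lapply(node$children, pn_preterminals_with_ancestors,
           ancestors = c(ancestors, list(node))),
    recursive = FALSE
  )
}

#' Prune middle clauses off the protein dependency path
#'
#' Deletes every clause subtree (`SBAR`-labeled node) lying strictly between
#' the two mentions whose token span contains no token of the protein
#' dependency path: such clauses cannot make the target proteins associated.
#' An empty dependency path (disconnected mentions) disables the operator.
#'
#' @param ipt A `parse_node`.
#' @param dep_path Integer vector of 0-based token indices from
#'   [protein_dependency_path()].
#' @param m1,m2 Target mention token spans `c(start, end)`.
#' @return A `parse_node`.
#' @export
prune_middle_clauses <- function(ipt, dep_path, m1, m2) {
  if (!length(dep_path)) {
    return(ipt)
  }
  keep <- function(node) {
    if (pn_is_leaf(node)) {
      return(node)
    }
    middle <- node$start >= m1[2] && node$end <= m2[1]
    if (startsWith(node$label %||% "", "SBAR") && middle &&
        !any(dep_path >= node$start & dep_path < node$end)) {
      return(NULL)
    }
    kept <- Filter(Negate(is.null), lapply(node$children, keep))
    if (!length(kept)) {
      return(NULL)
    }
    node$children <- kept
    node
  }
  out <- keep(ipt)
  if (is.null(out)) ipt else out
}

#' Build a stop-word list from corpus frequencies
#'
#' Sorts words by descending corpus frequency and keeps the smallest prefix
#' whose cumulative frequency reaches the `stopword_cumfreq` fraction
#' (default 80%) of the total word count; verbs (any occurrence tagged
#' `VB*`) and protein placeholders/names are then excluded, since both are
#' key constructs of interactions.  Entries are stored as Porter stems.
#'
#' @param tokens Character vector: the corpus token stream (lowercased
#'   internally).
#' @param pos Character vector of POS tags parallel to `tokens`.
#' @param config A [ppi_config()].
#' @param protein_names Additional protein surface forms to exclude.
#' @return Character vector of stems, class `stopword_list`.
#' @export
build_stopword_list <- function(tokens, pos, config = ppi_config(),
                                protein_names = character()) {
  stopifnot(length(tokens) == length(pos), length(tokens) >= 1L)
  word <- tolower(tokens)
  freq <- sort(table(word), decreasing = TRUE)
  cum <- cumsum(as.integer(freq))
  cut <- which(cum >= config$stopword_cumfreq * sum(freq))[1]
  kept <- names(freq)[seq_len(cut)]
  verbs <- unique(word[startsWith(pos, "VB")])
  proteins <- tolower(c("PROTEIN1", "PROTEIN2", "PROTEIN", protein_names))
  kept <- setdiff(kept, c(verbs, proteins))
  structure(unique(porter_stem(kept)), class = "stopword_list")
}

#' Prune stop-word leaves from an IPT
#'
#' Removes every leaf whose Porter stem is in the stop-word list, together
#' with any ancestor left childless by the removal.  Protein placeholder
#' leaves are never stop words, so the mention pair always survives.
#'
#' @param ipt A `parse_node`.
#' @param stopwords A `stopword_list` (or character vector of stems).
#' @return A `parse_node`.
#' @export
prune_stopwords <- function(ipt, stopwords) {
  protected <- c("PROTEIN1", "PROTEIN2", "PROTEIN")
  strip <- function(node) {
    if (pn_is_leaf(node)) {
      if (!node$word %in% protected &&
          porter_stem(tolower(node$word)) %in% stopwords) {
        return(NULL)
      }
      return(node)
    }
    kept <- Filter(Negate(is.null), lapply(node$children, strip))
    if (!length(kept)) {
      return(NULL)
    }
    node$children <- kept
    node
  }
  out <- strip(ipt)
  if (is.null(out)) ipt else out
}

#' Collapse duplicate unary nodes
#'
#' A node is duplicated when it is the single child of a parent carrying the
#' same label; such chains add no structure but inflate kernel overlap.
#' Every parent -> single-child chain with equal labels is collapsed (the
#' child removed and its children promoted), applied to a fixed point, so
#' the output contains no unary same-label edge.
#'
#' @param ipt A `parse_node`.
#' @return A `parse_node`.
#' @export
remove_duplicate_nodes <- function(ipt) {
  if (pn_is_leaf(ipt)) {
    return(ipt)
  }
  ipt$children <- lapply(ipt$children, remove_duplicate_nodes)
  while (length(ipt$children) == 1L &&
         !pn_is_leaf(ipt$children[[1]]) &&
         identical(ipt$children[[1]]$label, ipt$label)) {
    ipt$children <- ipt$children[[1]]$children
  }
  ipt
}

#' Ornament an IPT with matched interaction patterns
#'
#' For every mined pattern that matches the candidate's semantic-class
#' sequence, one `IP` node carrying the pattern id is appended as a child of
#' the tree root, in pattern rank order.  The tags take part in the kernel
#' like ordinary nodes, which is how shared interaction semantics raises the
#' similarity of two candidates.
#'
#' @param ipt A `parse_node`.
#' @param matched_pattern_ids Character or integer vector of matched pattern
#'   ids (ranks), in rank order.
#' @return A `parse_node` of class `ipt` with attribute `ip_tags`.
#' @export
ornament <- function(ipt, matched_pattern_ids) {
  for (id in matched_pattern_ids) {
    tag <- structure(
      list(label = "IP",
           children = list(pn_leaf(as.character(id))),
           word = NULL, start = ipt$end, end = ipt$end),
      class = "parse_node"
    )
    ipt$children <- c(ipt$children, list(tag))
  }
  class(ipt) <- unique(c("ipt", class(ipt)))
  attr(ipt, "ip_tags") <- as.character(matched_pattern_ids)
  ipt
}

# replace leaf words inside a token span with a placeholder label
pn_substitute_span <- function(node, span_start, span_end, label) {
  if (pn_is_leaf(node)) {
    if (node$start >= span_start && node$end <= span_end) {
      node$word <- label
    }
    return(node)
  }
  node$children <- lapply(node$children, pn_substitute_span,
                          span_start, span_end, label)
  node
}

#' Construct the interaction pattern tree of a candidate
#'
#' Full IPT pipeline for one expanded candidate, applied in the fixed order
#' SPET extraction, branching, middle-clause pruning, stop-word pruning,
#' duplicate-node collapsing, ornamenting.  Mention leaves are normalized to
#' `PROTEIN1` / `PROTEIN2` / `PROTEIN` placeholders so candidates with
#' different protein names remain comparable under the kernel.  Degenerate
#' inputs (no dependency graph, disconnected mentions) skip the affected
#' operator rather than fail.
#'
#' @param tree Full-sentence `parse_node`.
#' @param m1,m2 Target mention token spans `c(start, end)`, `m1` first.
#' @param deps Optional `dependency_graph` for the sentence.
#' @param sc_seq The candidate's `sc_sequence` (for pattern matching).
#' @param patterns An `interaction_patterns` tibble (may be empty or
#'   `NULL`).
#' @param stopwords A `stopword_list` (may be empty or `NULL`).
#' @param other_mentions Optional list of further protein mention token
#'   spans to normalize to `PROTEIN`.
#' @return A `parse_node` of class `ipt`.
#' @export
construct_ipt <- function(tree, m1, m2, deps = NULL, sc_seq = NULL,
                          patterns = NULL, stopwords = NULL,
                          other_mentions = list()) {
  ipt <- extract_spet(tree, m1, m2)
  ipt <- ipt_branch(ipt, tree, m2)
  dep_path <- if (!is.null(deps)) {
    protein_dependency_path(deps, m1, m2)
  } else {
    integer(0)
  }
  ipt <- prune_middle_clauses(ipt, dep_path, m1, m2)
  if (!is.null(stopwords) && length(stopwords)) {
    ipt <- prune_stopwords(ipt, stopwords)
  }
  ipt <- remove_duplicate_nodes(ipt)
  ipt <- pn_substitute_span(ipt, m1[1], m1[2], "PROTEIN1")
  ipt <- pn_substitute_span(ipt, m2[1], m2[2], "PROTEIN2")
  for (om in other_mentions) {
    ipt <- pn_substitute_span(ipt, om[1], om[2], "PROTEIN")
  }
  matched <- character(0)
  if (!is.null(patterns) && nrow(patterns) && !is.null(sc_seq)) {
    hit <- vapply(patterns$labels, match_pattern, logical(1), seq = sc_seq)
    matched <- patterns$rank[hit]
  }
  ornament(ipt, matched)
}
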