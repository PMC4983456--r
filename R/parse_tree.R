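#' Parse-tree nodes
#'
#' Constituency trees are represented as nested lists of class `parse_node`.
#' An internal node has a `label` (phrase or POS tag) and ordered `children`;
#' a terminal node carries the token text in `word`.  After construction every
#' node holds the half-open token-index span `[start, end)` it covers, which
#' the IPT operators use to reason about mention positions and clause extents.
#'
#' @param label Node label (phrase tag such as `"NP"` or POS tag such as
#'   `"NN"`).
#' @param ... Child nodes, either `parse_node` objects or single strings
#'   (coerced to terminals).
#' @return A `parse_node`.
#' @examples
#' pn("NP", pn("NN", "PROTEIN1"))
#' @export
pn <- function(label, ...) {
  children <- lapply(list(...), function(ch) {
    if (inherits(ch, "parse_node")) ch else pn_leaf(ch)
  })
  node <- structure(
    list(label = label, children = children, word = NULL,
         start = NA_integer_, end = NA_integer_),
    class = "parse_node"
  )
  pn_index(node, 0L)$node
}

pn_leaf <- function(word) {
  structure(
    list(label = NULL, children = list(), word = as.character(word),
         start = NA_integer_, end = NA_integer_),
    class = "parse_node"
  )
}

pn_is_leaf <- function(node) !is.null(node$word)

pn_is_preterminal <- function(node) {
  !pn_is_leaf(node) && length(node$children) == 1L &&
    pn_is_leaf(node$children[[1]])
}

# assign 0-based token-index spans in leaf order
pn_index <- function(node, next_idx) {
  if (pn_is_leaf(node)) {
    node$start <- next_idx
    node$end <- next_idx + 1L
    return(list(node = node, next_idx = next_idx + 1L))
  }
  for (k in seq_along(node$children)) {
    res <- pn_index(node$children[[k]], next_idx)
    node$children[[k]] <- res$node
    next_idx <- res$next_idx
  }
  node$start <- if (length(node$children)) node$children[[1]]$start else next_idx
  node$end <- next_idx
  list(node = node, next_idx = next_idx)
}

#' Read a Penn-bracketed parse tree
#'
#' @param text A balanced Penn-bracketed string, e.g.
#'   `"(S (NP (NN a)) (VP (VB binds) (NP (NN b))))"`.
#' @return A `parse_node` with token spans assigned in leaf order.
#' @examples
#' read_bracketed_tree("(NP (NN PROTEIN1))")
#' @export
read_bracketed_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- pn_lex(text)
  if (!nrow(toks)) {
    stop("empty parse-tree string")
  }
  res <- pn_parse(toks, 1L, text)
  if (res$pos <= nrow(toks)) {
    stop(sprintf(
      "unbalanced parse tree: trailing input at character %d",
      toks$at[res$pos]
    ))
  }
  pn_index(res$node, 0L)$node
}

pn_lex <- function(text) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(tok = character(), at = integer()))
  }
  data.frame(
    tok = regmatches(text, list(m))[[1]],
    at = as.integer(m),
    stringsAsFactors = FALSE
  )
}

pn_parse <- function(toks, pos, text) {
  if (pos > nrow(toks)) {
    stop(sprintf(
      "unbalanced parse tree: unexpected end of input at character %d",
      nchar(text) + 1L
    ))
  }
  tok <- toks$tok[pos]
  if (tok == ")") {
    stop(sprintf(
      "unbalanced parse tree: unexpected ')' at character %d", toks$at[pos]
    ))
  }
  if (tok != "(") {
    return(list(node = pn_leaf(tok), pos = pos + 1L))
  }
  pos <- pos + 1L
  if (pos > nrow(toks) || toks$tok[pos] %in% c("(", ")")) {
    stop(sprintf(
      "parse tree node missing label at character %d",
      if (pos > nrow(toks)) nchar(text) + 1L else toks$at[pos]
    ))
  }
  label <- toks$tok[pos]
  pos <- pos + 1L
  children <- list()
  repeat {
    if (pos > nrow(toks)) {
      stop(sprintf(
        "unbalanced parse tree: missing ')' at character %d", nchar(text) + 1L
      ))
    }
    if (toks$tok[pos] == ")") {
      pos <- pos + 1L
      break
    }
    res <- pn_parse(toks, pos, text)
    children[[length(children) + 1L]] <- res$node
    pos <- res$pos
  }
  node <- structure(
    list(label = label, children = children, word = NULL,
         start = NA_integer_, end = NA_integer_),
    class = "parse_node"
  )
  list(node = node, pos = pos)
}

#' Serialize a parse tree to Penn-bracketed form
#'
#' Inverse of [read_bracketed_tree()] up to whitespace.
#'
#' @param node A `parse_node`.
#' @return A single bracketed string.
#' @export
write_bracketed_tree <- function(node) {
  stopifnot(inherits(node, "parse_node"))
  if (pn_is_leaf(node)) {
    return(node$word)
  }
  paste0(
    "(", node$label,
    paste0(vapply(node$children, function(ch) {
      paste0(" ", write_bracketed_tree(ch))
    }, character(1)), collapse = ""),
    ")"
  )
}

#' Leaf tokens of a parse tree
#'
#' @param node A `parse_node`.
#' @return Character vector of leaf words in textual order.
#' @export
tree_leaves <- function(node) {
  if (pn_is_leaf(node)) {
    return(node$word)
  }
  unlist(lapply(node$children, tree_leaves))
}

# all nodes that participate in the kernel: internal + pre-terminal, no leaves
pn_nodes <- function(node) {
  if (pn_is_leaf(node)) {
    return(list())
  }
  c(list(node), unlist(lapply(node$children, pn_nodes), recursive = FALSE))
}

#' Number of labeled nodes in a tree
#'
#' Counts internal and pre-terminal nodes; lexical leaves are not counted,
#' matching the node sets the convolution tree kernel sums over.
#'
#' @param node A `parse_node`.
#' @return Integer node count.
#' @export
tree_size <- function(node) {
  length(pn_nodes(node))
}

#' POS-tagged tokens of a parse tree
#'
#' @param node A `parse_node`.
#' @return Tibble with `word` and `pos` (the pre-terminal label) in token
#'   order.
#' @export
tree_pos_tokens <- function(node) {
  pres <- Filter(pn_is_preterminal, pn_nodes(node))
  tibble::tibble(
    word = vapply(pres, function(p) p$children[[1]]$word, character(1)),
    pos = vapply(pres, function(p) p$label, character(1))
  )
}

#' @export
print.parse_node <- function(x, ...) {
  cat(write_bracketed_tree(x), "\n")
  invisible(x)
}

#' @export
format.parse_node <- function(x, ...) write_bracketed_tree(x)
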