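#' Read a typed-dependency graph
#'
#' Parses the CoNLL-like tabular form used for per-sentence typed
#' dependencies: the first line lists the sentence tokens (tab-separated) and
#' every following line is one labeled dependency
#' `relation<TAB>governor<TAB>dependent` with 0-based token indices.
#'
#' @param table Path to a file, or the table content itself as a string.
#' @return A list of class `dependency_graph` with `tokens` (character
#'   vector) and `edges` (tibble `relation`, `governor`, `dependent`).
#' @export
read_dependency_graph <- function(table) {
  stopifnot(is.character(table), length(table) == 1L)
  lines <- if (grepl("\n", table) || grepl("\t", table)) {
    strsplit(table, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(table, warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    stop("empty dependency table")
  }
  tokens <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  edges <- tibble::tibble(
    relation = character(), governor = integer(), dependent = integer()
  )
  if (length(lines) > 1L) {
    parts <- strsplit(lines[-1], "\t", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad)) {
      stop("malformed dependency row: ", lines[-1][bad][1])
    }
    edges <- tibble::tibble(
      relation = vapply(parts, `[[`, character(1), 1L),
      governor = as.integer(vapply(parts, `[[`, character(1), 2L)),
      dependent = as.integer(vapply(parts, `[[`, character(1), 3L))
    )
  }
  dependency_graph(tokens, edges)
}

#' Construct a dependency graph
#'
#' @param tokens Character vector of sentence tokens.
#' @param edges Tibble with columns `relation`, `governor`, `dependent`
#'   (0-based token indices).
#' @return A `dependency_graph`.
#' @export
dependency_graph <- function(tokens, edges) {
  n <- length(tokens)
  idx <- c(edges$governor, edges$dependent)
  if (length(idx) && (anyNA(idx) || any(idx < 0L) || any(idx >= n))) {
    stop(
      "dependency index out of token range [0, ", n, "): ",
      paste(unique(idx[is.na(idx) | idx < 0L | idx >= n]), collapse = ", ")
    )
  }
  structure(
    list(tokens = tokens, edges = tibble::as_tibble(edges)),
    class = "dependency_graph"
  )
}

#' Serialize a dependency graph
#'
#' Inverse of [read_dependency_graph()].
#'
#' @param deps A `dependency_graph`.
#' @return The tabular form as a single string.
#' @export
write_dependency_graph <- function(deps) {
  stopifnot(inherits(deps, "dependency_graph"))
  header <- paste(deps$tokens, collapse = "\t")
  if (!nrow(deps$edges)) {
    return(paste0(header, "\n"))
  }
  rows <- sprintf(
    "%s\t%d\t%d", deps$edges$relation, deps$edges$governor,
    deps$edges$dependent
  )
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Shortest dependency path between two mentions
#'
#' Finds the protein dependency path: the shortest connecting path between
#' the head tokens of the two target mentions in the dependency graph, with
#' edges traversed in both directions.  The head of a multi-token mention is
#' its last token.  Ties between equally short paths are broken by the
#' lexicographically smallest token-index sequence, which a breadth-first
#' search visiting neighbours in increasing index order produces directly.
#'
#' @param deps A `dependency_graph`.
#' @param m1,m2 Mention token spans, integer vectors `c(start, end)`
#'   (0-based half-open), or single token indices.
#' @return Integer vector of 0-based token indices from the first mention
#'   head to the second, or `integer(0)` when the mentions are disconnected.
#' @export
protein_dependency_path <- function(deps, m1, m2) {
  stopifnot(inherits(deps, "dependency_graph"))
  head_of <- function(m) {
    if (length(m) >= 2L) as.integer(m[2]) - 1L else as.integer(m)
  }
  src <- head_of(m1)
  dst <- head_of(m2)
  n <- length(deps$tokens)
  if (src < 0L || src >= n || dst < 0L || dst >= n) {
    stop("mention head token outside the dependency graph")
  }
  if (src == dst) {
    return(src)
  }
  adj <- vector("list", n)
  for (i in seq_len(nrow(deps$edges))) {
    g <- deps$edges$governor[i] + 1L
    d <- deps$edges$dependent[i] + 1L
    adj[[g]] <- c(adj[[g]], d - 1L)
    adj[[d]] <- c(adj[[d]], g - 1L)
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  parent <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  seen[src + 1L] <- TRUE
  queue <- src
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    if (cur == dst) break
    for (nb in adj[[cur + 1L]]) {
      if (!seen[nb + 1L]) {
        seen[nb + 1L] <- TRUE
        parent[nb + 1L] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  if (!seen[dst + 1L]) {
    return(integer(0))
  }
  path <- dst
  while (path[1] != src) {
    path <- c(parent[path[1] + 1L], path)
  }
  path
}
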