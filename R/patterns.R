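#' Select frequent semantic classes
#'
#' Ranks semantic classes by their total frequency in positive sentences and
#' keeps the smallest prefix whose cumulative frequency first exceeds the
#' `sc_cumfreq` fraction (default 70%) of the total; every retained class
#' must additionally occur strictly more than `support_min` times (default
#' 20).  The rank-frequency distribution of SCs is Zipf-like, so the prefix
#' captures the classes that matter for interactions while rare, irrelevant
#' classes drop out.
#'
#' @param sequences List of `sc_sequence` objects (or character vectors of
#'   labels), one per candidate.
#' @param labels Gold labels, +1/-1 or logical, parallel to `sequences`.
#' @param config A [ppi_config()].
#' @return Character vector of frequent SC labels, most frequent first.
#' @export
select_frequent_scs <- function(sequences, labels, config = ppi_config()) {
  pos <- as_positive(labels)
  if (!any(pos)) {
    stop("no positive sequences: frequent-SC selection needs positives")
  }
  freq <- sort(table(unlist(lapply(sequences[pos], sc_labels))),
               decreasing = TRUE)
  if (!length(freq)) {
    return(character(0))
  }
  total <- sum(freq)
  cum <- cumsum(as.integer(freq))
  cut <- which(cum > config$sc_cumfreq * total)[1]
  kept <- names(freq)[seq_len(cut)]
  kept[as.integer(freq[kept]) > config$support_min]
}

as_positive <- function(labels) {
  if (is.logical(labels)) {
    return(labels)
  }
  as.numeric(labels) > 0
}

#' Build the semantic co-occurrence graph
#'
#' Constructs the directed association-rule graph over frequent semantic
#' classes: an edge `SC_i -> SC_j` records that `SC_i` immediately precedes
#' `SC_j` within a positive sequence.  Support counts sequences containing
#' the adjacent pair; `confidence(SC_i => SC_j) = support(SC_i u SC_j) /
#' support(SC_i)`.  Edges below the minimum support or confidence are
#' dropped, and the remaining confidences are renormalized per source vertex
#' into the row-stochastic transition matrix `M` that drives the random
#' walks.
#'
#' @param sequences List of `sc_sequence` objects or label vectors.
#' @param labels Gold labels parallel to `sequences`; by default only
#'   positive sequences contribute edges.
#' @param frequent_scs Vertices, from [select_frequent_scs()].
#' @param config A [ppi_config()].
#' @param positives_only Use only positive sequences for edge statistics
#'   (default `TRUE`).
#' @return A list of class `semantic_graph`: `vertices` and an `edges`
#'   tibble (`from`, `to`, `support`, `confidence`, `weight`) where
#'   `weight` rows sum to 1 per source vertex with outgoing edges.
#' @export
build_semantic_graph <- function(sequences, labels, frequent_scs,
                                 config = ppi_config(),
                                 positives_only = TRUE) {
  stopifnot(length(frequent_scs) >= 1L)
  use <- if (positives_only) as_positive(labels) else rep(TRUE, length(sequences))
  seqs <- lapply(sequences[use], sc_labels)
  vertex_support <- integer(length(frequent_scs))
  names(vertex_support) <- frequent_scs
  pair_support <- list()
  for (s in seqs) {
    s <- s[s %in% frequent_scs]
    for (v in unique(s)) {
      vertex_support[v] <- vertex_support[v] + 1L
    }
    if (length(s) >= 2L) {
      bigrams <- unique(paste(s[-length(s)], s[-1], sep = "\r"))
      for (b in bigrams) {
        pair_support[[b]] <- (pair_support[[b]] %||% 0L) + 1L
      }
    }
  }
  edges <- tibble::tibble(
    from = character(), to = character(), support = integer(),
    confidence = numeric(), weight = numeric()
  )
  if (length(pair_support)) {
    parts <- strsplit(names(pair_support), "\r", fixed = TRUE)
    edges <- tibble::tibble(
      from = vapply(parts, `[[`, character(1), 1L),
      to = vapply(parts, `[[`, character(1), 2L),
      support = as.integer(unlist(pair_support))
    )
    edges$confidence <- unname(edges$support / vertex_support[edges$from])
    edges <- edges |>
      dplyr::filter(
        .data$support >= config$support_min,
        .data$confidence >= config$confidence_min
      ) |>
      dplyr::group_by(.data$from) |>
      dplyr::mutate(weight = .data$confidence / sum(.data$confidence)) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$from, .data$to)
  }
  structure(
    list(vertices = frequent_scs, edges = edges,
         vertex_support = vertex_support),
    class = "semantic_graph"
  )
}

#' @export
print.semantic_graph <- function(x, ...) {
  cat("<semantic_graph> ", length(x$vertices), " vertices, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Harvest candidate patterns by random walks
#'
#' Runs seeded random walks on the semantic graph: one walk starts at each
#' frequent SC and at each of its out-neighbours, repeatedly, until the
#' global step budget `4 * u^2` (with `u` the edge count) is exhausted.
#' Each step samples the next vertex from the transition weights; a vertex
#' with no outgoing edges ends the walk, and a walk visits at most `v`
#' vertices (the vertex count).  Every walk prefix of length >= 2 is emitted
#' as a candidate pattern, so short frequent motifs are captured before
#' merging.  Deterministic given the seed.
#'
#' @param graph A `semantic_graph`.
#' @param seed Integer seed; defaults to the seed in `config`.
#' @param config A [ppi_config()].
#' @return Unique candidate patterns as a list of character vectors.
#' @export
random_walk_patterns <- function(graph, seed = NULL, config = ppi_config()) {
  stopifnot(inherits(graph, "semantic_graph"))
  if (is.null(seed)) seed <- config$seed
  edges <- graph$edges
  if (!nrow(edges)) {
    return(list())
  }
  adj <- split(
    data.frame(to = edges$to, w = edges$weight, stringsAsFactors = FALSE),
    edges$from
  )
  starts <- unique(c(intersect(graph$vertices, names(adj)),
                     unlist(lapply(adj, function(a) a$to), use.names = FALSE)))
  starts <- starts[starts %in% c(graph$vertices, edges$to)]
  if (!length(starts)) {
    return(list())
  }
  budget <- 4 * nrow(edges)^2
  max_len <- max(length(graph$vertices), 2L)
  seen <- new.env(parent = emptyenv())
  patterns <- list()
  withr::local_seed(seed)
  repeat {
    for (s in starts) {
      walk <- s
      while (length(walk) < max_len && budget > 0L) {
        out <- adj[[walk[length(walk)]]]
        if (is.null(out)) break
        nxt <- out$to[sample.int(nrow(out), 1L, prob = out$w)]
        budget <- budget - 1L
        walk <- c(walk, nxt)
        key <- paste(walk, collapse = "\r")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          patterns[[length(patterns) + 1L]] <- walk
        }
      }
      if (budget <= 0L) break
    }
    if (budget <= 0L) break
  }
  patterns
}

#' Merge redundant patterns
#'
#' Applies the two merging rules to a fixed point: (1) a pattern that is a
#' contiguous subsequence of another pattern is absorbed by it; (2) a bigram
#' whose tail equals the head SC of another pattern is concatenated onto it
#' at that pivot.  Patterns are processed longest first, ties broken
#' lexicographically, so the result is deterministic.
#'
#' @param patterns List of character vectors (SC label sequences).
#' @return Merged list of character vectors, longest first.
#' @export
merge_patterns <- function(patterns) {
  pats <- unique(lapply(patterns, as.character))
  repeat {
    pats <- pats[order(-lengths(pats),
                       vapply(pats, paste, character(1), collapse = "\r"))]
    changed <- FALSE
    # rule 1: drop contiguous subsequences of longer patterns; keys are
    # delimiter-padded so label boundaries cannot match mid-label
    keys <- vapply(pats, function(p) {
      paste0("\r", paste(p, collapse = "\r"), "\r")
    }, character(1))
    covered <- rep(FALSE, length(pats))
    for (i in seq_along(pats)) {
      for (j in seq_along(pats)) {
        if (i == j || covered[j] || lengths(pats)[i] <= lengths(pats)[j]) next
        if (grepl(keys[j], keys[i], fixed = TRUE)) covered[j] <- TRUE
      }
    }
    if (any(covered)) {
      pats <- pats[!covered]
      changed <- TRUE
    }
    # rule 2: pivot-concatenate a bigram onto a pattern starting with its tail
    n <- length(pats)
    done <- FALSE
    for (i in seq_len(n)) {
      if (done) break
      if (length(pats[[i]]) != 2L) next
      for (j in seq_len(n)) {
        if (i == j) next
        if (pats[[j]][1] == pats[[i]][2]) {
          merged <- c(pats[[i]][1], pats[[j]])
          pats <- pats[-c(i, j)]
          pats[[length(pats) + 1L]] <- merged
          pats <- unique(pats)
          changed <- TRUE
          done <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  pats[order(-lengths(pats),
             vapply(pats, paste, character(1), collapse = "\r"))]
}

#' Log-likelihood ratio of a semantic class
#'
#' Tests whether the occurrence of a semantic class in positive PPI
#' sentences is non-random: `-2 log` of the ratio between the likelihood of
#' the pooled model (one rate `p(SC)` for positives and negatives) and the
#' conditional model (`p(SC|I)` in positives, `p(SC|not I)` in negatives),
#' all rates estimated by maximum likelihood.  The statistic is 0 exactly
#' when the conditional rates are equal and grows with their separation.
#' Zero or unit MLE rates are clamped by a small epsilon so the value stays
#' finite.
#'
#' @param n_pos,n_neg Numbers of positive / negative sentences.
#' @param k_pos,k_neg Numbers of positive / negative sentences containing
#'   the class.
#' @param eps Smoothing bound for degenerate rates (default 1e-9).
#' @return Nonnegative LLR value.
#' @export
llr_score <- function(n_pos, n_neg, k_pos, k_neg, eps = 1e-9) {
  stopifnot(
    k_pos >= 0, k_neg >= 0, k_pos <= n_pos, k_neg <= n_neg
  )
  if (n_pos + n_neg == 0) {
    stop("llr_score needs at least one sentence")
  }
  clamp <- function(p) pmin(pmax(p, eps), 1 - eps)
  p <- clamp((k_pos + k_neg) / (n_pos + n_neg))
  p1 <- clamp(if (n_pos > 0) k_pos / n_pos else p)
  p2 <- clamp(if (n_neg > 0) k_neg / n_neg else p)
  loglik <- function(k, n, pr) k * log(pr) + (n - k) * log(1 - pr)
  -2 * (loglik(k_pos, n_pos, p) + loglik(k_neg, n_neg, p) -
          loglik(k_pos, n_pos, p1) - loglik(k_neg, n_neg, p2))
}

#' Per-class LLR values for a labeled corpus
#'
#' @param sequences List of `sc_sequence` objects or label vectors.
#' @param labels Gold labels parallel to `sequences`.
#' @return Tibble with columns `label` and `llr`.
#' @export
llr_table <- function(sequences, labels) {
  pos <- as_positive(labels)
  scs <- unique(unlist(lapply(sequences, sc_labels)))
  contains <- function(sc, idx) {
    sum(vapply(sequences[idx], function(s) sc %in% sc_labels(s), logical(1)))
  }
  tibble::tibble(
    label = scs,
    llr = vapply(scs, function(sc) {
      llr_score(sum(pos), sum(!pos), contains(sc, pos), contains(sc, !pos))
    }, numeric(1))
  )
}

#' Rank patterns by summed LLR and keep the top k
#'
#' Scores each pattern as the sum of its member classes' LLR values
#' (classes without a value contribute 0), sorts by descending score with
#' ties broken by longer pattern then lexicographically, and retains the top
#' `k` (default 20).
#'
#' @param patterns List of character vectors.
#' @param llr Tibble from [llr_table()] (columns `label`, `llr`).
#' @param k Number of patterns to keep; defaults to 20.
#' @return Tibble of class `interaction_patterns` with columns `rank`,
#'   `score` and `labels` (list-column of character vectors).
#' @export
rank_and_select_patterns <- function(patterns, llr, k = 20) {
  scores <- vapply(patterns, function(p) {
    sum(llr$llr[match(p, llr$label)], na.rm = TRUE)
  }, numeric(1))
  ord <- order(
    -scores, -lengths(patterns),
    vapply(patterns, paste, character(1), collapse = "\r")
  )
  ord <- ord[seq_len(min(k, length(ord)))]
  out <- tibble::tibble(
    rank = seq_along(ord),
    score = scores[ord],
    labels = patterns[ord]
  )
  structure(out, class = c("interaction_patterns", class(out)))
}

#' Mine interaction patterns from labeled sequences
#'
#' Convenience wrapper running the full mining stage: frequent-SC selection,
#' semantic-graph construction, random-walk harvesting, merging and
#' LLR-based top-k selection.
#'
#' @param sequences List of `sc_sequence` objects or label vectors.
#' @param labels Gold labels parallel to `sequences`.
#' @param config A [ppi_config()].
#' @return An `interaction_patterns` tibble (possibly empty).
#' @export
mine_patterns <- function(sequences, labels, config = ppi_config()) {
  frequent <- select_frequent_scs(sequences, labels, config)
  empty <- structure(
    tibble::tibble(rank = integer(), score = numeric(), labels = list()),
    class = c("interaction_patterns", "tbl_df", "tbl", "data.frame")
  )
  if (!length(frequent)) {
    return(empty)
  }
  graph <- build_semantic_graph(sequences, labels, frequent, config)
  walks <- random_walk_patterns(graph, config = config)
  if (!length(walks)) {
    return(empty)
  }
  merged <- merge_patterns(walks)
  rank_and_select_patterns(merged, llr_table(sequences, labels),
                           k = config$top_k_patterns)
}

#' Match a pattern against a semantic-class sequence
#'
#' @param pattern Character vector of SC labels.
#' @param seq An `sc_sequence` or character vector of labels.
#' @return `TRUE` iff the pattern occurs as an ordered (not necessarily
#'   contiguous) subsequence of the sequence.
#' @export
match_pattern <- function(pattern, seq) {
  s <- sc_labels(seq)
  p <- as.character(pattern)
  i <- 1L
  for (lab in s) {
    if (i <= length(p) && lab == p[i]) {
      i <- i + 1L
    }
  }
  i > length(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
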