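#' Find protein mentions in a sentence
#'
#' Matches a set of known protein names against a tokenized sentence.
#' Unigram names (no internal space) are matched by exact token equality;
#' names containing spaces are matched by substring search of the sentence
#' text.  Overlapping matches are resolved longest-first, so "amyloid beta
#' protein" beats a shorter name inside it, and a name that only occurs as a
#' substring of a longer token ("LIF" inside "hLIF") is not matched.
#'
#' @param sentence A list or one-row tibble with `text` and `tokens` (as
#'   produced by [split_sentences()]).
#' @param names Character vector of protein surface strings.
#' @return Tibble with columns `surface`, `start`, `end` (character span in
#'   the sentence), `token_start`, `token_end` (0-based half-open token
#'   span), ordered by position.
#' @export
find_protein_mentions <- function(sentence, names) {
  stopifnot(length(names) >= 1L)
  tokens <- sentence$tokens
  if (is.list(tokens) && !is.data.frame(tokens)) tokens <- tokens[[1]]
  text <- sentence$text[[1]]
  hits <- list()
  for (nm in unique(names)) {
    if (grepl(" ", nm, fixed = TRUE)) {
      m <- gregexpr(nm, text, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      for (j in seq_along(m)) {
        s <- as.integer(m[j]) - 1L
        e <- s + attr(m, "match.length")[j]
        hits[[length(hits) + 1L]] <- tibble::tibble(
          surface = nm, start = s, end = e
        )
      }
    } else {
      idx <- which(tokens$surface == nm)
      for (j in idx) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          surface = nm, start = tokens$start[j], end = tokens$end[j]
        )
      }
    }
  }
  empty <- tibble::tibble(
    surface = character(), start = integer(), end = integer(),
    token_start = integer(), token_end = integer()
  )
  if (!length(hits)) {
    return(empty)
  }
  hits <- dplyr::bind_rows(hits) |>
    dplyr::arrange(dplyr::desc(.data$end - .data$start), .data$start)
  kept <- list()
  taken <- rep(FALSE, nchar(text))
  for (i in seq_len(nrow(hits))) {
    span <- seq(hits$start[i] + 1L, hits$end[i])
    if (any(taken[span])) next
    taken[span] <- TRUE
    kept[[length(kept) + 1L]] <- hits[i, ]
  }
  kept <- dplyr::bind_rows(kept) |> dplyr::arrange(.data$start)
  # token span covering the character span
  kept$token_start <- vapply(seq_len(nrow(kept)), function(i) {
    min(which(tokens$end > kept$start[i])) - 1L
  }, integer(1))
  kept$token_end <- vapply(seq_len(nrow(kept)), function(i) {
    max(which(tokens$start < kept$end[i]))
  }, integer(1))
  kept
}

#' Enumerate candidate protein pairs of a sentence
#'
#' Generates one candidate per unordered pair of distinct protein names
#' mentioned in the sentence: `choose(k, 2)` candidates for `k` distinct
#' names, each ordered so that `p1` is the name whose first mention occurs
#' earlier in the text.  Candidates are listed lexicographically by mention
#' positions.  Sentences with fewer than two distinct names are filtered out
#' (empty result).
#'
#' @param sentence A list or one-row tibble with `text` and `tokens`.
#' @param mentions Mention tibble from [find_protein_mentions()].
#' @return Tibble with one row per candidate pair: `p1`, `p2`, their first
#'   mention token spans (`p1_token_start`, `p1_token_end`, `p2_token_start`,
#'   `p2_token_end`) and `other_proteins`, a list-column of the remaining
#'   distinct names.
#' @export
enumerate_candidates <- function(sentence, mentions) {
  empty <- tibble::tibble(
    p1 = character(), p2 = character(),
    p1_token_start = integer(), p1_token_end = integer(),
    p2_token_start = integer(), p2_token_end = integer(),
    other_proteins = list()
  )
  if (is.null(mentions) || !nrow(mentions)) {
    return(empty)
  }
  firsts <- mentions |>
    dplyr::group_by(.data$surface) |>
    dplyr::slice_min(.data$start, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$start)
  k <- nrow(firsts)
  if (k < 2L) {
    return(empty)
  }
  pairs <- utils::combn(seq_len(k), 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]
    b <- pairs[2L, j]
    tibble::tibble(
      p1 = firsts$surface[a], p2 = firsts$surface[b],
      p1_token_start = firsts$token_start[a],
      p1_token_end = firsts$token_end[a],
      p2_token_start = firsts$token_start[b],
      p2_token_end = firsts$token_end[b],
      other_proteins = list(setdiff(firsts$surface, firsts$surface[c(a, b)]))
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$p1_token_start, .data$p2_token_start)
}

#' Normalize a candidate's tokens
#'
#' Replaces protein tokens with placeholder labels: every token of a mention
#' of the target pair becomes `PROTEIN1` or `PROTEIN2` (by order of first
#' occurrence, so `PROTEIN1` always precedes `PROTEIN2`), every token of any
#' other recognized protein mention becomes `PROTEIN`, and all remaining
#' tokens are unchanged.  Token count is preserved, and normalization is
#' idempotent.
#'
#' @param tokens Token tibble (from [tokenize_text()]) or character vector.
#' @param mentions Mention tibble from [find_protein_mentions()].
#' @param p1,p2 The target pair's surface names, `p1` first in the text.
#' @return Character vector of normalized tokens, same length as `tokens`.
#' @export
normalize_candidate <- function(tokens, mentions, p1, p2) {
  surfaces <- if (is.data.frame(tokens)) tokens$surface else tokens
  out <- surfaces
  if (!any(mentions$surface == p1) || !any(mentions$surface == p2)) {
    stop("target pair mention missing from the sentence: ", p1, " / ", p2)
  }
  for (i in seq_len(nrow(mentions))) {
    label <- if (mentions$surface[i] == p1) {
      "PROTEIN1"
    } else if (mentions$surface[i] == p2) {
      "PROTEIN2"
    } else {
      "PROTEIN"
    }
    span <- seq(mentions$token_start[i] + 1L, mentions$token_end[i])
    out[span] <- label
  }
  out
}
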