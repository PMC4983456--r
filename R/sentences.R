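#' Tokenize text preserving offsets
#'
#' Whitespace-and-punctuation tokenizer: decimal numbers and hyphenated or
#' apostrophised word characters stay together ("6.5", "CRE-dependent",
#' "Sec24p"), every other non-space character becomes its own token.  Tokens
#' tile the non-whitespace text left to right without overlap.
#'
#' @param text A single string.
#' @return Tibble with columns `surface`, `start`, `end` (0-based half-open
#'   character offsets into `text`).
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr("\\d+(?:\\.\\d+)?|[\\w'-]+|[^\\w\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(
      surface = character(), start = integer(), end = integer()
    ))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  tibble::tibble(
    surface = regmatches(text, list(m))[[1]],
    start = starts,
    end = starts + lens
  )
}

# words that commonly precede a non-terminal period in biomedical text
sentence_abbrevs <- c(
  "fig", "figs", "e.g", "i.e", "vs", "sp", "spp", "approx", "etc", "al",
  "cf", "no", "ref"
)

#' Split a passage into sentences
#'
#' Rule-based sentence splitter: a boundary is a `.`, `!` or `?` followed by
#' whitespace and a capital letter, except when the period sits inside a
#' decimal number ("ph 6.5"), after "et al.", after a single capital initial,
#' or after a known abbreviation token (Fig., e.g., i.e., vs., sp.,
#' approx., ...).  Nonempty input always yields at least one sentence.
#'
#' @param passage_text A single nonempty string.
#' @return Tibble with columns `sentence_index`, `text`, `start` (0-based
#'   offset of the sentence in the passage) and `tokens`, a list-column of
#'   [tokenize_text()] tibbles with sentence-relative offsets.
#' @export
split_sentences <- function(passage_text) {
  stopifnot(is.character(passage_text), length(passage_text) == 1L,
            nzchar(passage_text))
  chars <- strsplit(passage_text, "")[[1]]
  n <- length(chars)
  boundaries <- integer(0)
  for (i in seq_len(n)) {
    if (!chars[i] %in% c(".", "!", "?")) next
    after <- substr(passage_text, i + 1L, n)
    if (!grepl("^\\s+[A-Z]", after)) next
    if (chars[i] == ".") {
      # inside a decimal number: digit on both sides
      if (i > 1L && i < n && grepl("[0-9]", chars[i - 1L]) &&
          grepl("[0-9]", chars[i + 1L])) {
        next
      }
      before <- substr(passage_text, 1L, i - 1L)
      prev_word <- stringr::str_extract(before, "[A-Za-z.]+$")
      if (!is.na(prev_word)) {
        pw <- tolower(sub("\\.+$", "", prev_word))
        if (pw %in% sentence_abbrevs) next
        if (pw == "al" || grepl("(^|\\s)et\\s+al$", tolower(before))) next
        if (grepl("^[A-Z]$", prev_word)) next # single capital initial
      }
    }
    boundaries <- c(boundaries, i)
  }
  cut_starts <- c(1L, boundaries + 1L)
  cut_ends <- c(boundaries, n)
  out <- list()
  for (k in seq_along(cut_starts)) {
    raw <- substr(passage_text, cut_starts[k], cut_ends[k])
    lead <- nchar(raw) - nchar(sub("^\\s+", "", raw))
    text <- trimws(raw)
    if (!nzchar(text)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      text = text,
      start = cut_starts[k] - 1L + lead
    )
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::mutate(res, sentence_index = dplyr::row_number(),
                       .before = 1L)
  res$tokens <- lapply(res$text, tokenize_text)
  res
}
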