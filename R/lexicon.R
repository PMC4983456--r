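#' Load a trigger-word lexicon
#'
#' Reads a two-column TSV mapping trigger words to semantic-class labels.
#' Terms are lowercased and Porter-stemmed before keying, so inflected forms
#' of the same trigger ("bind", "binds", "binding") collapse onto one entry.
#' Duplicate stems are allowed when they agree on the class and rejected when
#' they conflict.
#'
#' @param tsv Path to a TSV file, or the TSV content itself as a string
#'   (detected by the presence of a tab or newline).
#' @return A tibble of class `trigger_lexicon` with columns `stem` and
#'   `class`.
#' @examples
#' load_trigger_lexicon("bind\tBinding\nbinding\tBinding\n")
#' @export
load_trigger_lexicon <- function(tsv) {
  stopifnot(is.character(tsv), length(tsv) == 1L)
  lines <- if (grepl("[\t\n]", tsv)) {
    strsplit(tsv, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(tsv, warn = FALSE)
  }
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("trigger lexicon line is not 2-column TSV: ", lines[bad][1])
  }
  term <- vapply(parts, `[[`, character(1), 1L)
  cls <- vapply(parts, `[[`, character(1), 2L)
  if (any(!nzchar(cls))) {
    stop("trigger lexicon has an empty class label")
  }
  entries <- tibble::tibble(stem = porter_stem(term), class = cls) |>
    dplyr::distinct()
  conflicts <- entries |>
    dplyr::count(.data$stem) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflicts)) {
    stop(
      "conflicting semantic classes for stem(s): ",
      paste(conflicts$stem, collapse = ", ")
    )
  }
  structure(entries, class = c("trigger_lexicon", class(entries)))
}

#' Default trigger lexicon
#'
#' A small illustrative lexicon shipped with the package, covering the
#' semantic classes Binding, Regulation, Positive_regulation,
#' Negative_regulation, Gene_expression, Transcription, Localization and
#' Antagonist.  It is meant as a user-replaceable stand-in, not a full
#' event-trigger inventory.
#'
#' @return A `trigger_lexicon` tibble.
#' @export
default_trigger_lexicon <- function() {
  load_trigger_lexicon(
    system.file("extdata", "trigger_lexicon.tsv", package = "pipeppi",
                mustWork = TRUE)
  )
}

# case-insensitive stemmed lookup; returns NA for non-triggers
lexicon_lookup <- function(lexicon, tokens) {
  stems <- porter_stem(tolower(tokens))
  lexicon$class[match(stems, lexicon$stem)]
}
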