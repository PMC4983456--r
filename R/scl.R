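#' Semantic class labeling of a normalized sentence
#'
#' Converts the normalized token list of a candidate sentence into its
#' ordered semantic-class sequence.  The protein placeholders `PROTEIN1`,
#' `PROTEIN2` and `PROTEIN` pass through as labels (consecutive identical
#' placeholders from one multi-token mention collapse to a single label);
#' every other token is lowercased, Porter-stemmed and looked up in the
#' trigger lexicon — matches emit the lexicon class, non-matches emit
#' nothing.  Because lookup is by stem, synonym inflections map to the same
#' label.
#'
#' @param normalized Character vector of normalized tokens
#'   (see [normalize_candidate()]).
#' @param lexicon A `trigger_lexicon`.
#' @return Tibble of class `sc_sequence` with columns `label` and
#'   `token_index` (0-based source token position), in token order.
#' @examples
#' lex <- load_trigger_lexicon("binds\tBinding\nantagonist\tAntagonist\n")
#' label_semantic_classes(
#'   c("PROTEIN1", "binding", "to", "PROTEIN2", "antagonists"), lex
#' )
#' @export
label_semantic_classes <- function(normalized, lexicon) {
  stopifnot(is.character(normalized))
  if (!any(normalized == "PROTEIN1") || !any(normalized == "PROTEIN2")) {
    stop("normalized tokens must contain both PROTEIN1 and PROTEIN2")
  }
  protein_labels <- c("PROTEIN1", "PROTEIN2", "PROTEIN")
  is_protein <- normalized %in% protein_labels
  labels <- character(length(normalized))
  labels[is_protein] <- normalized[is_protein]
  if (any(!is_protein)) {
    labels[!is_protein] <- {
      cls <- lexicon_lookup(lexicon, normalized[!is_protein])
      ifelse(is.na(cls), "", cls)
    }
  }
  keep <- nzchar(labels)
  # collapse runs of the same protein placeholder (multi-token mentions)
  run_same <- keep & is_protein &
    c(FALSE, labels[-length(labels)] == labels[-1] &
        is_protein[-length(labels)])
  keep <- keep & !run_same
  out <- tibble::tibble(
    label = labels[keep],
    token_index = which(keep) - 1L
  )
  structure(out, class = c("sc_sequence", class(out)))
}

sc_labels <- function(seq) {
  if (is.data.frame(seq)) seq$label else as.character(seq)
}
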