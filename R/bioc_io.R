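#' Read a BioC-style XML collection
#'
#' Parses the minimal BioC-style dialect used by the pipeline: a `collection`
#' of `document`s, each with an `id` and one or more `passage` elements
#' carrying an absolute character `offset`, the passage `text` and zero or
#' more protein `annotation` elements (`location` with absolute `offset` and
#' `length`, plus the annotated `text`).  Unknown elements are ignored.
#' Annotation offsets are validated against the passage text: the substring
#' at each span must equal the annotated surface form.
#'
#' @param xml_text XML content as a string, or a path to an XML file.
#' @return A list of class `bioc_collection` with two tibbles:
#'   `passages` (`doc_id`, `passage_index`, `offset`, `text`) and
#'   `annotations` (`doc_id`, `passage_index`, `ann_id`, `surface`, `start`,
#'   `end`), with 0-based half-open spans relative to the passage text.
#' @export
read_bioc_collection <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)
  documents <- xml2::xml_find_all(doc, ".//document")
  passages <- list()
  annotations <- list()
  for (dnode in documents) {
    doc_id <- xml2::xml_text(xml2::xml_find_first(dnode, "./id"))
    pnodes <- xml2::xml_find_all(dnode, "./passage")
    for (pi in seq_along(pnodes)) {
      pnode <- pnodes[[pi]]
      offset <- as.integer(xml2::xml_text(
        xml2::xml_find_first(pnode, "./offset")
      ))
      if (is.na(offset)) offset <- 0L
      ptext <- xml2::xml_text(xml2::xml_find_first(pnode, "./text"))
      passages[[length(passages) + 1L]] <- tibble::tibble(
        doc_id = doc_id, passage_index = pi, offset = offset, text = ptext
      )
      for (anode in xml2::xml_find_all(pnode, "./annotation")) {
        ann_id <- xml2::xml_attr(anode, "id")
        loc <- xml2::xml_find_first(anode, "./location")
        a_off <- as.integer(xml2::xml_attr(loc, "offset"))
        a_len <- as.integer(xml2::xml_attr(loc, "length"))
        surface <- xml2::xml_text(xml2::xml_find_first(anode, "./text"))
        start <- a_off - offset
        end <- start + a_len
        check_span(ptext, start, end, surface,
                   what = sprintf("annotation '%s' in document '%s'",
                                  ann_id, doc_id))
        annotations[[length(annotations) + 1L]] <- tibble::tibble(
          doc_id = doc_id, passage_index = pi, ann_id = ann_id,
          surface = surface, start = start, end = end
        )
      }
    }
  }
  new_bioc_collection(
    passages = dplyr::bind_rows(passages),
    annotations = dplyr::bind_rows(annotations)
  )
}

new_bioc_collection <- function(passages, annotations) {
  if (!nrow(passages)) {
    passages <- tibble::tibble(
      doc_id = character(), passage_index = integer(),
      offset = integer(), text = character()
    )
  }
  if (!nrow(annotations)) {
    annotations <- tibble::tibble(
      doc_id = character(), passage_index = integer(), ann_id = character(),
      surface = character(), start = integer(), end = integer()
    )
  }
  structure(
    list(passages = passages, annotations = annotations),
    class = "bioc_collection"
  )
}

# single enforcement point for the 0-based half-open span convention
check_span <- function(text, start, end, surface, what = "span") {
  if (is.na(start) || is.na(end) || start >= end || !nzchar(surface)) {
    stop(what, ": invalid span [", start, ", ", end, ")")
  }
  got <- substr(text, start + 1L, end)
  if (!identical(got, surface)) {
    stop(
      what, ": text at span [", start, ", ", end, ") is '", got,
      "' but the annotation says '", surface, "'"
    )
  }
  invisible(TRUE)
}

#' Write a BioC-style XML collection
#'
#' Serializes a `bioc_collection` back to the dialect read by
#' [read_bioc_collection()]; the two functions are inverse on all fields.
#' Optional pair-level predictions are emitted as `relation` elements with
#' `p1`, `p2` and `label` attributes.
#'
#' @param docs A `bioc_collection`.
#' @param predictions Optional tibble with columns `doc_id`,
#'   `passage_index`, `p1`, `p2`, `label`.
#' @return XML as a single string.
#' @export
write_bioc_collection <- function(docs, predictions = NULL) {
  stopifnot(inherits(docs, "bioc_collection"))
  root <- xml2::xml_new_root("collection")
  for (id in unique(docs$passages$doc_id)) {
    dnode <- xml2::xml_add_child(root, "document")
    xml2::xml_add_child(dnode, "id", id)
    rows <- docs$passages[docs$passages$doc_id == id, ]
    for (ri in seq_len(nrow(rows))) {
      pnode <- xml2::xml_add_child(dnode, "passage")
      xml2::xml_add_child(pnode, "offset", as.character(rows$offset[ri]))
      xml2::xml_add_child(pnode, "text", rows$text[ri])
      anns <- docs$annotations[
        docs$annotations$doc_id == id &
          docs$annotations$passage_index == rows$passage_index[ri],
      ]
      for (ai in seq_len(nrow(anns))) {
        anode <- xml2::xml_add_child(pnode, "annotation",
                                     id = anns$ann_id[ai])
        inf <- xml2::xml_add_child(anode, "infon", "protein")
        xml2::xml_set_attr(inf, "key", "type")
        xml2::xml_add_child(
          anode, "location",
          offset = as.character(rows$offset[ri] + anns$start[ai]),
          length = as.character(anns$end[ai] - anns$start[ai])
        )
        xml2::xml_add_child(anode, "text", anns$surface[ai])
      }
      if (!is.null(predictions)) {
        preds <- predictions[
          predictions$doc_id == id &
            predictions$passage_index == rows$passage_index[ri],
        ]
        for (qi in seq_len(nrow(preds))) {
          xml2::xml_add_child(
            pnode, "relation",
            p1 = preds$p1[qi], p2 = preds$p2[qi],
            label = as.character(preds$label[qi])
          )
        }
      }
    }
  }
  as.character(root)
}

#' @export
print.bioc_collection <- function(x, ...) {
  cat(
    "<bioc_collection> ", dplyr::n_distinct(x$passages$doc_id),
    " document(s), ", nrow(x$passages), " passage(s), ",
    nrow(x$annotations), " annotation(s)\n", sep = ""
  )
  invisible(x)
}
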