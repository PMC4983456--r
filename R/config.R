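#' Run configuration
#'
#' Bundles the tunable parameters of the pipeline.  Defaults follow the
#' published settings: association-rule mining with minimum support 20 and
#' minimum confidence 0.5, frequent semantic classes kept up to 70% of the
#' cumulative SC frequency in positive sentences, stop words up to 80% of the
#' cumulative word frequency, the top 20 mined patterns retained, and kernel
#' decay lambda = 0.4.  The SVM penalty C defaults to the negative/positive
#' class ratio of the training set (`derived_C`).
#'
#' @param support_min Minimum association-rule support count (default 20).
#' @param confidence_min Minimum rule confidence (default 0.5).
#' @param sc_cumfreq Cumulative-frequency cutoff for frequent semantic
#'   classes, fraction of the total SC frequency in positives (default 0.70).
#' @param stopword_cumfreq Cumulative-frequency cutoff for the stop-word
#'   list (default 0.80).
#' @param top_k_patterns Number of mined patterns retained (default 20).
#' @param lambda_decay Kernel decay factor in (0, 1) (default 0.4).
#' @param normalize_kernel Normalize kernel values to unit self-similarity
#'   (default `TRUE`).
#' @param derived_C Derive the SVM penalty as #negatives / #positives from
#'   the training labels (default `TRUE`).
#' @param C Explicit SVM penalty, used when `derived_C` is `FALSE`.
#' @param seed Integer seed for every stochastic step (random walks, fold
#'   assignment).
#' @return A list of class `ppi_config`.
#' @examples
#' ppi_config()
#' @export
ppi_config <- function(support_min = 20,
                       confidence_min = 0.5,
                       sc_cumfreq = 0.70,
                       stopword_cumfreq = 0.80,
                       top_k_patterns = 20,
                       lambda_decay = 0.4,
                       normalize_kernel = TRUE,
                       derived_C = TRUE,
                       C = 1,
                       seed = 1L) {
  stopifnot(
    lambda_decay > 0, lambda_decay < 1,
    sc_cumfreq > 0, sc_cumfreq <= 1,
    stopword_cumfreq > 0, stopword_cumfreq <= 1,
    support_min >= 0, confidence_min >= 0, confidence_min <= 1,
    top_k_patterns >= 0, C > 0
  )
  structure(
    list(
      support_min = support_min,
      confidence_min = confidence_min,
      sc_cumfreq = sc_cumfreq,
      stopword_cumfreq = stopword_cumfreq,
      top_k_patterns = top_k_patterns,
      lambda_decay = lambda_decay,
      normalize_kernel = normalize_kernel,
      derived_C = derived_C,
      C = C,
      seed = as.integer(seed)
    ),
    class = "ppi_config"
  )
}

#' Read a flat key=value configuration file
#'
#' @param path Path to a file with one `key=value` pair per line; `#` starts
#'   a comment.  Unknown keys are rejected.
#' @return A `ppi_config`.
#' @export
read_ppi_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed config line: ", lines[bad][1])
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[[`, character(1), 2L))
  known <- names(formals(ppi_config))
  if (any(!keys %in% known)) {
    stop("unknown config key: ", keys[!keys %in% known][1])
  }
  args <- lapply(vals, function(v) {
    if (toupper(v) %in% c("TRUE", "FALSE")) {
      as.logical(v)
    } else {
      as.numeric(v)
    }
  })
  names(args) <- keys
  do.call(ppi_config, args)
}
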