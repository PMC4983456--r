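#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation result
#'
#' One row per fold (CV), per held-out corpus (CL) or per train/test cell
#' (CC), with counts and P/R/F1.
#'
#' @param x A `ppi_eval`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ppi_eval
#' @export
tidy.ppi_eval <- function(x, ...) {
  out <- switch(x$protocol,
    cv = x$per_fold,
    cl = x$per_corpus,
    cc = x$cells
  )
  tibble::as_tibble(out)
}

#' Summarize an evaluation result
#'
#' @param x A `ppi_eval`.
#' @param ... Unused.
#' @return One-row tibble with the pooled precision, recall and F1 (CV/CL)
#'   or the mean off-diagonal F1 (CC).
#' @method glance ppi_eval
#' @export
glance.ppi_eval <- function(x, ...) {
  if (x$protocol == "cc") {
    return(tibble::tibble(
      protocol = "cc",
      mean_f1 = mean(x$f1[row(x$f1) != col(x$f1)], na.rm = TRUE),
      n_cells = sum(row(x$f1) != col(x$f1))
    ))
  }
  dplyr::mutate(tibble::as_tibble(x$metrics), protocol = x$protocol,
                .before = 1L)
}

#' Tidy mined interaction patterns
#'
#' @param x An `interaction_patterns` tibble.
#' @param ... Unused.
#' @return Tibble with `rank`, `score` and the pattern rendered as
#'   `"[A] -> [B]"`.
#' @method tidy interaction_patterns
#' @export
tidy.interaction_patterns <- function(x, ...) {
  tibble::tibble(
    rank = x$rank,
    score = x$score,
    pattern = vapply(x$labels, function(p) {
      paste(sprintf("[%s]", p), collapse = " -> ")
    }, character(1))
  )
}

#' Summarize a fitted pipeline
#'
#' @param x A `ppi_fit`.
#' @param ... Unused.
#' @return One-row tibble: training size, pattern count, stop-word count,
#'   penalty C and support-vector count.
#' @method glance ppi_fit
#' @export
glance.ppi_fit <- function(x, ...) {
  tibble::tibble(
    n_train = length(x$idx),
    n_patterns = nrow(x$patterns),
    n_stopwords = length(x$stopwords),
    C = x$model$C,
    n_sv = length(x$model$sv)
  )
}

#' Plot an evaluation result
#'
#' CV and CL evaluations plot per-unit precision/recall/F1 bars; CC plots
#' the train-by-test F1 heatmap.
#'
#' @param object A `ppi_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_eval
#' @export
autoplot.ppi_eval <- function(object, ...) {
  if (object$protocol == "cc") {
    df <- tidy(object)
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$test, .data$train,
                                       fill = .data$f1)) +
        ggplot2::geom_tile() +
        ggplot2::geom_text(ggplot2::aes(
          label = sprintf("%.2f", .data$f1)
        ), color = "white") +
        ggplot2::labs(title = "Cross-corpus F1", x = "test corpus",
                      y = "training corpus") +
        ggplot2::theme_minimal()
    )
  }
  unit <- if (object$protocol == "cv") "fold" else "corpus"
  df <- tidy(object) |>
    dplyr::mutate(unit = as.factor(.data[[unit]])) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$unit, .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = unit, y = NULL,
                  title = "Held-out precision / recall / F1") +
    ggplot2::theme_minimal()
}

#' Plot mined interaction patterns
#'
#' Bar chart of the summed-LLR scores of the retained patterns.
#'
#' @param object An `interaction_patterns` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_patterns
#' @export
autoplot.interaction_patterns <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    .data$score, stats::reorder(.data$pattern, .data$score)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "summed LLR score", y = NULL,
                  title = "Mined interaction patterns") +
    ggplot2::theme_minimal()
}

#' Plot a Gram matrix
#'
#' @param object A `gram_matrix`.
#' @param ... Unused.
#' @return A ggplot heatmap of kernel values.
#' @method autoplot gram_matrix
#' @export
autoplot.gram_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::tibble(
    i = as.vector(row(m)), j = as.vector(col(m)), k = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$k)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "kernel",
                  title = "Convolution tree kernel Gram matrix") +
    ggplot2::theme_minimal()
}
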