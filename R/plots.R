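#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an SSE profile
#'
#' SSE against the number of cluster solutions, the curve used to select
#' the cluster count: the selected k (dashed line) is where the reduction
#' reaches `threshold` of the achievable reduction.
#'
#' @param object An `sse_profile`.
#' @param threshold Selection threshold to annotate (default 0.9).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sse_profile <- function(object, threshold = 0.9, ...) {
  k_best <- select_k(object, threshold = threshold)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$sse)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = k_best, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Number of cluster solutions", y = "SSE",
                  title = sprintf("SSE profile (selected k = %d)", k_best)) +
    ggplot2::theme_minimal()
}

#' Plot measure distributions of an ambiguity table
#'
#' Histograms of log CD, SemD, and SemVar over the scored lexicon.
#'
#' @param object An `ambiguity_table`.
#' @param bins Histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ambiguity_table <- function(object, bins = 30, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("log_cd", "semd", "semvar")],
    cols = dplyr::everything(), names_to = "measure", values_to = "value"
  )
  long$measure <- factor(long$measure, levels = c("log_cd", "semd", "semvar"),
                         labels = c("log CD", "SemD", "SemVar"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white", na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = NULL, y = "Words") +
    ggplot2::theme_minimal()
}

#' Plot class separation of the ambiguity measures
#'
#' SemVar and SemD by planted word class, for judging how strongly each
#' measure separates homonyms from polysemes.
#'
#' @param records An `ambiguity_table`.
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @return A ggplot.
#' @export
plot_separation <- function(records, truth) {
  joined <- dplyr::inner_join(truth, tibble::as_tibble(records), by = "word")
  long <- tidyr::pivot_longer(joined[, c("class", "semd", "semvar")],
                              cols = c("semd", "semvar"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.7, na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
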