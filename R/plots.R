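#' Plot the per-source agreement breakdown
#'
#' @param breakdown Output of [agreement_by_source()].
#' @return A ggplot.
#' @export
plot_agreement <- function(breakdown) {
  ggplot2::ggplot(breakdown,
                  ggplot2::aes(x = .data$source_id, y = .data$pct_agree)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%",
                                                    .data$pct_agree)),
                       vjust = -0.4, size = 3.2) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "annotation source", y = "% agreement",
                  title = "Validator agreement by source") +
    ggplot2::theme_minimal()
}

#' Plot agreement by order of appearance
#'
#' @param cells Output of [order_effect()].
#' @return A ggplot.
#' @export
plot_order_effect <- function(cells) {
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = factor(.data$rank), y = .data$pct_agree,
                               group = .data$source_id,
                               colour = .data$source_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "order of appearance", y = "% agreement",
                  colour = "source",
                  title = "Agreement by order of appearance") +
    ggplot2::theme_minimal()
}

#' Plot session durations and throughput
#'
#' @param sessions Output of [detect_sessions()].
#' @return A ggplot.
#' @export
plot_sessions <- function(sessions) {
  ggplot2::ggplot(sessions,
                  ggplot2::aes(x = factor(.data$session),
                               y = .data$n_items)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$duration_hours)) +
    ggplot2::labs(x = "session", y = "items labeled",
                  fill = "duration (h)",
                  title = "Annotation sessions") +
    ggplot2::theme_minimal()
}
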