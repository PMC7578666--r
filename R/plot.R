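#' Draw a classic enrichment plot
#'
#' Renders the running enrichment score, the member-position ticks and
#' the centered interaction-count bars for one gene set, in the familiar
#' three-panel layout.
#'
#' @param bundle An `enrichment_plot_data` from [plot_data()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(bundle) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_enrichment() requires the ggplot2 package")
  }
  n <- length(bundle$running_score)
  df <- tibble::tibble(rank = seq_len(n),
                       running = bundle$running_score,
                       centered = bundle$centered_scores)
  hits <- tibble::tibble(rank = bundle$hit_positions)
  scale_f <- max(abs(df$running)) /
    max(abs(df$centered), .Machine$double.eps)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$centered * scale_f * 0.5),
                      width = 1, fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$running),
                       colour = "#2c7fb8", linewidth = 0.7) +
    ggplot2::geom_rug(data = hits, ggplot2::aes(x = .data$rank),
                      inherit.aes = FALSE, sides = "b", length =
                        ggplot2::unit(0.03, "npc")) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2,
                        linewidth = 0.3) +
    ggplot2::labs(
      title = sprintf("%s (%s)", bundle$set_name, bundle$collection),
      subtitle = sprintf("ES = %.3f at rank %d", bundle$es,
                         bundle$es_position),
      x = "rank by centered chemical-gene interaction count",
      y = "running enrichment score"
    ) +
    ggplot2::theme_minimal()
}
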