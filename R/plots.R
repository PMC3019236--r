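#' Plot per-bin gene densities
#'
#' Bars of gene density per deletion bin in chromosome order; when island
#' statistics are present ([island_bin_stats()]), island and isolated
#' densities are stacked and the island percentage is printed on the bars.
#'
#' @param object A `bin_stats` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bin_stats <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  df$bin <- factor(df$bin, levels = df$bin)
  if (all(c("island_density", "isolated_density") %in% names(df))) {
    long <- tidyr::pivot_longer(df, c("isolated_density", "island_density"),
                                names_to = "class", values_to = "d")
    long$class <- factor(long$class, levels = c("isolated_density", "island_density"),
                         labels = c("isolated", "island"))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$d,
                                            fill = .data$class)) +
      ggplot2::geom_col() +
      ggplot2::geom_text(
        data = df, inherit.aes = FALSE,
        ggplot2::aes(x = .data$bin, y = .data$density,
                     label = paste0(round(.data$pct_island), "%")),
        vjust = -0.4, size = 3
      ) +
      ggplot2::labs(fill = NULL, y = "gene density (loci / Mb)")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$density)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(y = "gene density (loci / Mb)")
  }
  p + ggplot2::labs(x = "deletion bin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heat map of a signal matrix
#'
#' Probe-by-pool intensities on a log scale, pools grouped by axis; spikes
#' above the background band are the positive pools the scoring methods
#' call.
#'
#' @param object A [signal_matrix()].
#' @param max_probes Subsample cap for readability.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_matrix <- function(object, max_probes = 100, ...) {
  layout <- attr(object, "layout")
  df <- as_tibble(as.data.frame(object))
  if (nrow(df) > max_probes) df <- df[seq_len(max_probes), , drop = FALSE]
  long <- tidyr::pivot_longer(df, -"probe_id", names_to = "pool_id",
                              values_to = "value")
  long$axis <- layout$axis[match(long$pool_id, layout$pool_id)]
  long$pool_id <- factor(long$pool_id, levels = layout$pool_id)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pool_id, y = .data$probe_id,
                                     fill = log1p(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(. ~ axis, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_viridis_c(name = "log(1+signal)") +
    ggplot2::labs(x = "pool", y = "probe") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot synteny blocks along the reference
#'
#' Horizontal segments of each deletion bin's synteny block interval on the
#' reference map, in bin order; overlaps between segments reveal
#' order-breaking rearrangements.
#'
#' @param blocks A [build_synteny_blocks()] result.
#' @return A ggplot object.
#' @export
plot_synteny_blocks <- function(blocks) {
  df <- blocks[!is.na(blocks$ref_min), , drop = FALSE]
  df$bin <- factor(df$bin, levels = rev(blocks$bin))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$bin)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ref_min, xend = .data$ref_max,
                                       yend = .data$bin),
                          linewidth = 3, colour = "steelblue") +
    ggplot2::labs(x = "reference position", y = "deletion bin") +
    ggplot2::theme_minimal()
}
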