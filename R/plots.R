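#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text
#'   scale_fill_gradient labs theme_minimal geom_col
#' @export
ggplot2::autoplot

#' Plot a cluster heatmap
#'
#' Renders the 4 x 5 grid with the spatial arrangement of the flow plots
#' (GFP levels left to right, BFP levels bottom to top) and the value
#' printed in each bin.
#'
#' @param object A `cluster_heatmap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_heatmap
#' @export
autoplot.cluster_heatmap <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$gfp_level, y = .data$bfp_level,
                 fill = .data$value)) +
    geom_tile(colour = "grey30") +
    geom_text(aes(label = ifelse(is.nan(.data$value), "-",
                                 sprintf("%.1f", .data$value))),
              size = 3) +
    scale_fill_gradient(low = "white", high = "firebrick",
                        na.value = "grey90") +
    labs(x = "GFP level", y = "BFP level", fill = attr(object, "kind")) +
    theme_minimal()
}

#' Plot an LD size histogram
#'
#' @param summary Output of [ld_summary()].
#' @return A ggplot object.
#' @export
plot_ld_sizes <- function(summary) {
  df <- summary$histogram
  df$bin <- factor(df$bin, levels = df$bin)
  ggplot(df, aes(x = .data$bin, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "deletion size (bp)", y = "LD reads") +
    theme_minimal()
}
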