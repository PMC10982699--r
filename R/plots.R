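#' Plot an aggregate bias curve with its 2xSE ribbon
#'
#' @param profile A [bias_profile()].
#' @param which `"normalized"` (BrdU-subtracted, default) or `"raw"`.
#' @return A ggplot object.
#' @export
plot_bias_aggregate <- function(profile, which = c("normalized", "raw")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  which <- match.arg(which)
  agg <- if (which == "normalized") profile$aggregate else profile$aggregate_raw
  agg <- agg[is.finite(agg$mean), ]
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$bin_center, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$halfwidth,
                                      ymax = .data$mean + .data$halfwidth),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance from origin (bp)",
                  y = "(W - C)/(W + C), BrdU-subtracted",
                  title = paste0(profile$mark, " eSPAN bias, ",
                                 profile$genotype_label,
                                 " (mean ± 2 SE, n = ", nrow(profile$raw),
                                 " origins)")) +
    ggplot2::theme_classic()
}

#' Violin plot of strand-resolved densities per genotype
#'
#' @param table A [density_table()].
#' @return A ggplot object.
#' @export
plot_density_violin <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- table[is.finite(table$density), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$density,
                                  fill = .data$strand_class)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         scale = "width") +
    ggplot2::labs(x = NULL, y = "BrdU-relative density",
                  fill = "strand") +
    ggplot2::theme_classic()
}
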