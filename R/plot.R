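#' Plot group-average AIS profiles
#'
#' Mean normalized intensity per group (line) with an SEM band, and the
#' AIS interval shaded, in the style of per-condition profile figures.
#' Advisory output; not part of the tested numeric contract.
#'
#' @param group_profiles data frame from [run_pipeline()]'s
#'   `group_profiles.csv` (columns `genotype`, `age`, `position`, `mean`,
#'   `sem`) or from [aggregate_group()] with `genotype`/`age` columns
#'   added.
#' @param interval optional [ais_interval()] to shade.
#' @return A ggplot object.
#' @export
plot_group_profile <- function(group_profiles, interval = NULL) {
  gp <- group_profiles
  gp$group <- paste(gp$genotype, gp$age)
  p <- ggplot2::ggplot(gp, ggplot2::aes(
    x = .data$position, y = .data$mean,
    ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem,
    colour = .data$group, fill = .data$group))
  if (!is.null(interval))
    p <- p + ggplot2::annotate(
      "rect", xmin = interval$distal_edge, xmax = interval$proximal_edge,
      ymin = -Inf, ymax = Inf, alpha = 0.12)
  p + ggplot2::geom_ribbon(alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(
      x = "position along peduncle (um, distal negative)",
      y = "normalized mitochondrial intensity",
      colour = NULL, fill = NULL) +
    ggplot2::theme_classic()
}
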