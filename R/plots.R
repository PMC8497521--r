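## Report figures. Styling mirrors the standard presentation of these
## experiments: loss proportion against corrected depth with
## biomass-weighted LOESS lines, per-bead loss-ratio boxplots, log10 size
## against normalized radial distance with a 95% band, and multi-day loss
## trajectories with SEM error bars.

#' Plot depth-resolved plasmid loss with LOESS curves
#'
#' Points are the per-layer loss proportions (area proportional to the
#' layer biomass), lines the biomass-weighted LOESS fit per replicate.
#'
#' @param profiles averaged profile data.frame with `zCorrected`, `pLoss`,
#'   `biomass` and a `replicate` column.
#' @param curves LOESS curve data.frame with `position`, `clipped`,
#'   `replicate`.
#' @return a ggplot object.
#' @export
plotLossCurve <- function(profiles, curves) {
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = profiles,
      ggplot2::aes(x = .data$zCorrected, y = .data$pLoss,
                   size = .data$biomass),
      alpha = 0.3, colour = "grey40") +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$position, y = .data$clipped,
                   group = .data$replicate),
      colour = "red") +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "corrected z position (layers)",
                  y = "proportion plasmid-free", size = "biomass") +
    ggplot2::theme_bw()
}

#' Boxplot of per-bead plasmid-loss ratios
#'
#' Center line = median, box = quartiles, whiskers = 1.5 x IQR, points =
#' outliers.
#'
#' @param perBead data.frame with a `ratio` column (one row per bead).
#' @return a ggplot object.
#' @export
plotLossRatioBox <- function(perBead) {
  ggplot2::ggplot(perBead, ggplot2::aes(x = "", y = .data$ratio)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.colour = "black") +
    ggplot2::labs(x = NULL, y = "plasmid-free : plasmid-carrying aggregates") +
    ggplot2::theme_bw()
}

#' Aggregate size against normalized distance from the bead center
#'
#' @param table a filtered, normalized AggregateTable.
#' @param band regression band from [sizeDistanceRegression()] (`$band`).
#' @return a ggplot object.
#' @export
plotSizeDistance <- function(table, band) {
  tab <- table[table$retained %in% TRUE, , drop = FALSE]
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = tab,
      ggplot2::aes(x = .data$normalizedDistance, y = log10(.data$volume),
                   colour = .data$channel), alpha = 0.6) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$d, ymin = .data$lwr, ymax = .data$upr),
      alpha = 0.25) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$d, y = .data$fit)) +
    ggplot2::scale_colour_manual(
      values = c(free = "forestgreen", carrier = "firebrick")) +
    ggplot2::labs(x = "normalized distance from bead center",
                  y = expression(log[10] ~ "aggregate volume (" * mu * m^3 * ")"),
                  colour = "plasmid status") +
    ggplot2::theme_bw()
}

#' Plasmid-loss trajectory with SEM error bars
#'
#' @param summary trajectory summary from [aggregateTrajectory()].
#' @return a ggplot object.
#' @export
plotTrajectory <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$day, y = .data$mean,
                               colour = .data$strain,
                               linetype = .data$plasmid)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.1) +
    ggplot2::labs(x = "day", y = "plasmid-free fraction") +
    ggplot2::theme_bw()
}
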