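#' Phase-diagram heatmap of a region map
#'
#' Colours each grid cell by its dominant strategy and overlays contours of
#' constant equilibrium OSR (and optionally ASR), the quantities that track
#' the strategy boundary.
#'
#' @param map a \code{\link{run_grid}} result.
#' @param contour one of \code{"osr"}, \code{"asr"}, \code{"both"},
#'   \code{"none"}.
#' @param bins approximate number of contour levels.
#' @return A ggplot object.
#' @export
plot_region_map <- function(map, contour = c("osr", "asr", "both", "none"),
                            bins = 8) {
  stopifnot(inherits(map, "region_map"))
  contour <- match.arg(contour)
  n1 <- length(map$axis1$values); n2 <- length(map$axis2$values)
  grid <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  df <- data.frame(x = map$axis1$values[grid$i],
                   y = map$axis2$values[grid$j],
                   dominance = map$dominance[cbind(grid$i, grid$j)],
                   osr = map$osr[cbind(grid$i, grid$j)],
                   asr = map$asr[cbind(grid$i, grid$j)])
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$dominance)) +
    ggplot2::scale_fill_manual(
      values = c(multiple_mating = "#D55E00", guarding = "#0072B2",
                 coexistence = "#CC79A7", extinct = "grey40"),
      na.value = "grey80", name = "dominant strategy") +
    ggplot2::labs(x = map$axis1$name, y = map$axis2$name) +
    ggplot2::theme_minimal()
  if (contour %in% c("osr", "both"))
    pl <- pl + ggplot2::geom_contour(ggplot2::aes(z = .data$osr),
                                     bins = bins, colour = "black",
                                     na.rm = TRUE)
  if (contour %in% c("asr", "both"))
    pl <- pl + ggplot2::geom_contour(ggplot2::aes(z = .data$asr),
                                     bins = bins, colour = "white",
                                     linetype = 2, na.rm = TRUE)
  pl
}

#' Equilibrium sex-ratio curves
#'
#' Line plot of equilibrium OSR (solid) and ASR (dashed) against the varied
#' parameter, as produced by \code{\link{osr_curve}}.
#'
#' @param curve an \code{\link{osr_curve}} result.
#' @param xlab x-axis label.
#' @return A ggplot object.
#' @export
plot_osr_curve <- function(curve, xlab = "parameter value") {
  long <- rbind(data.frame(value = curve$value, ratio = curve$osr,
                           which = "OSR"),
                data.frame(value = curve$value, ratio = curve$asr,
                           which = "ASR"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$ratio,
                                     linetype = .data$which)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = xlab, y = "males per female", linetype = NULL) +
    ggplot2::theme_minimal()
}
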