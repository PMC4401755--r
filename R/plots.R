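#' Plot a pulse-height spectrum
#'
#' Channel counts on a log scale; photopeaks of 40K (1.464 MeV) and 208Tl
#' (2.615 MeV) are the prominent features in natural-background spectra.
#'
#' @param object A `ph_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ph_spectrum <- function(object, ...) {
  d <- tibble(channel = seq_along(object$counts), counts = object$counts)
  ggplot2::ggplot(d, ggplot2::aes(.data$channel, .data$counts)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "channel", y = "counts",
                  title = sprintf("Pulse-height spectrum (%.0f s live)", object$live_time))
}

#' Plot an unfolded energy-bin spectrum
#'
#' @param object An `energy_spectrum`.
#' @param ... Unused.
#' @return A ggplot of per-bin flux density with error bars.
#' @export
autoplot.energy_spectrum <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$energy, .data$flux)) +
    ggplot2::geom_col(width = object$bins$width, fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$flux - .data$se,
                                        ymax = .data$flux + .data$se),
                           width = 0) +
    ggplot2::labs(x = "energy (MeV)", y = expression(flux~(cm^-2~s^-1~bin^-1)))
}

#' Plot an activity field
#'
#' @param object An `activity_field`.
#' @param nuclide Which grid to show.
#' @param ... Unused.
#' @return A ggplot raster of activity concentration.
#' @export
autoplot.activity_field <- function(object, nuclide = "Th232_series", ...) {
  d <- tidy(object)
  col <- c(K40 = "k40", U238_series = "u238", Th232_series = "th232")[[nuclide]]
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat, fill = .data[[col]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste0(nuclide, "\n(Bq/kg)")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' Plot a gridded dose map
#'
#' @param object A `dose_raster` from [grid_dose_map()].
#' @param value `"kerma_mean"` or `"dose_mean"`.
#' @param ... Unused.
#' @return A ggplot tile map; empty cells are blank.
#' @export
autoplot.dose_raster <- function(object, value = "kerma_mean", ...) {
  d <- as_tibble(object) %>% filter(.data$n > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat, fill = .data[[value]])) +
    ggplot2::geom_tile(width = attr(object, "cell_deg"),
                       height = attr(object, "cell_deg")) +
    ggplot2::scale_fill_viridis_c(name = if (value == "kerma_mean") "kerma\n(nGy/h)" else "dose\n(mSv/y)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude")
}
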