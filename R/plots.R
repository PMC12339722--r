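# ggplot2 displays for the main result types.

#' Polar histogram of spike phases
#'
#' Rose plot of a unit's spike phases in the trough-at-pi convention (0 =
#' LFP peak, +/-pi = trough).
#'
#' @param spike_table A `spike_phase_table` tibble (column `phase`).
#' @param bins Number of angular bins (default 24).
#' @return A ggplot object.
#' @export
plot_phase_histogram <- function(spike_table, bins = 24) {
  ggplot2::ggplot(spike_table, ggplot2::aes(x = .data$phase)) +
    ggplot2::geom_histogram(bins = bins, boundary = -pi,
                            fill = "steelblue", colour = "white") +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-pi, pi),
                                breaks = c(-pi / 2, 0, pi / 2, pi),
                                labels = c("-π/2", "0 (peak)",
                                           "π/2", "π (trough)")) +
    ggplot2::labs(x = NULL, y = "spike count") +
    ggplot2::theme_minimal()
}

#' Plot a spike-field coherence spectrum
#'
#' @param object An [sfc_spectrum()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfc_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$sfc)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "frequency (Hz)", y = "SFC (%)") +
    ggplot2::theme_minimal()
}

#' Plot time-resolved aperiodic exponents
#'
#' @param frame_fits Output of [fit_frames()].
#' @return A ggplot object.
#' @export
plot_aperiodic_exponent <- function(frame_fits) {
  ggplot2::ggplot(frame_fits[frame_fits$valid, ],
                  ggplot2::aes(x = .data$time, y = .data$exponent)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "aperiodic exponent χ") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
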