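# ggplot2 displays for maps, pitch tracks, descriptors and evaluations.

#' @describeIn acoustic_map Heatmap of the SPL grid with the peak marked.
#' @param object An `acoustic_map`.
#' @param ... Unused.
#' @export
autoplot.acoustic_map <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$x, y = .data$y,
                                            fill = .data$spl)) +
    ggplot2::geom_raster() +
    ggplot2::annotate("point", x = object$peak$x, y = object$peak$y,
                      shape = 3, size = 3, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "dB SPL") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (m)", y = "y (m)",
      title = sprintf("Acoustic map, window [%.2f, %.2f] s",
                      object$window[1], object$window[2])
    )
}

#' @describeIn extract_pitch Pitch track with voicing strength.
#' @param object A `pitch_track`.
#' @param ... Unused.
#' @export
autoplot.pitch_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$f0,
                                       alpha = .data$strength)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "F0 (Hz)") +
    ggplot2::guides(alpha = "none")
}

#' Heatmap of descriptor vectors by class
#'
#' One row per call, 26 spectral-envelope components over 0-500 Hz,
#' grouped by emission class — the fingerprint view that makes the
#' nasal/oral envelope difference visible at a glance.
#'
#' @param descriptors Tibble from [build_descriptors()].
#' @param fmax Upper band edge in Hz used to label the component axis.
#' @return A ggplot object.
#' @export
plot_descriptors <- function(descriptors, fmax = 500) {
  cols <- descriptor_cols(descriptors)
  long <- descriptors |>
    dplyr::mutate(row = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "component",
                        values_to = "level") |>
    dplyr::mutate(
      frequency = (as.integer(sub("^d", "", .data$component)) - 0.5) *
        fmax / length(cols)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frequency, y = .data$row,
                                     fill = .data$level)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$label), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "frequency (Hz)", y = "call")
}

#' @describeIn evaluate Bar chart of held-out accuracy per classifier.
#' @param object A `rumble_eval`.
#' @param ... Unused.
#' @export
autoplot.rumble_eval <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$classifier, y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "held-out accuracy")
}
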