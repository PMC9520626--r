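#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_col
#'   geom_point geom_abline labs scale_fill_viridis_c theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a power spectrum
#'
#' @param object A `power_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot power_spectrum
#' @export
autoplot.power_spectrum <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(.data$freq_hz, .data$psd_uv2_per_hz)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz))) +
    theme_minimal()
}

#' Plot a phase-amplitude distribution
#'
#' Bar height is the normalized mean amplitude per 15-degree phase bin; a
#' flat profile means no coupling.
#'
#' @param object A `phase_amplitude_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phase_amplitude_distribution
#' @export
autoplot.phase_amplitude_distribution <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(.data$phase_center * 180 / pi, .data$p)) +
    geom_col(width = 360 / nrow(object)) +
    labs(x = "theta phase (deg)", y = "normalized mean gamma amplitude") +
    theme_minimal()
}

#' Plot a comodulogram heatmap
#'
#' @param object A `comodulogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot comodulogram
#' @export
autoplot.comodulogram <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(.data$phase_freq_hz, .data$amp_freq_hz, fill = .data$mi)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey90") +
    labs(x = "phase frequency (Hz)", y = "amplitude frequency (Hz)",
         fill = "MI") +
    theme_minimal()
}

#' Plot a learning curve
#'
#' @param object A `learning_curve`.
#' @param ... Unused.
#' @param threshold Optional criterion line (default 0.8).
#' @return A ggplot.
#' @method autoplot learning_curve
#' @export
autoplot.learning_curve <- function(object, ..., threshold = 0.8) {
  ggplot(tibble::as_tibble(object), aes(.data$window_end, .data$accuracy)) +
    geom_line() + geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::ylim(0, 1) +
    labs(x = "trial (window end)", y = "windowed accuracy") +
    theme_minimal()
}

#' Plot a correlation fit with its regression line
#'
#' @param object A `correlation_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot correlation_fit
#' @export
autoplot.correlation_fit <- function(object, ...) {
  ggplot(object$data, aes(.data$x, .data$y)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept) +
    labs(title = sprintf("r = %.2f, p = %.3g (Pearson, n = %d)",
                         object$r, object$p, object$n)) +
    theme_minimal()
}
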