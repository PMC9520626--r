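#' Remove mean and linear trend from a recording
#'
#' Least-squares linear detrend: the fitted intercept and slope are
#' subtracted, so the output has zero mean and zero linear trend. A constant
#' trace detrends to all zeros.
#'
#' @param rec An [lfp_recording].
#' @return A detrended [lfp_recording] of the same length and labels.
#' @export
detrend_signal <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  n <- length(rec$samples)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), rec$samples)
  out <- rec
  out$samples <- as.numeric(rec$samples - cbind(1, t) %*% fit$coefficients)
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Butterworth band-pass (default order 4) applied forward and backward
#' ([signal::filtfilt]), giving zero phase distortion and an effective
#' order of 8. Standard bands here are theta (8-13 Hz for phase, 8-12 Hz
#' for spectra) and gamma (30-42 or 30-45 Hz). Filter transients live in
#' roughly the first/last second of the output; downstream statistics trim
#' them (see [analytic_phase_amplitude()]).
#'
#' @param rec An [lfp_recording].
#' @param band A [band_spec]; `high_hz` must be below the Nyquist frequency.
#' @param order Butterworth order of the one-way prototype (default 4).
#' @return The band-limited [lfp_recording].
#' @export
bandpass <- function(rec, band, order = 4) {
  stopifnot(inherits(rec, "lfp_recording"), inherits(band, "band_spec"))
  nyq <- rec$fs_hz / 2
  if (band$high_hz >= nyq)
    tg_stop(sprintf("band edge %g Hz >= Nyquist (%g Hz)", band$high_hz, nyq),
            "tg_parameter_error")
  bf <- signal::butter(order, c(band$low_hz, band$high_hz) / nyq, type = "pass")
  out <- rec
  out$samples <- as.numeric(signal::filtfilt(bf, rec$samples))
  out
}

#' Welch averaged-periodogram power spectral density
#'
#' Hann-tapered periodograms over sliding windows (window `window_s`, step
#' `step_s`, both in seconds), averaged across the whole trace. Density
#' normalization: the integral of the one-sided PSD over frequency equals the
#' signal variance (Parseval), so units are uV^2/Hz. Each window is
#' mean-subtracted before tapering.
#'
#' @param rec An [lfp_recording].
#' @param window_s Window length in seconds (default 1, i.e. 1 Hz resolution
#'   at any sampling rate).
#' @param step_s Step between window starts in seconds (default 0.1).
#' @return A `power_spectrum` object: tibble columns `freq_hz`,
#'   `psd_uv2_per_hz`, with attributes `window_s`, `step_s`, `n_windows`,
#'   `fs_hz`.
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 40 * seq(0, 10, by = 1 / 500)), 500)
#' ps <- estimate_power_spectrum(rec)
#' ps$freq_hz[which.max(ps$psd_uv2_per_hz)]  # 40
#' @export
estimate_power_spectrum <- function(rec, window_s = 1, step_s = 0.1) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (!(window_s >= step_s && step_s > 0))
    tg_stop("need window_s >= step_s > 0", "tg_parameter_error")
  fs <- rec$fs_hz
  x <- rec$samples
  nw <- round(window_s * fs)
  ns <- max(1L, round(step_s * fs))
  if (nw > length(x))
    tg_stop("window longer than the recording", "tg_parameter_error")
  starts <- seq(1L, length(x) - nw + 1L, by = ns)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))  # Hann
  u <- fs * sum(w^2)                                     # density norm
  nfreq <- nw %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg)[seq_len(nfreq)])^2 / u
    acc <- acc + p
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nw is even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nw %% 2L == 0L) dbl[nfreq] <- 1
  psd <- psd * dbl
  out <- tibble::tibble(freq_hz = (seq_len(nfreq) - 1) * fs / nw,
                        psd_uv2_per_hz = psd)
  attr(out, "window_s") <- window_s
  attr(out, "step_s") <- step_s
  attr(out, "n_windows") <- length(starts)
  attr(out, "fs_hz") <- fs
  class(out) <- c("power_spectrum", class(out))
  out
}

#' Band-integrated power from a power spectrum
#'
#' Trapezoidal integral of the PSD over `[low_hz, high_hz]`, with the PSD
#' linearly interpolated at the band edges, plus the mean density over the
#' band (the per-Hz summary used in group comparisons of spontaneous gamma
#' power).
#'
#' @param spec A `power_spectrum` from [estimate_power_spectrum()].
#' @param band A [band_spec] inside the spectrum's frequency range.
#' @return A one-row tibble: `low_hz`, `high_hz`, `power_uv2`,
#'   `mean_density_uv2_per_hz`.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "power_spectrum"), inherits(band, "band_spec"))
  f <- spec$freq_hz; p <- spec$psd_uv2_per_hz
  if (band$low_hz < min(f) || band$high_hz > max(f))
    tg_stop("band outside the spectrum's frequency grid", "tg_parameter_error")
  inside <- f > band$low_hz & f < band$high_hz
  fi <- c(band$low_hz, f[inside], band$high_hz)
  pi_ <- c(stats::approx(f, p, band$low_hz)$y, p[inside],
           stats::approx(f, p, band$high_hz)$y)
  pow <- sum(diff(fi) * (head(pi_, -1) + tail(pi_, -1)) / 2)
  tibble::tibble(low_hz = band$low_hz, high_hz = band$high_hz,
                 power_uv2 = pow,
                 mean_density_uv2_per_hz = pow / (band$high_hz - band$low_hz))
}

#' Write / read a power spectrum as TSV
#'
#' Plain two-column TSV (`freq_hz`, `psd_uv2_per_hz`).
#'
#' @param spec A `power_spectrum`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_power_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "power_spectrum"))
  utils::write.table(
    data.frame(freq_hz = sprintf("%.10g", spec$freq_hz),
               psd_uv2_per_hz = sprintf("%.10g", spec$psd_uv2_per_hz)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
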