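#' Analytic signal via the discrete Hilbert transform
#'
#' FFT construction: positive frequencies doubled, negative zeroed, DC (and
#' Nyquist for even lengths) kept, then inverse-transformed. For a
#' band-limited real input the modulus is the instantaneous amplitude
#' envelope and the argument the instantaneous phase.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude of a band-filtered pair
#'
#' Given the slow-band (theta) and fast-band (gamma) filtered versions of the
#' same trace, extracts the slow signal's instantaneous phase and the fast
#' signal's amplitude envelope via the Hilbert transform, then trims
#' `edge_trim_s` seconds from each end to drop filter and Hilbert edge
#' transients.
#'
#' @param slow,fast Band-filtered [lfp_recording]s with identical sampling
#'   rate and length.
#' @param edge_trim_s Seconds removed from each end (default 1).
#' @return An `analytic_series` tibble with columns `phase` (radians in
#'   `[-pi, pi)`) and `amplitude` (uV), attribute `fs_hz`.
#' @export
analytic_phase_amplitude <- function(slow, fast, edge_trim_s = 1) {
  stopifnot(inherits(slow, "lfp_recording"), inherits(fast, "lfp_recording"))
  if (length(slow$samples) != length(fast$samples) || slow$fs_hz != fast$fs_hz)
    tg_stop("slow/fast recordings differ in length or sampling rate",
            "tg_consistency_error")
  n <- length(slow$samples)
  trim <- round(edge_trim_s * slow$fs_hz)
  if (2 * trim >= n)
    tg_stop("edge trim removes the whole trace", "tg_parameter_error")
  keep <- (trim + 1L):(n - trim)
  ph <- Arg(analytic_signal(slow$samples))[keep]
  ph[ph >= pi] <- ph[ph >= pi] - 2 * pi   # phase = pi wraps to -pi
  am <- Mod(analytic_signal(fast$samples))[keep]
  out <- tibble::tibble(phase = ph, amplitude = am)
  attr(out, "fs_hz") <- slow$fs_hz
  class(out) <- c("analytic_series", class(out))
  out
}

#' Phase-binned mean amplitude distribution
#'
#' Partitions the phase axis into `n_bins` equal half-open bins
#' `[-pi + j*delta, -pi + (j+1)*delta)` (default 24 bins of 15 degrees),
#' averages the fast-band amplitude within each bin, and normalizes the bin
#' means to a distribution `p` summing to 1. A phase exactly on an edge goes
#' to the upper bin. Empty bins get mean amplitude 0 and raise the
#' `empty_bins` flag (attribute), which downstream group statistics use to
#' exclude the result.
#'
#' @param series An `analytic_series` (or any data frame with `phase` and
#'   `amplitude` columns).
#' @param n_bins Number of phase bins, at least 2 (default 24).
#' @return A `phase_amplitude_distribution` tibble: `bin`, `phase_lo`,
#'   `phase_hi`, `phase_center` (radians), `mean_amp`, `p`; attribute
#'   `empty_bins` (integer vector of empty bin indices).
#' @export
phase_amplitude_distribution <- function(series, n_bins = 24) {
  if (!is.numeric(n_bins) || n_bins < 2)
    tg_stop("`n_bins` must be at least 2", "tg_parameter_error")
  n_bins <- as.integer(n_bins)
  ph <- series$phase
  am <- series$amplitude
  stopifnot(length(ph) == length(am))
  delta <- 2 * pi / n_bins
  j <- pmin(floor((ph + pi) / delta), n_bins - 1L) + 1L
  mean_amp <- rep(0, n_bins)
  cnt <- tabulate(j, nbins = n_bins)
  sums <- vapply(split(am, factor(j, levels = seq_len(n_bins))), sum, 0)
  nonempty <- cnt > 0L
  mean_amp[nonempty] <- sums[nonempty] / cnt[nonempty]
  tot <- sum(mean_amp)
  p <- if (tot > 0) mean_amp / tot else rep(1 / n_bins, n_bins)
  empty <- which(!nonempty)
  if (length(empty) > 0)
    rlang::warn(sprintf("%d empty phase bin(s); result flagged", length(empty)),
                class = "tg_empty_bins")
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    phase_lo = -pi + (seq_len(n_bins) - 1) * delta,
    phase_hi = -pi + seq_len(n_bins) * delta,
    phase_center = -pi + (seq_len(n_bins) - 0.5) * delta,
    mean_amp = mean_amp, p = p
  )
  attr(out, "empty_bins") <- empty
  attr(out, "n_samples") <- length(ph)
  class(out) <- c("phase_amplitude_distribution", class(out))
  out
}

#' Tort modulation index
#'
#' Normalized Kullback-Leibler distance of the phase-binned amplitude
#' distribution from uniform:
#' `MI = (ln N - H(p)) / ln N` with Shannon entropy
#' `H(p) = -sum_j p_j ln p_j` (natural log, `0 ln 0 = 0`) over the `N` phase
#' bins. MI is 0 for a flat distribution (no coupling) and 1 when all
#' amplitude sits in one bin.
#'
#' @param dist A `phase_amplitude_distribution` from
#'   [phase_amplitude_distribution()], or a bare numeric probability vector.
#' @return A one-row tibble: `mi`, `entropy`, `n_bins`, `n_samples`,
#'   `flagged` (TRUE when empty phase bins were present).
#' @examples
#' modulation_index(rep(1 / 24, 24))$mi                 # 0
#' modulation_index(c(1, rep(0, 23)))$mi                # 1
#' modulation_index(c(0.5, 0.5, rep(0, 22)))$mi         # 1 - log(2)/log(24)
#' @export
modulation_index <- function(dist) {
  if (is.numeric(dist)) {
    p <- dist
    flagged <- FALSE
    n_samples <- NA_integer_
  } else {
    p <- dist$p
    flagged <- length(attr(dist, "empty_bins")) > 0
    n_samples <- attr(dist, "n_samples") %||% NA_integer_
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    tg_stop("`p` must be a probability vector", "tg_parameter_error")
  n <- length(p)
  nz <- p > 0
  # KL-to-uniform form of (ln N - H)/ln N: exact 0 at uniform, exact 1 one-hot
  mi <- sum(p[nz] * log(p[nz] * n)) / log(n)
  tibble::tibble(mi = mi, entropy = -sum(p[nz] * log(p[nz])), n_bins = n,
                 n_samples = n_samples, flagged = flagged)
}

#' Modulation index of a raw recording for a band pair
#'
#' Convenience composition of the full MI path: detrend, band-pass the slow
#' and fast bands, Hilbert phase/amplitude with edge trim, 15-degree binning,
#' Tort MI. Band defaults follow the coupling analysis convention
#' (theta 8-13 Hz, gamma 30-42 Hz).
#'
#' @param rec An [lfp_recording] (raw; detrended internally).
#' @param phase_band,amp_band [band_spec]s for the slow and fast bands.
#' @param n_bins Phase bins (default 24).
#' @param edge_trim_s Seconds trimmed per end (default 1).
#' @param detrend Detrend first (default TRUE).
#' @return One-row tibble: `subject_id`, `group`, `phase_lo`, `phase_hi`,
#'   `amp_lo`, `amp_hi`, `mi`, `flagged`, `n_samples`.
#' @export
mi_from_recording <- function(rec, phase_band = band_spec(8, 13),
                              amp_band = band_spec(30, 42), n_bins = 24,
                              edge_trim_s = 1, detrend = TRUE) {
  if (detrend) rec <- detrend_signal(rec)
  ser <- analytic_phase_amplitude(bandpass(rec, phase_band),
                                  bandpass(rec, amp_band),
                                  edge_trim_s = edge_trim_s)
  dist <- phase_amplitude_distribution(ser, n_bins = n_bins)
  res <- modulation_index(dist)
  tibble::tibble(subject_id = rec$subject_id, group = rec$group,
                 phase_lo = phase_band$low_hz, phase_hi = phase_band$high_hz,
                 amp_lo = amp_band$low_hz, amp_hi = amp_band$high_hz,
                 mi = res$mi, flagged = res$flagged, n_samples = res$n_samples)
}

#' Phase-amplitude comodulogram
#'
#' MI evaluated over a grid of (phase frequency, amplitude frequency) pairs:
#' 1 Hz phase steps and 2 Hz amplitude steps by default. Each phase
#' frequency `f_p` is analysed in a band of width `phase_bw` centred on it;
#' each amplitude frequency `f_a` in a band of width
#' `max(amp_bw_min, 2 f_p)` centred on it, wide enough to span the
#' modulation sidebands at `f_a +/- f_p`. Cells whose amplitude band reaches
#' down to the phase frequency (`f_a - bw/2 <= f_p`) or up past Nyquist are
#' marked invalid (`NA`), not computed.
#'
#' Instantaneous phase is only physically meaningful where the signal
#' actually oscillates: a band-pass filter applied off any rhythm returns
#' attenuated leakage whose phase is not a rhythm of that frequency, which
#' would smear coupling across the whole phase axis of the comodulogram.
#' Cells whose phase band contains no local maximum of the recording's
#' averaged power spectrum are therefore also marked invalid
#' (`require_phase_peak`, default on).
#'
#' @param rec An [lfp_recording]; detrended internally.
#' @param phase_range,amp_range [band_spec]s giving the grid extents
#'   (defaults 2-15 Hz and 20-100 Hz).
#' @param phase_step,amp_step Grid steps in Hz (defaults 1 and 2).
#' @param phase_bw Phase band width in Hz (default 2).
#' @param amp_bw_min Minimum amplitude band width in Hz (default 4).
#' @param amp_bw_pad Extra half-width in Hz added beyond the sideband offset
#'   `f_p`, so the modulation sidebands at `f_a +/- f_p` sit inside the flat
#'   passband rather than on the filter edges (default 2, about one filter
#'   transition width).
#' @param n_bins,edge_trim_s Passed to the MI path.
#' @param require_phase_peak Gate cells on a spectral peak in the phase band
#'   (default TRUE).
#' @return A `comodulogram` tibble in long form: `phase_freq_hz`,
#'   `amp_freq_hz`, `mi` (NA for invalid cells).
#' @export
comodulogram <- function(rec, phase_range = band_spec(2, 15),
                         amp_range = band_spec(20, 100),
                         phase_step = 1, amp_step = 2, phase_bw = 2,
                         amp_bw_min = 4, amp_bw_pad = 2, n_bins = 24, edge_trim_s = 1,
                         require_phase_peak = TRUE) {
  stopifnot(inherits(rec, "lfp_recording"))
  rec <- detrend_signal(rec)
  nyq <- rec$fs_hz / 2
  fp_grid <- seq(phase_range$low_hz, phase_range$high_hz, by = phase_step)
  fa_grid <- seq(amp_range$low_hz, amp_range$high_hz, by = amp_step)
  n <- length(rec$samples)
  trim <- round(edge_trim_s * rec$fs_hz)
  keep <- (trim + 1L):(n - trim)
  delta <- 2 * pi / n_bins

  peak_freqs <- NULL
  if (require_phase_peak) {
    # 0.5 Hz resolution is enough to localize peaks inside 2 Hz phase bands
    ps <- estimate_power_spectrum(rec, window_s = 2, step_s = 0.5)
    p <- ps$psd_uv2_per_hz
    is_peak <- c(FALSE, p[2:(length(p) - 1)] > p[1:(length(p) - 2)] &
                   p[2:(length(p) - 1)] >= p[3:length(p)], FALSE)
    peak_freqs <- ps$freq_hz[is_peak]
  }

  rows <- vector("list", length(fp_grid))
  for (i in seq_along(fp_grid)) {
    fp <- fp_grid[i]
    lo <- fp - phase_bw / 2
    no_peak <- require_phase_peak &&
      !any(peak_freqs >= lo & peak_freqs <= fp + phase_bw / 2)
    if (lo <= 0 || fp + phase_bw / 2 >= nyq || no_peak) {
      rows[[i]] <- tibble::tibble(phase_freq_hz = fp, amp_freq_hz = fa_grid,
                                  mi = NA_real_)
      next
    }
    ph <- Arg(analytic_signal(
      bandpass(rec, band_spec(lo, fp + phase_bw / 2))$samples))[keep]
    ph[ph >= pi] <- ph[ph >= pi] - 2 * pi
    j <- pmin(floor((ph + pi) / delta), n_bins - 1L) + 1L
    jf <- factor(j, levels = seq_len(n_bins))
    cnt <- tabulate(j, nbins = n_bins)
    mis <- vapply(fa_grid, function(fa) {
      bw <- max(amp_bw_min, 2 * fp + 2 * amp_bw_pad)
      alo <- fa - bw / 2; ahi <- fa + bw / 2
      if (alo <= fp || ahi >= nyq) return(NA_real_)
      am <- Mod(analytic_signal(
        bandpass(rec, band_spec(alo, ahi))$samples))[keep]
      sums <- vapply(split(am, jf), sum, 0)
      mean_amp <- ifelse(cnt > 0, sums / pmax(cnt, 1L), 0)
      p <- mean_amp / sum(mean_amp)
      nzp <- p > 0
      sum(p[nzp] * log(p[nzp] * n_bins)) / log(n_bins)
    }, 0)
    rows[[i]] <- tibble::tibble(phase_freq_hz = fp, amp_freq_hz = fa_grid,
                                mi = mis)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "subject_id") <- rec$subject_id
  attr(out, "group") <- rec$group
  class(out) <- c("comodulogram", class(out))
  out
}

#' Write a comodulogram as a TSV matrix
#'
#' Rows are amplitude frequencies, columns phase frequencies; the first row
#' and column carry the grids.
#'
#' @param com A `comodulogram`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_comodulogram <- function(com, path) {
  stopifnot(inherits(com, "comodulogram"))
  wide <- tidyr::pivot_wider(tibble::as_tibble(com), names_from = "phase_freq_hz",
                             values_from = "mi")
  names(wide)[1] <- "amp_hz\\phase_hz"
  utils::write.table(wide, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
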