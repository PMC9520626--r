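#' Parameters for a phase-amplitude-coupled synthetic LFP
#'
#' The signal model is the standard PAC benchmark construction: a slow
#' carrier plus a fast carrier whose amplitude is sinusoidally modulated by
#' the slow carrier's phase, on top of 1/f^beta background noise:
#'
#' `x(t) = A_s sin(2 pi f_p t) +
#'         A_f [ (1 - chi) + chi (1 + sin(2 pi f_p t)) / 2 ] sin(2 pi f_a t) +
#'         e(t)`
#'
#' `chi = 0` gives a constant fast envelope (no coupling); `chi = 1` gives
#' 100% modulation depth, with the envelope reaching zero where the slow
#' carrier's sine is -1 (slow phase -pi/2).
#'
#' @param phase_freq_hz Slow (theta-like) carrier frequency, Hz (default 10).
#' @param amp_freq_hz Fast (gamma-like) carrier frequency, Hz (default 40).
#' @param coupling Modulation depth chi in `[0, 1]` (default 0.5).
#' @param slow_amp_uv,fast_amp_uv Carrier amplitudes, uV (defaults 50 and 10;
#'   hippocampal theta dominates gamma).
#' @param noise_sd_uv Standard deviation of the additive background, uV
#'   (default 5).
#' @param noise_exponent Spectral slope beta of the 1/f^beta background
#'   (default 1, the approximate slope of LFP backgrounds).
#' @param duration_s Trace length, s (default 60).
#' @param fs_hz Sampling rate, Hz (default 500).
#' @param seed RNG seed (default 1).
#' @return A validated `coupled_lfp_params` list.
#' @export
coupled_lfp_params <- function(phase_freq_hz = 10, amp_freq_hz = 40,
                               coupling = 0.5, slow_amp_uv = 50,
                               fast_amp_uv = 10, noise_sd_uv = 5,
                               noise_exponent = 1, duration_s = 60,
                               fs_hz = 500, seed = 1) {
  p <- list(phase_freq_hz = phase_freq_hz, amp_freq_hz = amp_freq_hz,
            coupling = coupling, slow_amp_uv = slow_amp_uv,
            fast_amp_uv = fast_amp_uv, noise_sd_uv = noise_sd_uv,
            noise_exponent = noise_exponent, duration_s = duration_s,
            fs_hz = fs_hz, seed = seed)
  if (!(coupling >= 0 && coupling <= 1))
    tg_stop("`coupling` must lie in [0, 1]", "tg_parameter_error")
  if (!(phase_freq_hz > 0 && phase_freq_hz < amp_freq_hz &&
        amp_freq_hz < fs_hz / 2))
    tg_stop("need 0 < phase_freq_hz < amp_freq_hz < fs_hz/2",
            "tg_parameter_error")
  if (!(duration_s > 0))
    tg_stop("`duration_s` must be positive", "tg_parameter_error")
  if (noise_sd_uv < 0 || slow_amp_uv < 0 || fast_amp_uv < 0)
    tg_stop("amplitudes and noise SD must be non-negative",
            "tg_parameter_error")
  structure(p, class = "coupled_lfp_params")
}

# 1/f^beta noise by spectral shaping of white Gaussian noise,
# rescaled to unit standard deviation
pink_noise <- function(n, beta) {
  wh <- stats::rnorm(n)
  sp <- stats::fft(wh)
  k <- c(1, pmin(seq_len(n - 1), n - seq_len(n - 1)))  # symmetric freq index
  scale <- c(0, k[-1]^(-beta / 2))                      # kill DC
  x <- Re(stats::fft(sp * scale, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate a theta-gamma coupled synthetic LFP
#'
#' Deterministic given the seed in `params`. The ground truth records the
#' generating coupling depth and carrier frequencies for downstream
#' parameter-recovery checks.
#'
#' @param params A [coupled_lfp_params()].
#' @param subject_id,group Labels for the emitted recording.
#' @return A list with elements `recording` ([lfp_recording]) and
#'   `ground_truth` (list: `coupling`, `phase_freq_hz`, `amp_freq_hz`).
#' @examples
#' sim <- generate_coupled_lfp(coupled_lfp_params(coupling = 1, noise_sd_uv = 0))
#' mi_from_recording(sim$recording)$mi
#' @export
generate_coupled_lfp <- function(params, subject_id = "s1", group = "g1") {
  stopifnot(inherits(params, "coupled_lfp_params"))
  n <- round(params$duration_s * params$fs_hz)
  t <- (seq_len(n) - 1) / params$fs_hz
  slow <- sin(2 * pi * params$phase_freq_hz * t)
  modulator <- (1 - params$coupling) +
    params$coupling * (1 + slow) / 2
  x <- params$slow_amp_uv * slow +
    params$fast_amp_uv * modulator * sin(2 * pi * params$amp_freq_hz * t)
  if (params$noise_sd_uv > 0) {
    x <- x + params$noise_sd_uv *
      withr::with_seed(params$seed, pink_noise(n, params$noise_exponent))
  }
  list(
    recording = lfp_recording(x, fs_hz = params$fs_hz,
                              subject_id = subject_id, group = group),
    ground_truth = list(coupling = params$coupling,
                        phase_freq_hz = params$phase_freq_hz,
                        amp_freq_hz = params$amp_freq_hz)
  )
}
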