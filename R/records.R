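#' Local field potential recording
#'
#' A uniformly sampled single-channel voltage trace with its sampling rate and
#' subject/group labels. Voltages are in microvolts (uV), the unit the
#' downstream spectral and coupling analyses assume.
#'
#' @param samples Numeric vector of voltages (uV); at least 2 finite values.
#' @param fs_hz Sampling rate in Hz (positive scalar; hippocampal recordings
#'   here use 500 Hz).
#' @param subject_id,group,channel Character labels carried through to reports.
#'
#' @return An object of class `lfp_recording`: a list with elements `samples`,
#'   `fs_hz`, `subject_id`, `group`, `channel`.
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)), fs_hz = 500)
#' rec
#' @export
lfp_recording <- function(samples, fs_hz, subject_id = "s1", group = "g1",
                          channel = "ch1") {
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0)
    tg_stop("`fs_hz` must be a positive finite scalar", "tg_parameter_error")
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    tg_stop("an LFP recording needs at least 2 samples", "tg_data_error")
  if (!all(is.finite(samples)))
    tg_stop("LFP samples must all be finite", "tg_data_error")
  structure(
    list(samples = samples, fs_hz = fs_hz,
         subject_id = as.character(subject_id), group = as.character(group),
         channel = as.character(channel)),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %s/%s [%s]: %d samples @ %g Hz (%.1f s)\n",
              x$group, x$subject_id, x$channel, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz))
  invisible(x)
}

#' @export
length.lfp_recording <- function(x) length(x$samples)

#' @importFrom tibble as_tibble
#' @method as_tibble lfp_recording
#' @export
as_tibble.lfp_recording <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$samples) - 1) / x$fs_hz,
    voltage_uv = x$samples,
    subject_id = x$subject_id, group = x$group, channel = x$channel
  )
}

#' Validated Y-maze trial table
#'
#' Checks and normalizes a table of per-trial outcomes: a strictly
#' gapless 1-based `trial` index and a binary `correct` column.
#'
#' @param trials Data frame with columns `trial` and `correct`.
#' @param subject_id,group Labels attached to the table.
#' @return A tibble with columns `trial`, `correct`, `subject_id`, `group`,
#'   additionally classed `trial_table`.
#' @examples
#' trial_table(data.frame(trial = 1:5, correct = c(1, 0, 1, 1, 0)))
#' @export
trial_table <- function(trials, subject_id = "s1", group = "g1") {
  if (!all(c("trial", "correct") %in% names(trials)))
    tg_stop("trial table needs columns `trial` and `correct`", "tg_format_error")
  idx <- trials$trial
  if (length(idx) < 1L || !isTRUE(all(idx == seq_along(idx))))
    tg_stop("`trial` must increase gaplessly from 1", "tg_format_error")
  corr <- trials$correct
  if (!all(corr %in% c(0, 1)))
    tg_stop("`correct` must be 0 or 1", "tg_data_error")
  out <- tibble::tibble(trial = as.integer(idx), correct = as.integer(corr),
                        subject_id = as.character(subject_id),
                        group = as.character(group))
  class(out) <- c("trial_table", class(out))
  out
}

#' 2-D grayscale image with physical pixel size
#'
#' Container for an immunofluorescence-like field: a non-negative intensity
#' matrix plus the pixel size in micrometres, which all morphometry outputs
#' (lengths, diameters, areas) are reported in.
#'
#' @param pixels Numeric matrix of non-negative intensities, row-major with
#'   (1,1) the top-left pixel.
#' @param px_size_um Side length of one pixel in micrometres (positive scalar).
#' @param channel Stain label, e.g. `"iba1"` (microglia) or `"abeta"` (plaques).
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, px_size_um, channel = "iba1") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    tg_stop("`pixels` must be a numeric matrix", "tg_data_error")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    tg_stop("pixel intensities must be finite and non-negative", "tg_data_error")
  if (!is.numeric(px_size_um) || length(px_size_um) != 1L || px_size_um <= 0)
    tg_stop("`px_size_um` must be a positive scalar", "tg_metadata_error")
  structure(list(pixels = pixels, px_size_um = px_size_um,
                 channel = as.character(channel)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image> %s: %d x %d px @ %g um/px (%.0f x %.0f um)\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$px_size_um,
              ncol(x$pixels) * x$px_size_um, nrow(x$pixels) * x$px_size_um))
  invisible(x)
}

#' @method as_tibble labeled_image
#' @export
as_tibble.labeled_image <- function(x, ...) {
  px <- x$pixels
  tibble::tibble(
    x_um = rep((seq_len(ncol(px)) - 1) * x$px_size_um, each = nrow(px)),
    y_um = rep((seq_len(nrow(px)) - 1) * x$px_size_um, times = ncol(px)),
    intensity = as.vector(px),
    channel = x$channel
  )
}

#' Frequency band specification
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`. Validity
#'   against the Nyquist frequency is checked where a band meets a recording.
#' @return A `band_spec` object.
#' @examples
#' theta_band <- band_spec(8, 13)   # the slow (phase) band
#' gamma_band <- band_spec(30, 42)  # the fast (amplitude) band
#' @export
band_spec <- function(low_hz, high_hz) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      length(low_hz) != 1L || length(high_hz) != 1L ||
      !is.finite(low_hz) || !is.finite(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz)
    tg_stop("need 0 < low_hz < high_hz", "tg_parameter_error")
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %g-%g Hz\n", x$low_hz, x$high_hz)); invisible(x)
}
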