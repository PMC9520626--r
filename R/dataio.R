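#' Read an LFP recording from CSV + JSON sidecar
#'
#' The on-disk dialect is a UTF-8 CSV with header `voltage_uv` or
#' `time_s,voltage_uv`, next to a JSON sidecar `<path>.json` holding
#' `fs_hz`, `units`, `subject_id`, `group`, `channel`. A time column, when
#' present, must step by `1/fs_hz` within 1e-6 s.
#'
#' @param path Path to the CSV file.
#' @return An [lfp_recording].
#' @seealso [write_lfp()]
#' @export
read_lfp <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path))
    tg_stop(sprintf("LFP file not found: %s", path), "tg_io_error")
  if (!file.exists(sidecar))
    tg_stop(sprintf("missing JSON sidecar: %s", sidecar), "tg_format_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs_hz))
    tg_stop("sidecar lacks `fs_hz`", "tg_format_error")
  dat <- utils::read.csv(path, check.names = FALSE)
  if (!"voltage_uv" %in% names(dat))
    tg_stop("LFP CSV needs a `voltage_uv` column", "tg_format_error")
  v <- dat$voltage_uv
  if (!all(is.finite(v)))
    tg_stop("non-finite sample in LFP file", "tg_data_error")
  if ("time_s" %in% names(dat) && nrow(dat) >= 2) {
    steps <- diff(dat$time_s)
    if (any(abs(steps - 1 / meta$fs_hz) > 1e-6))
      tg_stop(sprintf(
        "time column inconsistent with fs_hz = %g (max step deviation %.3g s)",
        meta$fs_hz, max(abs(steps - 1 / meta$fs_hz))), "tg_consistency_error")
  }
  lfp_recording(v, fs_hz = meta$fs_hz,
                subject_id = meta$subject_id %||% "s1",
                group = meta$group %||% "g1",
                channel = meta$channel %||% "ch1")
}

#' Write an LFP recording to CSV + JSON sidecar
#'
#' @param rec An [lfp_recording].
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @param time_column Include an explicit `time_s` column (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_lfp <- function(rec, path, time_column = FALSE) {
  stopifnot(inherits(rec, "lfp_recording"))
  dat <- if (time_column) {
    data.frame(time_s = sprintf("%.9f", (seq_along(rec$samples) - 1) / rec$fs_hz),
               voltage_uv = sprintf("%.9g", rec$samples))
  } else {
    data.frame(voltage_uv = sprintf("%.9g", rec$samples))
  }
  ok <- tryCatch({
    utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) tg_stop(sprintf("cannot write LFP file: %s", path), "tg_io_error")
  jsonlite::write_json(
    list(fs_hz = rec$fs_hz, units = "uV", subject_id = rec$subject_id,
         group = rec$group, channel = rec$channel),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Y-maze trial table from CSV
#'
#' Expects a header `trial,correct`; the index must run gaplessly from 1 and
#' outcomes must be 0/1 — anything else is rejected, never coerced.
#'
#' @param path CSV path.
#' @param subject_id,group Labels (defaults taken from an optional
#'   `<path>.json` sidecar when present).
#' @return A [trial_table] tibble.
#' @export
read_trials <- function(path, subject_id = NULL, group = NULL) {
  if (!file.exists(path))
    tg_stop(sprintf("trial file not found: %s", path), "tg_io_error")
  dat <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  trial_table(dat,
              subject_id = subject_id %||% meta$subject_id %||% "s1",
              group = group %||% meta$group %||% "g1")
}

#' Write a trial table to CSV (+ label sidecar)
#'
#' @param trials A [trial_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "trial_table"))
  utils::write.csv(trials[, c("trial", "correct")], path,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(subject_id = trials$subject_id[1],
                            group = trials$group[1]),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a grayscale image with pixel-size metadata
#'
#' Reads TIFF (via the `tiff` package) or PNG; pixel size and channel label
#' come from a `<path>.json` sidecar or from the arguments. Multi-channel
#' images are averaged to one grayscale plane.
#'
#' @param path Image file (.tif/.tiff/.png).
#' @param px_size_um Pixel size override (um/px); required when no sidecar
#'   provides one.
#' @param channel Channel label override.
#' @return A [labeled_image].
#' @export
read_labeled_image <- function(path, px_size_um = NULL, channel = NULL) {
  if (!file.exists(path))
    tg_stop(sprintf("image not found: %s", path), "tg_io_error")
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    tg_stop(sprintf("unsupported image format: .%s", ext), "tg_format_error"))
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  psz <- px_size_um %||% meta$px_size_um
  if (is.null(psz))
    tg_stop("pixel size missing: supply `px_size_um` or a sidecar",
            "tg_metadata_error")
  if (!is.null(meta$max_intensity)) px <- px * meta$max_intensity
  labeled_image(px, px_size_um = psz,
                channel = channel %||% meta$channel %||% "iba1")
}

#' Write a labeled image to TIFF (+ metadata sidecar)
#'
#' Intensities are rescaled to `[0, 1]` by the stated `max_intensity` before
#' writing (TIFF float convention of the `tiff` package).
#'
#' @param img A [labeled_image].
#' @param path Output `.tif` path.
#' @param max_intensity Intensity mapped to white (default: image maximum, or
#'   1 for a blank image).
#' @return `path`, invisibly.
#' @export
write_labeled_image <- function(img, path, max_intensity = NULL) {
  stopifnot(inherits(img, "labeled_image"))
  top <- max_intensity %||% max(img$pixels, 1e-12)
  tiff::writeTIFF(pmin(img$pixels / top, 1), path, bits.per.sample = 16L)
  jsonlite::write_json(list(px_size_um = img$px_size_um, channel = img$channel,
                            max_intensity = top),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
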