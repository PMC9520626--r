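#' Sliding-window learning curve
#'
#' Windowed accuracy over a trial sequence: windows of `window_len` trials
#' starting every `step` trials (defaults 10 and 5, the standard Y-maze
#' summary), trailing partial windows discarded. `step = window_len` gives
#' the non-overlapping variant.
#'
#' @param trials A [trial_table] (or data frame with `trial` and `correct`).
#' @param window_len Trials per window (default 10).
#' @param step Trials between window starts (default 5).
#' @return A `learning_curve` tibble: `window`, `window_start`,
#'   `window_end`, `accuracy`, plus the subject/group labels when present.
#' @examples
#' tt <- trial_table(data.frame(trial = 1:90, correct = rep(c(1, 0), 45)))
#' learning_curve(tt)   # 17 windows, all 0.5
#' @export
learning_curve <- function(trials, window_len = 10, step = 5) {
  if (!(window_len >= 1 && step >= 1))
    tg_stop("`window_len` and `step` must be positive", "tg_parameter_error")
  n <- nrow(trials)
  if (n < window_len)
    tg_stop(sprintf("need at least %d trials, got %d", window_len, n),
            "tg_parameter_error")
  # a curve over concatenated subjects is not the mixture of their curves
  if ("subject_id" %in% names(trials) &&
      length(unique(trials$subject_id)) > 1)
    tg_stop("trials from more than one subject; compute curves per subject",
            "tg_consistency_error")
  starts <- seq(1L, n - window_len + 1L, by = step)
  acc <- vapply(starts, function(s)
    mean(trials$correct[s:(s + window_len - 1L)]), 0)
  out <- tibble::tibble(
    window = seq_along(starts),
    window_start = as.integer(starts),
    window_end = as.integer(starts + window_len - 1L),
    accuracy = acc)
  if ("subject_id" %in% names(trials)) out$subject_id <- trials$subject_id[1]
  if ("group" %in% names(trials)) out$group <- trials$group[1]
  attr(out, "window_len") <- window_len
  attr(out, "step") <- step
  class(out) <- c("learning_curve", class(out))
  out
}

#' Trials to an accuracy criterion
#'
#' First window of the learning curve whose accuracy reaches the threshold
#' (default 80%, the short-term-memory criterion); reported as that
#' window's last trial index. No persistence beyond the first crossing is
#' required.
#'
#' @param curve A `learning_curve` from [learning_curve()].
#' @param threshold Accuracy criterion in `(0, 1]` (default 0.8).
#' @return One-row tibble: `threshold`, `reached` (logical),
#'   `first_trial_reached` (NA when never reached), plus labels when present.
#' @export
trials_to_criterion <- function(curve, threshold = 0.8) {
  if (!(threshold > 0 && threshold <= 1))
    tg_stop("`threshold` must lie in (0, 1]", "tg_parameter_error")
  hit <- which(curve$accuracy >= threshold)
  out <- tibble::tibble(
    threshold = threshold,
    reached = length(hit) > 0,
    first_trial_reached = if (length(hit) > 0)
      as.integer(curve$window_end[hit[1]]) else NA_integer_)
  if ("subject_id" %in% names(curve)) out$subject_id <- curve$subject_id[1]
  if ("group" %in% names(curve)) out$group <- curve$group[1]
  out
}

#' Trial raster across subjects
#'
#' Stacks per-subject binary outcome sequences into one row per subject
#' (the tabular equivalent of a correct/incorrect raster plot). Subjects
#' with fewer trials than the longest sequence are padded with `NA` and
#' flagged.
#'
#' @param trials_list List of [trial_table]s.
#' @return Tibble with columns `subject_id`, `group`, `flagged`
#'   (TRUE for padded rows) and `t1 ... tN` outcome columns.
#' @export
trial_raster <- function(trials_list) {
  stopifnot(length(trials_list) >= 1)
  nmax <- max(vapply(trials_list, nrow, 0L))
  purrr::map_dfr(trials_list, function(tt) {
    v <- c(tt$correct, rep(NA_integer_, nmax - nrow(tt)))
    row <- tibble::as_tibble(setNames(as.list(v), paste0("t", seq_len(nmax))))
    dplyr::bind_cols(
      tibble::tibble(subject_id = tt$subject_id[1], group = tt$group[1],
                     flagged = nrow(tt) < nmax),
      row)
  })
}

#' Write a learning curve as TSV
#'
#' @param curve A `learning_curve`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_learning_curve <- function(curve, path) {
  utils::write.table(
    data.frame(window_start = curve$window_start,
               window_end = curve$window_end,
               accuracy = sprintf("%.10g", curve$accuracy)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
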