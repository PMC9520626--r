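#' Default seven-group study design
#'
#' The standard design of a stimulation-duration study: an untreated
#' disease-model group, a sham group, four treatment-duration groups and a
#' wild-type group, five subjects each. Longer treatment maps to higher
#' theta-gamma coupling and asymptotic accuracy, fewer and less activated
#' (smaller-soma, longer-process) microglia - so every downstream readout
#' has a known monotone ordering.
#'
#' @param n_subjects Subjects per group (default 5).
#' @return A `study_design` tibble, one row per group: `group`, `coupling`,
#'   `gamma_amp_uv` (gamma carrier amplitude; treated and wild-type animals
#'   have stronger spontaneous gamma), `p_start`, `p_final`, `tau_trials`,
#'   `n_cells`, `soma_diameter_um`, `process_length_um`, `n_subjects`.
#' @export
default_study_design <- function(n_subjects = 5) {
  design <- tibble::tibble(
    group = c("APP_PS1", "sham", "tACS_7d", "tACS_14d", "tACS_21d",
              "tACS_28d", "WT"),
    coupling = c(0.05, 0.07, 0.18, 0.30, 0.42, 0.52, 0.65),
    gamma_amp_uv = c(6, 6.2, 8, 10, 13, 15, 18),
    p_start = 0.5,
    p_final = c(0.60, 0.60, 0.70, 0.78, 0.86, 0.90, 0.92),
    tau_trials = 20,
    n_cells = c(26L, 25L, 21L, 17L, 13L, 11L, 9L),
    soma_diameter_um = c(8.5, 8.4, 7.8, 7.2, 6.6, 6.3, 6.0),
    process_length_um = c(18, 18, 22, 26, 30, 33, 35),
    n_subjects = as.integer(n_subjects))
  validate_study_design(design)
}

#' Validate a study design table
#'
#' @param design A data frame with the columns of [default_study_design()].
#' @return The design as a validated `study_design` tibble.
#' @export
validate_study_design <- function(design) {
  need <- c("group", "coupling", "p_final", "n_subjects")
  miss <- setdiff(need, names(design))
  if (length(miss))
    tg_stop(paste("design lacks columns:", paste(miss, collapse = ", ")),
            "tg_design_error")
  if (nrow(design) < 2)
    tg_stop("a study needs at least 2 groups", "tg_design_error")
  if (anyDuplicated(design$group))
    tg_stop("duplicate group labels in design", "tg_design_error")
  if (any(design$n_subjects < 2))
    tg_stop("every group needs n_subjects >= 2", "tg_design_error")
  design <- tibble::as_tibble(design)
  fill <- list(gamma_amp_uv = 10, p_start = 0.5, tau_trials = 20,
               n_cells = 15L, soma_diameter_um = 7, process_length_um = 25)
  for (nm in names(fill))
    if (!nm %in% names(design)) design[[nm]] <- fill[[nm]]
  class(design) <- unique(c("study_design", class(design)))
  design
}

# stable per-subject seed below 2^31, derived from the master seed
subject_seed <- function(seed, group_index, subject_index, stream = 0L) {
  (abs(seed) %% 1000003L) * 2000L + group_index * 200L +
    subject_index * 8L + stream
}

#' Generate a full synthetic study on disk
#'
#' One directory per group, one per subject, holding the subject's LFP
#' (CSV + JSON sidecar), trial table (CSV), microglia image (TIFF + sidecar)
#' and a ground-truth JSON. Deterministic: the master seed spawns one stream
#' per subject and data type, so any subject can be regenerated in
#' isolation.
#'
#' @param design A `study_design` (see [default_study_design()]).
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param lfp_duration_s,fs_hz,noise_sd_uv LFP generation settings
#'   (defaults 60 s, 500 Hz, 5 uV).
#' @param n_trials Y-maze trials per subject (default 90).
#' @param write_images Render and write the microglia TIFFs (default TRUE;
#'   turning it off speeds up purely electrophysiological simulations).
#' @return The study directory, invisibly; a `study.json` manifest of the
#'   design is written at its root.
#' @export
generate_group_study <- function(design, dir, seed = 1, lfp_duration_s = 60,
                                 fs_hz = 500, noise_sd_uv = 5,
                                 n_trials = 90, write_images = TRUE) {
  design <- validate_study_design(design)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gi in seq_len(nrow(design))) {
    g <- design[gi, ]
    for (si in seq_len(g$n_subjects)) {
      sid <- sprintf("s%02d", si)
      sdir <- file.path(dir, g$group, sid)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      lfp <- generate_coupled_lfp(
        coupled_lfp_params(coupling = g$coupling,
                           fast_amp_uv = g$gamma_amp_uv,
                           duration_s = lfp_duration_s,
                           fs_hz = fs_hz, noise_sd_uv = noise_sd_uv,
                           seed = subject_seed(seed, gi, si, 0L)),
        subject_id = sid, group = g$group)
      write_lfp(lfp$recording, file.path(sdir, "lfp.csv"))
      beh <- generate_learning_trials(
        learner_profile(p_start = g$p_start, p_final = g$p_final,
                        tau_trials = g$tau_trials, n_trials = n_trials,
                        seed = subject_seed(seed, gi, si, 1L)),
        subject_id = sid, group = g$group)
      write_trials(beh$trials, file.path(sdir, "trials.csv"))
      gt <- list(coupling = lfp$ground_truth$coupling,
                 p_final = g$p_final)
      if (write_images) {
        # per-subject biological variability in cell density
        n_cells_s <- max(2L, withr::with_seed(
          subject_seed(seed, gi, si, 3L), stats::rpois(1, g$n_cells)))
        img <- generate_microglia_image(microglia_scene_params(
          n_cells = n_cells_s,
          soma_diameter_um = c(g$soma_diameter_um, 0.4),
          process_length_um = c(g$process_length_um, 3),
          seed = subject_seed(seed, gi, si, 2L)))
        write_labeled_image(img$image, file.path(sdir, "iba1.tif"))
        gt$morphometry <- img$ground_truth$totals
      }
      jsonlite::write_json(gt, file.path(sdir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  jsonlite::write_json(
    list(design = design, seed = seed, lfp_duration_s = lfp_duration_s,
         fs_hz = fs_hz, noise_sd_uv = noise_sd_uv, n_trials = n_trials),
    file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
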