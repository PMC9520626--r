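#' Study configuration
#'
#' Builds the resolved configuration driving [run_pipeline()]: frequency
#' bands (the coupling analysis uses theta 8-13 / gamma 30-42 Hz, the
#' spectral summaries theta 8-12 / gamma 30-45 Hz - both conventions are
#' config), spectral estimation settings, coupling, behavior, morphometry
#' and statistics blocks. Unknown fields are rejected with their path, so a
#' typo in a config file fails loudly before any computation.
#'
#' @param config A named list of overrides, or a path to a YAML file of
#'   them; `NULL` keeps all defaults.
#' @return The validated, fully resolved `study_config` list.
#' @export
study_config <- function(config = NULL) {
  defaults <- list(
    bands = list(theta_phase = c(8, 13), gamma_amp = c(30, 42),
                 theta_spec = c(8, 12), gamma_spec = c(30, 45)),
    spectral = list(window_s = 1, step_s = 0.1, filter_order = 4),
    cfc = list(n_bins = 24, edge_trim_s = 1),
    behavior = list(window_len = 10, step = 5, threshold = 0.8),
    morphometry = list(min_soma_area_um2 = 12),
    stats = list(alpha = 0.05),
    correlation = list(metric = "n_cells", groups = NULL),
    synth = list(seed = 1, lfp_duration_s = 60, fs_hz = 500,
                 noise_sd_uv = 5, n_trials = 90, n_subjects = 5)
  )
  if (is.character(config)) {
    if (!file.exists(config))
      tg_stop(sprintf("config file not found: %s", config), "tg_config_error")
    config <- yaml::read_yaml(config)
  }
  merged <- merge_config(defaults, config %||% list(), path = "")
  for (b in c("theta_phase", "gamma_amp", "theta_spec", "gamma_spec")) {
    v <- merged$bands[[b]]
    if (!(is.numeric(v) && length(v) == 2 && v[1] > 0 && v[1] < v[2]))
      tg_stop(sprintf("config field bands.%s must be c(low, high), 0 < low < high", b),
              "tg_config_error")
  }
  if (!(merged$stats$alpha > 0 && merged$stats$alpha < 1))
    tg_stop("config field stats.alpha must lie in (0, 1)", "tg_config_error")
  structure(merged, class = "study_config")
}

# recursive default merge; unknown keys are an error carrying their path
merge_config <- function(defaults, override, path) {
  extra <- setdiff(names(override), names(defaults))
  if (length(extra))
    tg_stop(sprintf("unknown config field(s): %s",
                    paste0(sub("^\\.", "", paste0(path, ".", extra)),
                           collapse = ", ")),
            "tg_config_error")
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]],
                                     paste0(path, ".", nm))
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

tg_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Analyze every subject of a study directory
#'
#' Walks the on-disk study layout written by [generate_group_study()] and
#' computes, per subject: the theta-gamma modulation index, gamma band power
#' from the averaged power spectrum, the learning curve and
#' trials-to-criterion, and (when an image is present) the microglial field
#' metrics. Missing subject files are collected and reported in one error
#' rather than failing one at a time.
#'
#' @param study_dir Study root directory.
#' @param config A [study_config()] (or overrides passed to it).
#' @param verbose Log one line per subject (default FALSE).
#' @return List of tibbles: `lfp_features` (one row per subject: `mi`,
#'   `gamma_power_uv2`, `gamma_density_uv2_per_hz`, flags), `criteria`,
#'   `curves`, `morphometry`.
#' @export
analyze_study <- function(study_dir, config = study_config(),
                          verbose = FALSE) {
  if (!inherits(config, "study_config")) config <- study_config(config)
  if (!dir.exists(study_dir))
    tg_stop(sprintf("study directory not found: %s", study_dir),
            "tg_io_error")
  groups <- sort(setdiff(list.dirs(study_dir, recursive = FALSE,
                                   full.names = FALSE), "reports"))
  subjects <- purrr::map_dfr(groups, function(g) {
    tibble::tibble(group = g,
                   subject_id = sort(list.dirs(file.path(study_dir, g),
                                               recursive = FALSE,
                                               full.names = FALSE)))
  })
  missing <- character(0)
  for (i in seq_len(nrow(subjects))) {
    sdir <- file.path(study_dir, subjects$group[i], subjects$subject_id[i])
    for (f in c("lfp.csv", "trials.csv"))
      if (!file.exists(file.path(sdir, f)))
        missing <- c(missing, file.path(sdir, f))
  }
  if (length(missing))
    tg_stop(paste0("missing subject file(s):\n  ",
                   paste(missing, collapse = "\n  ")), "tg_io_error")

  theta <- band_spec(config$bands$theta_phase[1], config$bands$theta_phase[2])
  gamma <- band_spec(config$bands$gamma_amp[1], config$bands$gamma_amp[2])
  gamma_spec <- band_spec(config$bands$gamma_spec[1],
                          config$bands$gamma_spec[2])

  lfp_rows <- list(); crit_rows <- list(); curve_rows <- list()
  morpho_rows <- list()
  for (i in seq_len(nrow(subjects))) {
    g <- subjects$group[i]; sid <- subjects$subject_id[i]
    sdir <- file.path(study_dir, g, sid)
    tg_log(verbose, "analyze %s/%s: lfp", g, sid)
    rec <- read_lfp(file.path(sdir, "lfp.csv"))
    mires <- mi_from_recording(rec, phase_band = theta, amp_band = gamma,
                               n_bins = config$cfc$n_bins,
                               edge_trim_s = config$cfc$edge_trim_s)
    ps <- estimate_power_spectrum(detrend_signal(rec),
                                  window_s = config$spectral$window_s,
                                  step_s = config$spectral$step_s)
    bp <- band_power(ps, gamma_spec)
    lfp_rows[[i]] <- tibble::tibble(
      group = g, subject_id = sid, mi = mires$mi, flagged = mires$flagged,
      gamma_power_uv2 = bp$power_uv2,
      gamma_density_uv2_per_hz = bp$mean_density_uv2_per_hz)
    tg_log(verbose, "analyze %s/%s: behavior", g, sid)
    tt <- read_trials(file.path(sdir, "trials.csv"),
                      subject_id = sid, group = g)
    curve <- learning_curve(tt, window_len = config$behavior$window_len,
                            step = config$behavior$step)
    curve_rows[[i]] <- curve
    crit_rows[[i]] <- trials_to_criterion(curve,
                                          threshold = config$behavior$threshold)
    img_path <- file.path(sdir, "iba1.tif")
    if (file.exists(img_path)) {
      tg_log(verbose, "analyze %s/%s: morphometry", g, sid)
      img <- read_labeled_image(img_path)
      fm <- field_metrics(img,
                          min_soma_area_um2 = config$morphometry$min_soma_area_um2)
      morpho_rows[[i]] <- dplyr::bind_cols(
        tibble::tibble(group = g, subject_id = sid), fm)
    }
  }
  list(lfp_features = dplyr::bind_rows(lfp_rows),
       criteria = dplyr::bind_rows(crit_rows),
       curves = dplyr::bind_rows(curve_rows),
       morphometry = dplyr::bind_rows(morpho_rows))
}

#' Correlate a morphometry metric with the modulation index
#'
#' Pearson correlation (with best-fit line) between one per-subject
#' morphometry metric - microglia count, mean soma diameter, or total
#' process length - and the subject's theta-gamma modulation index,
#' optionally restricted to a subset of groups (e.g. the treatment groups).
#'
#' @param analysis Result of [analyze_study()], or a list with
#'   `lfp_features` and `morphometry` tibbles.
#' @param metric Morphometry column to use (default `"n_cells"`).
#' @param groups Optional character vector of groups to include.
#' @return A `correlation_fit` (see [pearson_correlation()]).
#' @export
correlate_morphometry_cfc <- function(analysis, metric = "n_cells",
                                      groups = NULL) {
  mo <- analysis$morphometry
  if (is.null(mo) || nrow(mo) == 0 || !metric %in% names(mo))
    tg_stop(sprintf("morphometry metric `%s` not available", metric),
            "tg_parameter_error")
  d <- dplyr::inner_join(
    dplyr::select(analysis$lfp_features, "group", "subject_id", "mi"),
    dplyr::select(mo, "group", "subject_id", metric_value = dplyr::all_of(metric)),
    by = c("group", "subject_id"))
  if (!is.null(groups)) d <- dplyr::filter(d, .data$group %in% groups)
  pearson_correlation(d, x = "metric_value", y = "mi")
}

#' Group-statistics report for a study analysis
#'
#' Runs the comparison chain ([compare_groups()]: ANOVA, homogeneity gate,
#' LSD or Tamhane T2) on the modulation index, the gamma band power, and
#' each morphometry readout, plus the morphometry-vs-MI correlation.
#' Subjects with flagged (empty-phase-bin) MI estimates are excluded from
#' the MI comparison.
#'
#' @param analysis Result of [analyze_study()].
#' @param config A [study_config()].
#' @return List: `comparisons` (named list of [compare_groups()] results),
#'   `correlation` (a `correlation_fit`, or NULL without morphometry),
#'   `summary` (tibble of group means per measure).
#' @export
report_study <- function(analysis, config = study_config()) {
  if (!inherits(config, "study_config")) config <- study_config(config)
  alpha <- config$stats$alpha
  lf <- dplyr::filter(analysis$lfp_features, !.data$flagged)
  comparisons <- list(
    mi = compare_groups(dplyr::rename(lf, value = "mi"), alpha = alpha),
    gamma_power = compare_groups(dplyr::rename(lf, value = "gamma_power_uv2"),
                                 alpha = alpha))
  if (!is.null(analysis$morphometry) && nrow(analysis$morphometry) > 0) {
    for (mvar in c("n_cells", "mean_soma_diameter_um", "total_length_um")) {
      comparisons[[mvar]] <- compare_groups(
        dplyr::rename(analysis$morphometry, value = dplyr::all_of(mvar)),
        alpha = alpha)
    }
  }
  correlation <- NULL
  if (!is.null(analysis$morphometry) && nrow(analysis$morphometry) >= 3) {
    correlation <- correlate_morphometry_cfc(
      analysis, metric = config$correlation$metric,
      groups = config$correlation$groups)
  }
  summary <- purrr::imap_dfr(comparisons, function(cg, nm)
    dplyr::mutate(cg$measure_summary, measure = nm, .before = 1))
  list(comparisons = comparisons, correlation = correlation,
       summary = summary)
}

# deterministic TSV writer used for all report files
tg_write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full study pipeline
#'
#' `synthesize` writes a seeded synthetic study to disk; `analyze` runs the
#' per-subject analyses and writes per-subject TSVs; `full` does both plus
#' the group-statistics report, correlation report and a run manifest.
#' Re-running with the same config and seed reproduces every output file
#' byte for byte.
#'
#' @param config A [study_config()], a named list of overrides, or a YAML
#'   path.
#' @param mode `"synthesize"`, `"analyze"`, or `"full"`.
#' @param study_dir Study data directory (created in synthesize/full mode).
#' @param design Study design for synthesis (default
#'   [default_study_design()]).
#' @param seed Master seed (default: the config's `synth.seed`).
#' @param verbose Per-stage logging (default FALSE).
#' @return List with `analysis` and `report` (NULL in synthesize mode) and
#'   the paths written.
#' @export
run_pipeline <- function(config = NULL, mode = c("full", "synthesize",
                                                 "analyze"),
                         study_dir, design = NULL, seed = NULL,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  config <- study_config(config)
  seed <- seed %||% config$synth$seed
  if (mode %in% c("synthesize", "full")) {
    design <- design %||% default_study_design(config$synth$n_subjects)
    tg_log(verbose, "synthesize: %d groups -> %s", nrow(design), study_dir)
    generate_group_study(design, study_dir, seed = seed,
                         lfp_duration_s = config$synth$lfp_duration_s,
                         fs_hz = config$synth$fs_hz,
                         noise_sd_uv = config$synth$noise_sd_uv,
                         n_trials = config$synth$n_trials)
  }
  if (mode == "synthesize")
    return(invisible(list(analysis = NULL, report = NULL,
                          study_dir = study_dir)))

  analysis <- analyze_study(study_dir, config, verbose = verbose)
  report <- report_study(analysis, config)
  rdir <- file.path(study_dir, "reports")
  dir.create(rdir, showWarnings = FALSE)
  tg_write_tsv(analysis$lfp_features, file.path(rdir, "lfp_features.tsv"))
  tg_write_tsv(analysis$criteria, file.path(rdir, "criteria.tsv"))
  tg_write_tsv(analysis$curves, file.path(rdir, "learning_curves.tsv"))
  if (nrow(analysis$morphometry) > 0)
    tg_write_tsv(analysis$morphometry, file.path(rdir, "morphometry.tsv"))
  tg_write_tsv(report$summary, file.path(rdir, "group_summary.tsv"))
  omnibus <- purrr::imap_dfr(report$comparisons, function(cg, nm)
    dplyr::mutate(glance(cg$anova), measure = nm, .before = 1))
  tg_write_tsv(omnibus, file.path(rdir, "anova.tsv"))
  ph <- purrr::imap_dfr(report$comparisons, function(cg, nm)
    dplyr::mutate(cg$posthoc, measure = nm, .before = 1))
  tg_write_tsv(ph, file.path(rdir, "posthoc.tsv"))
  if (!is.null(report$correlation))
    tg_write_tsv(glance(report$correlation),
                 file.path(rdir, "correlation.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("thetagamma")),
    seed = seed, mode = mode,
    config = unclass(config),
    flagged_mi = sum(analysis$lfp_features$flagged),
    files = sort(basename(list.files(rdir))))
  jsonlite::write_json(manifest, file.path(rdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(analysis = analysis, report = report,
                 study_dir = study_dir, reports_dir = rdir))
}
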