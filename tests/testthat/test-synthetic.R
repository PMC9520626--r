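test_that("coupled-LFP generator honours its invariants", {
  expect_error(coupled_lfp_params(coupling = 1.2),
               class = "tg_parameter_error")
  expect_error(coupled_lfp_params(phase_freq_hz = 50, amp_freq_hz = 40),
               class = "tg_parameter_error")
  expect_error(coupled_lfp_params(amp_freq_hz = 300, fs_hz = 500),
               class = "tg_parameter_error")
  expect_error(coupled_lfp_params(duration_s = 0),
               class = "tg_parameter_error")

  p <- coupled_lfp_params(duration_s = 12.3, fs_hz = 500)
  sim <- generate_coupled_lfp(p)
  expect_equal(length(sim$recording$samples), round(12.3 * 500))
  expect_equal(sim$ground_truth$coupling, 0.5)

  # bit-identical under the same seed
  sim2 <- generate_coupled_lfp(p)
  expect_identical(sim$recording$samples, sim2$recording$samples)
})

test_that("zero coupling gives a flat fast envelope", {
  # slow carrier off so the trace IS the fast band; Butterworth passband
  # micro-ripple alone would exceed this flatness bound, so the envelope is
  # taken on the bare carrier
  sim <- generate_coupled_lfp(coupled_lfp_params(
    coupling = 0, slow_amp_uv = 0, noise_sd_uv = 0, duration_s = 20,
    seed = 1))
  env <- Mod(analytic_signal(sim$recording$samples))
  core <- env[2001:8000]
  expect_lt(sd(core) / mean(core), 1e-6)
})

test_that("full coupling zeroes the envelope at the slow carrier's minimum", {
  # Hilbert phase of sin(wt) is wt - pi/2, so the modulator zero
  # (sin = -1, i.e. wt = -pi/2) sits at extracted phase +/- pi
  sim <- generate_coupled_lfp(coupled_lfp_params(
    coupling = 1, noise_sd_uv = 0, duration_s = 20, seed = 1))
  slow <- bandpass(sim$recording, band_spec(8, 12))
  # the amplitude band must span both modulation sidebands (40 +/- 10 Hz);
  # a 30-45 Hz band truncates one and the envelope can no longer reach zero
  fast <- bandpass(sim$recording, band_spec(25, 55))
  ser <- analytic_phase_amplitude(slow, fast, edge_trim_s = 1)
  trough <- abs(abs(ser$phase) - pi) < 0.1
  peak <- abs(ser$phase) < 0.1
  expect_lt(mean(ser$amplitude[trough]), 0.05 * mean(ser$amplitude[peak]))
})

test_that("downstream MI separates strong from weak coupling", {
  mi <- vapply(c(0.2, 0.8), function(chi) {
    sim <- generate_coupled_lfp(coupled_lfp_params(
      coupling = chi, duration_s = 30, seed = 9))
    mi_from_recording(sim$recording)$mi
  }, 0)
  expect_gt(mi[2], mi[1])
})

test_that("1/f noise has the requested spectral slope", {
  sim <- generate_coupled_lfp(coupled_lfp_params(
    coupling = 0, slow_amp_uv = 0, fast_amp_uv = 0, noise_sd_uv = 1,
    noise_exponent = 1, duration_s = 120, seed = 4))
  ps <- estimate_power_spectrum(sim$recording, window_s = 2)
  sel <- ps$freq_hz >= 2 & ps$freq_hz <= 100
  fit <- lm(log(ps$psd_uv2_per_hz[sel]) ~ log(ps$freq_hz[sel]))
  expect_lt(abs(unname(coef(fit)[2]) + 1), 0.2)
})

test_that("learning-trial generator follows its profile", {
  expect_error(learner_profile(p_start = 0.9, p_final = 0.5),
               class = "tg_parameter_error")
  expect_error(learner_profile(tau_trials = 0), class = "tg_parameter_error")

  # degenerate Bernoulli: always correct
  sim <- generate_learning_trials(learner_profile(p_start = 1, p_final = 1))
  expect_equal(sum(sim$trials$correct), 90)

  # stationary p = 0.5: overall accuracy within 3 binomial SE
  sim2 <- generate_learning_trials(learner_profile(
    p_start = 0.5, p_final = 0.5, n_trials = 10000, seed = 8))
  acc <- mean(sim2$trials$correct)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 10000))

  # learning effect: late accuracy beats early accuracy across seeds
  gains <- vapply(1:100, function(s) {
    tr <- generate_learning_trials(learner_profile(
      p_start = 0.5, p_final = 0.95, tau_trials = 20, seed = s))$trials
    mean(tr$correct[81:90]) - mean(tr$correct[1:10])
  }, 0)
  expect_gt(mean(gains), 0)
  expect_gt(mean(gains > 0), 0.9)
})

test_that("microglia scenes are blank at zero cells and error on overflow", {
  sim <- generate_microglia_image(microglia_scene_params(n_cells = 0))
  expect_equal(sum(sim$image$pixels), 0)
  expect_equal(sim$ground_truth$totals$endpoints, 0)
  expect_equal(sim$ground_truth$totals$n_cells, 0)

  expect_error(
    generate_microglia_image(microglia_scene_params(
      field_um = c(100, 60), n_cells = 40, seed = 1)),
    class = "tg_generation_error")
})

test_that("a single unbranched cell yields two skeleton endpoints", {
  sim <- generate_microglia_image(microglia_scene_params(
    n_cells = 1, processes_per_cell = 1, branching_prob = 0, seed = 3))
  expect_equal(sim$ground_truth$cells$gt_endpoints, 2L)
  expect_equal(sim$ground_truth$cells$gt_junctions, 0L)
  sk <- skeletonize(binarize(sim$image), sim$image$px_size_um)
  expect_equal(sk$n_endpoints, 2L)
  expect_equal(sk$n_junctions, 0L)
})

test_that("skeletal renders reproduce their topology ground truth exactly", {
  for (seed in c(11, 29, 57)) {
    sim <- generate_microglia_image(microglia_scene_params(
      n_cells = 5, render_soma = FALSE, branching_prob = 0.5, seed = seed))
    sk <- skeletonize(sim$mask, 1)
    expect_identical(sk$n_endpoints, sim$ground_truth$totals$endpoints)
    expect_identical(sk$n_junctions, sim$ground_truth$totals$junctions)
  }
})

test_that("full renders recover endpoints within 10% and cell count exactly", {
  sim <- generate_microglia_image(microglia_scene_params(
    n_cells = 5, branching_prob = 0.5, seed = 7))
  fm <- field_metrics(sim$image)
  gt <- sim$ground_truth$totals
  expect_equal(fm$n_cells, 5L)
  expect_lt(abs(fm$n_endpoints - gt$endpoints) / gt$endpoints, 0.1)
  expect_lt(abs(fm$total_length_um - gt$process_length_um) /
              gt$process_length_um, 0.15)
})

test_that("plaque images report their exact drawn area fraction", {
  sim <- generate_plaque_image(n_plaques = 10, seed = 6)
  fm <- field_metrics(sim$image)
  expect_equal(fm$area_fraction, sim$ground_truth$area_fraction,
               tolerance = 1e-12)
})

test_that("study generation writes a complete deterministic layout", {
  design <- validate_study_design(tibble::tibble(
    group = c("A", "B"), coupling = c(0.1, 0.6), p_final = c(0.6, 0.9),
    n_subjects = 2L, n_cells = 4L))
  expect_error(validate_study_design(design[1, ]), class = "tg_design_error")
  expect_error(
    validate_study_design(tibble::tibble(
      group = c("A", "A"), coupling = 0.2, p_final = 0.8, n_subjects = 2L)),
    class = "tg_design_error")

  dir <- withr::local_tempdir()
  generate_group_study(design, dir, seed = 3, lfp_duration_s = 5,
                       n_trials = 30)
  for (g in c("A", "B")) for (s in c("s01", "s02"))
    for (f in c("lfp.csv", "lfp.csv.json", "trials.csv", "iba1.tif",
                "ground_truth.json"))
      expect_true(file.exists(file.path(dir, g, s, f)))

  dir2 <- withr::local_tempdir()
  generate_group_study(design, dir2, seed = 3, lfp_duration_s = 5,
                       n_trials = 30)
  f1 <- file.path(dir, "A", "s01", "lfp.csv")
  f2 <- file.path(dir2, "A", "s01", "lfp.csv")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
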