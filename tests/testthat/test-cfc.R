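test_that("analytic phase advances at the carrier frequency", {
  fs <- 500
  slow <- sine_rec(10, fs = fs, dur = 20)
  ser <- analytic_phase_amplitude(slow, slow, edge_trim_s = 1)
  dphi <- diff(ser$phase)
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  rate <- mean(dphi) * fs   # rad/s
  expect_lt(abs(rate / (2 * pi * 10) - 1), 0.001)
})

test_that("analytic amplitude recovers the envelope", {
  fast <- sine_rec(40, dur = 20, amp = 3)
  ser <- analytic_phase_amplitude(fast, fast, edge_trim_s = 1)
  expect_lt(max(abs(ser$amplitude - 3)) / 3, 0.01)

  # envelope modulated at 10 Hz demodulates to a 10 Hz peak
  t <- seq(0, 30, by = 1 / 500)
  x <- lfp_recording((1 + 0.5 * sin(2 * pi * 10 * t)) * sin(2 * pi * 40 * t),
                     500)
  fx <- bandpass(x, band_spec(25, 55))
  ser <- analytic_phase_amplitude(fx, fx, edge_trim_s = 1)
  env <- lfp_recording(ser$amplitude, 500)
  ps <- estimate_power_spectrum(env)
  nz <- ps$freq_hz > 2
  expect_equal(ps$freq_hz[nz][which.max(ps$psd_uv2_per_hz[nz])], 10)
})

test_that("phase/amplitude pairing enforces consistency", {
  a <- sine_rec(10, dur = 10); b <- sine_rec(40, dur = 12)
  expect_error(analytic_phase_amplitude(a, b), class = "tg_consistency_error")
  expect_error(analytic_phase_amplitude(a, a, edge_trim_s = 6),
               class = "tg_parameter_error")
})

test_that("phase binning matches analytic profiles", {
  # uniform phases, constant amplitude -> flat distribution
  ser <- tibble::tibble(phase = seq(-pi, pi - 1e-9, length.out = 24000),
                        amplitude = 1)
  d <- phase_amplitude_distribution(ser)
  expect_lt(max(abs(d$p - 1 / 24)), 1e-12)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)

  # amplitude concentrated in bin 1
  ser2 <- tibble::tibble(phase = ser$phase,
                         amplitude = as.numeric(ser$phase < -pi + 2 * pi / 24))
  d2 <- phase_amplitude_distribution(ser2)
  expect_equal(d2$p[1], 1)
  expect_equal(sum(d2$p[-1]), 0)

  # amplitude = 1 + cos(phase): p proportional to 1 + cos(bin centre)
  ser3 <- tibble::tibble(phase = ser$phase, amplitude = 1 + cos(ser$phase))
  d3 <- phase_amplitude_distribution(ser3)
  expected <- (1 + cos(d3$phase_center)) / sum(1 + cos(d3$phase_center))
  expect_lt(max(abs(d3$p - expected) / pmax(expected, 0.01)), 0.02)
})

test_that("bin-edge phases go to the upper bin and pi wraps to -pi", {
  delta <- 2 * pi / 24
  ser <- tibble::tibble(phase = c(-pi, -pi + delta, pi), amplitude = 1)
  suppressWarnings(d <- phase_amplitude_distribution(ser))
  expect_equal(d$mean_amp[1], 1)  # -pi and the wrapped pi land in bin 1
  expect_equal(d$mean_amp[2], 1)  # exact edge belongs to bin 2
})

test_that("empty phase bins are flagged, not fatal", {
  ser <- tibble::tibble(phase = runif(500, 0, 1), amplitude = 1)
  expect_warning(d <- phase_amplitude_distribution(ser),
                 class = "tg_empty_bins")
  expect_gt(length(attr(d, "empty_bins")), 0)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)
  expect_true(modulation_index(d)$flagged)
})

test_that("modulation index analytic values are exact", {
  expect_identical(modulation_index(rep(1 / 24, 24))$mi, 0)
  expect_identical(modulation_index(c(1, rep(0, 23)))$mi, 1)
  expect_equal(modulation_index(c(0.5, 0.5, rep(0, 22)))$mi,
               1 - log(2) / log(24), tolerance = 1e-12)
})

test_that("vectorized MI equals the brute-force loop on random toy series", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    phase <- runif(n, -pi, pi)
    amp <- rexp(n)
    suppressWarnings({
      d <- phase_amplitude_distribution(
        tibble::tibble(phase = phase, amplitude = amp))
      mi <- modulation_index(d)$mi
    })
    expect_equal(mi, brute_mi(phase, amp), tolerance = 1e-12)
  }
})

test_that("MI is invariant to amplitude scaling", {
  set.seed(303)
  phase <- runif(5000, -pi, pi)
  amp <- rexp(5000)
  base <- modulation_index(phase_amplitude_distribution(
    tibble::tibble(phase = phase, amplitude = amp)))$mi
  for (c_ in c(1e-6, 0.3, 1e6)) {
    scaled <- modulation_index(phase_amplitude_distribution(
      tibble::tibble(phase = phase, amplitude = c_ * amp)))$mi
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("MI increases strictly with generated coupling depth", {
  mis <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(chi) {
    sim <- generate_coupled_lfp(coupled_lfp_params(
      coupling = chi, noise_sd_uv = 0, duration_s = 30, seed = 5))
    mi_from_recording(sim$recording)$mi
  }, 0)
  expect_true(all(diff(mis) > 0))
  expect_lt(mis[1], 0.01)
})

test_that("comodulogram marks invalid and gated cells NA and stays in [0,1]", {
  sim <- generate_coupled_lfp(coupled_lfp_params(
    coupling = 1, noise_sd_uv = 0, duration_s = 20, seed = 2))
  cm <- comodulogram(sim$recording, phase_range = band_spec(8, 12),
                     amp_range = band_spec(10, 40))
  # amplitude cells at/below the phase band are never computed
  expect_true(all(is.na(cm$mi[cm$amp_freq_hz <= cm$phase_freq_hz])))
  ok <- !is.na(cm$mi)
  expect_true(any(ok))
  expect_true(all(cm$mi[ok] >= 0 & cm$mi[ok] <= 1))
})

test_that("white noise yields a near-zero comodulogram", {
  set.seed(42)
  mx <- vapply(1:3, function(i) {
    rec <- lfp_recording(rnorm(30000), 500)
    max(comodulogram(rec, phase_range = band_spec(5, 15),
                     amp_range = band_spec(20, 60))$mi, na.rm = TRUE)
  }, 0)
  expect_lt(max(mx), 0.01)
})
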