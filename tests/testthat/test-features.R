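test_that("peak detection: counting, degenerate input, noisy localization", {
  cfg <- small_config(n_frames = 20000)
  tr <- generate_displacement(
    pulse_waveform_model(heart_rate_hz = 1, pulse_width_s = 0.3), cfg)
  pk <- detect_pulse_peaks(tr)
  expect_equal(pk$n_candidates, 10)
  expect_length(pk$peak_indices, 3)
  expect_true(all(diff(pk$peak_indices) > 0))   # time order

  ramp <- displacement_trace(seq(0, 1, length.out = 5000), 5e-4)
  expect_warning(rpk <- detect_pulse_peaks(ramp), "peaks|maxima")
  expect_length(rpk$peak_indices, 0)
  expect_true(rpk$short)

  expect_error(detect_pulse_peaks(displacement_trace(rnorm(100), 5e-4)),
               "2 s")

  # noisy train: detected peaks within +-1 frame of the exhaustive
  # local-max oracle applied to the clean trace
  set.seed(21)
  noisy <- add_noise_snr(tr, 20)
  sm <- stats::filter(noisy$values, rep(1 / 81, 81), sides = 2)
  sm[is.na(sm)] <- 0
  noisy_s <- displacement_trace(as.numeric(sm), 5e-4)
  npk <- detect_pulse_peaks(noisy_s)
  truth <- which(diff(sign(diff(tr$values))) < 0) + 1L
  for (p in npk$peak_indices) {
    expect_lte(min(abs(truth - p)), 40)   # within 20 ms of a true beat
  }
})

test_that("PTT estimation: exact on shifts, boundary semantics, window", {
  cfg <- small_config(n_frames = 20000)
  chest <- generate_displacement(pulse_waveform_model(), cfg)
  # circular-shift construction: exact lag recovery
  shift <- 420                       # 0.210 s at 0.5 ms frames
  wrist_vals <- c(chest$values[(20000 - shift + 1):20000],
                  chest$values[1:(20000 - shift)])
  wrist <- displacement_trace(wrist_vals, chest$sample_period_s)
  ptt <- estimate_ptt(chest, wrist)
  expect_equal(as.numeric(ptt), 0.210)
  expect_gt(attr(ptt, "correlation"), 0.99)
  expect_false(attr(ptt, "at_boundary"))

  # zero delay: best lag pinned to the window's lower edge -> flagged
  expect_warning(p0 <- estimate_ptt(chest, chest), "edge")
  expect_true(attr(p0, "at_boundary"))
  expect_equal(as.numeric(p0), 0.05)

  # uncorrelated traces -> unreliable-estimate error
  set.seed(5)
  junk <- displacement_trace(rnorm(20000), chest$sample_period_s)
  expect_error(estimate_ptt(chest, junk), "unreliable")
})

test_that("PTT under noise matches the exhaustive-lag oracle within 2 ms", {
  cfg <- small_config(n_frames = 20000)
  chest0 <- generate_displacement(pulse_waveform_model(), cfg)
  wrist0 <- generate_displacement(
    pulse_waveform_model(pulse_amplitude_mm = 0.08, ptt_delay_s = 0.180), cfg)
  set.seed(31)
  for (i in 1:3) {
    ptt <- estimate_ptt(add_noise_snr(chest0, 20), add_noise_snr(wrist0, 20))
    expect_lt(abs(as.numeric(ptt) - 0.180), 2e-3)
  }
})

test_that("PWV = arm length / PTT", {
  expect_equal(compute_pwv(0.21, 0.725), 0.725 / 0.21)
  expect_equal(compute_pwv(0.21, 0.725), 3.452, tolerance = 1e-3)
  expect_equal(compute_pwv(1, 1), 1)
  expect_equal(compute_pwv(0.4, 0.7), compute_pwv(0.2, 0.7) / 2)
  expect_error(compute_pwv(0, 0.7), "positive")
  expect_error(compute_pwv(0.2, -1), "positive")
})

test_that("AUC matches analytic shapes at 0.5 ms sampling", {
  dt <- 5e-4
  t <- seq(0, 3, by = dt)

  # symmetric triangle, base B, height 1: area above half height = B/8
  B <- 0.2
  tri <- pmax(0, 1 - abs(t - 1.5) * 2 / B)
  tr_tri <- displacement_trace(tri, dt)
  auc_tri <- compute_auc(tr_tri, detect_pulse_peaks(tr_tri, k_peaks = 1))
  expect_equal(as.numeric(auc_tri), B / 8, tolerance = 0.01)

  # rectangle width W: area = W/2
  W <- 0.1
  rect <- as.numeric(abs(t - 1.5) <= W / 2)
  tr_rect <- displacement_trace(rect, dt)
  auc_rect <- compute_auc(tr_rect, detect_pulse_peaks(tr_rect, k_peaks = 1))
  expect_equal(as.numeric(auc_rect), W / 2, tolerance = 0.01)

  # raised cosine width B: area = B/(2*pi)
  tr_rc <- one_peak_trace(B = 0.2, dt = dt)
  auc_rc <- compute_auc(tr_rc, detect_pulse_peaks(tr_rc, k_peaks = 1))
  expect_equal(as.numeric(auc_rc), 0.2 / (2 * pi), tolerance = 0.01)
})

test_that("AUC is invariant to amplitude gain and offset", {
  tr <- one_peak_trace(B = 0.25)
  base <- as.numeric(compute_auc(tr, detect_pulse_peaks(tr, k_peaks = 1)))
  tr2 <- displacement_trace(tr$values * 10 + 5, tr$sample_period_s)
  scaled <- as.numeric(compute_auc(tr2, detect_pulse_peaks(tr2, k_peaks = 1)))
  expect_lt(abs(scaled - base) / base, 1e-9)
})

test_that("AUC increases with pulse width over the raised-cosine family", {
  widths <- seq(0.1, 0.4, by = 0.05)
  aucs <- vapply(widths, function(B) {
    tr <- one_peak_trace(B = B)
    as.numeric(compute_auc(tr, detect_pulse_peaks(tr, k_peaks = 1)))
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("AUC warns when a segment never crosses the half line", {
  dt <- 5e-4
  t <- seq(0, 3, by = dt)
  # rises 0 -> 1, then decays only to 0.6 before the record ends, so the
  # right side never re-crosses the half-amplitude line
  x <- ifelse(t <= 1.5, t / 1.5, 1 - 0.4 * (t - 1.5) / 1.5)
  tr <- displacement_trace(x, dt)
  pk <- suppressWarnings(detect_pulse_peaks(tr, k_peaks = 1))
  expect_warning(compute_auc(tr, pk), "segment edge")
})

test_that("extract_features bundles PTT, PWV and AUC for a trace pair", {
  cfg <- small_config(n_frames = 20000)
  chest <- generate_displacement(pulse_waveform_model(), cfg)
  wrist <- generate_displacement(
    pulse_waveform_model(pulse_amplitude_mm = 0.08, pulse_width_s = 0.25,
                         ptt_delay_s = 0.21), cfg)
  rec <- extract_features(chest, wrist, arm_length = 0.725, subject_id = 1)
  expect_equal(rec$ptt_s, 0.21, tolerance = 1e-6)
  expect_equal(rec$pwv_mps, 0.725 / 0.21, tolerance = 1e-6)
  expect_equal(rec$auc_s, 0.25 / (2 * pi), tolerance = 0.01)
})

test_that("zero-noise cohort: rank correlations of features with pressure", {
  z <- generate_cohort(noise = zero_noise_spec(), seed = 17)
  f <- cohort_features(z)
  for (sid in 1:5) {
    s <- f[f$subject_id == sid, ]
    expect_equal(stats::cor(1 / s$ptt_s, s$dbp_mmhg, method = "spearman"), 1)
    expect_equal(stats::cor(s$auc_s, s$sbp_mmhg, method = "spearman"), -1)
  }
})
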