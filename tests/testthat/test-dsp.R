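test_that("range FFT localizes tones and matches a direct DFT-sum oracle", {
  cfg <- small_config(n_frames = 16)
  n_fast <- cfg$adc_samples_per_chirp

  # pure tone at integer bin k: argmax = k+1 every frame
  k <- 9
  tone <- exp(2i * pi * k * (seq_len(n_fast) - 1) / n_fast)
  cube <- structure(list(samples = matrix(tone, 16, n_fast, byrow = TRUE),
                         config = cfg, dc_offset = 0 + 0i,
                         noise_snr_db = Inf),
                    class = "if_frame_cube")
  map <- range_fft(cube, window = "rect")
  expect_true(all(apply(Mod(map$values), 1, which.max) == k + 1))

  # all-zero cube -> all-zero map
  zcube <- cube; zcube$samples[] <- 0 + 0i
  expect_true(all(Mod(range_fft(zcube)$values) == 0))

  # two-tone frame vs explicit DFT sum
  tone2 <- tone + 0.5 * exp(2i * pi * 30 * (seq_len(n_fast) - 1) / n_fast)
  cube$samples <- matrix(tone2, 16, n_fast, byrow = TRUE)
  map2 <- range_fft(cube, window = "rect")
  dft <- vapply(seq_len(n_fast), function(b) {
    sum(tone2 * exp(-2i * pi * (b - 1) * (seq_len(n_fast) - 1) / n_fast))
  }, complex(1))
  expect_equal(map2$values[1, ], dft, tolerance = 1e-10)
  mags <- Mod(map2$values[1, ])
  expect_setequal(order(mags, decreasing = TRUE)[1:2], c(k + 1, 31))

  expect_error(range_fft(zcube[c("config")]), class = "error")
})

test_that("range-bin selection: target bin, tie rule, dominance", {
  cfg <- small_config(n_frames = 256)
  tr <- generate_displacement(pulse_waveform_model(), cfg)
  cube <- synthesize_if_cube(tr, cfg, target_range_m = 0.5)
  map <- range_fft(cube)
  sel <- select_range_bin(map)
  expect_equal(sel$bin, round(0.5 / map$bin_spacing_m) + 1)

  # uniform magnitude: tie resolved to the nearest bin, with a warning
  umap <- map
  umap$values <- matrix(1 + 0i, 4, 8)
  expect_warning(usel <- select_range_bin(umap), "tie")
  expect_equal(usel$bin, 1L)

  # stronger of two targets wins (magnitude-sum oracle)
  t2 <- synthesize_if_cube(tr, cfg, target_range_m = 1.1)
  mix <- cube
  mix$samples <- cube$samples + 0.3 * t2$samples
  msel <- select_range_bin(range_fft(mix))
  expect_equal(msel$bin, sel$bin)

  # pure noise has no dominant bin
  ncube <- cube
  ncube$samples <- matrix(complex(real = rnorm(256 * 128),
                                  imaginary = rnorm(256 * 128)), 256, 128)
  expect_error(select_range_bin(range_fft(ncube), min_dominance = 3),
               "no dominant")
})

test_that("Kasa DC compensation recovers circle centres", {
  th <- seq(0, 2 * pi, length.out = 100)[-100]
  z <- exp(1i * th) + (1 + 0.5i)
  out <- dc_compensate(z)
  expect_equal(attr(out, "dc_offset"), 1 + 0.5i, tolerance = 1e-9)
  expect_lt(stats::var(Mod(out)), 1e-10)

  # idempotent on centred data
  out2 <- dc_compensate(out)
  expect_equal(as.complex(out2), as.complex(out), tolerance = 1e-9)

  # collinear IQ points: flagged, input returned unchanged
  lin <- complex(real = seq(0, 1, length.out = 20), imaginary = 0.3)
  expect_warning(flat <- dc_compensate(lin), "collinear")
  expect_true(attr(flat, "dc_failed"))
  expect_equal(as.complex(flat), lin)
})

test_that("noisy quarter-arc offset recovery matches a grid-search oracle", {
  set.seed(11)
  n <- 1000    # a quarter arc of a few-second slow-time record
  th <- seq(0, pi / 2, length.out = n)
  true_c <- 0.3 - 0.2i
  z0 <- exp(1i * th) + true_c
  # 30 dB complex noise relative to unit radius
  sigma <- sqrt(10^(-30 / 10) / 2)
  z <- z0 + complex(real = rnorm(n, sd = sigma),
                    imaginary = rnorm(n, sd = sigma))
  est <- attr(dc_compensate(z), "dc_offset")
  expect_lt(Mod(est - true_c), 0.05)   # within 5% of radius

  # independent oracle: coarse grid search minimizing radius variance
  grid <- expand.grid(re = seq(0.1, 0.5, by = 0.02),
                      im = seq(-0.4, 0, by = 0.02))
  spread <- mapply(function(re, im) {
    stats::var(Mod(z - complex(real = re, imaginary = im)))
  }, grid$re, grid$im)
  oracle <- complex(real = grid$re[which.min(spread)],
                    imaginary = grid$im[which.min(spread)])
  expect_lt(Mod(est - oracle), 0.05)
})

test_that("quarter-arc offset error stays below 5% of radius across seeds", {
  set.seed(12)
  th <- seq(0, pi / 2, length.out = 1000)
  sigma <- sqrt(10^(-30 / 10) / 2)
  errs <- replicate(10, {
    true_c <- complex(real = runif(1, -0.5, 0.5),
                      imaginary = runif(1, -0.5, 0.5))
    z <- exp(1i * th) + true_c +
      complex(real = rnorm(1000, sd = sigma),
              imaginary = rnorm(1000, sd = sigma))
    Mod(attr(dc_compensate(z), "dc_offset") - true_c)
  })
  expect_lt(median(errs), 0.05)
})

test_that("arctangent demodulation and unwrapping", {
  expect_equal(arctan_demodulate(rep(exp(1i * pi / 2), 5)), rep(pi / 2, 5))

  # synthesis/analysis identity on random phases in (-pi, pi]
  set.seed(4)
  ph <- runif(200, -pi + 1e-9, pi)
  expect_equal(arctan_demodulate(exp(1i * ph)), ph, tolerance = 1e-12)

  expect_warning(out <- arctan_demodulate(c(1 + 0i, 0 + 0i, 1i)),
                 "zero-magnitude")
  expect_equal(out[2], out[1])

  # single wrap
  expect_equal(unwrap_phase(c(0, pi - 0.1, -pi + 0.1)),
               c(0, pi - 0.1, pi + 0.1))
  # smooth sequence unchanged
  sm <- seq(0, 2, by = 0.1)
  expect_identical(unwrap_phase(sm), sm)
  # analytic ramp oracle: wrapped linear ramp is restored to a line
  ramp <- seq(0, 40, by = 0.3)
  wrapped <- Arg(exp(1i * ramp))
  expect_lt(max(abs(unwrap_phase(wrapped) - ramp)), 1e-9)
})

test_that("unwrap output differs from input by integer multiples of 2*pi", {
  set.seed(9)
  for (i in 1:20) {
    ph <- Arg(exp(1i * cumsum(rnorm(300, sd = 1.2))))
    k <- (unwrap_phase(ph) - ph) / (2 * pi)
    expect_equal(k, round(k), tolerance = 1e-9)
    expect_true(all(abs(diff(unwrap_phase(ph))) <= pi + 1e-12))
  }
})

test_that("phase-to-displacement conversion and its sign/demean options", {
  lam <- 3.9e-3
  tr <- phase_to_displacement(c(0, pi / 2), lam, 5e-4, demean = FALSE)
  expect_equal(tr$values[2], lam / 8 * 1e3)   # ~0.4875 mm
  expect_equal(tr$values[1], 0)
  z <- phase_to_displacement(rep(0, 10), lam, 5e-4, demean = FALSE)
  expect_true(all(z$values == 0))
  flipped <- phase_to_displacement(c(0, pi / 2), lam, 5e-4, sign = -1,
                                   demean = FALSE)
  expect_equal(flipped$values[2], -lam / 8 * 1e3)
})

test_that("full chain recovers the simulated displacement", {
  cfg <- small_config(n_frames = 4000)
  tr <- generate_displacement(pulse_waveform_model(), cfg)
  cube <- synthesize_if_cube(tr, cfg, dc_offset = 0.3 - 0.2i)
  rec <- process_cube(cube)
  truth <- tr$values - mean(tr$values)
  expect_lt(max(abs(rec$values - truth)), 1e-3)   # < 1 um

  # linearity: doubling the displacement doubles the recovery
  tr2 <- displacement_trace(2 * tr$values, tr$sample_period_s)
  rec2 <- process_cube(synthesize_if_cube(tr2, cfg))
  expect_equal(rec2$values, 2 * rec$values, tolerance = 0.01)

  # invariance to a global complex gain
  gcube <- cube
  gcube$samples <- cube$samples * (1.7 * exp(0.6i))
  grec <- process_cube(gcube)
  expect_lt(max(abs(grec$values - rec$values)), 1e-9)
})

test_that("band-pass removes respiration but keeps the pulse band", {
  cfg <- small_config(n_frames = 20000)
  model <- pulse_waveform_model(respiration_amplitude_mm = 1.0)
  tr <- generate_displacement(model, cfg)
  filt <- bandpass_trace(tr, c(0.7, 10))
  # respiration energy (the bulk of the raw variance) is removed
  expect_lt(mean((filt$values - mean(filt$values))^2),
            mean((tr$values - mean(tr$values))^2) / 2)
  # what remains is the band-limited pulse train (residual respiration
  # sits ~36 dB down, bounding the achievable correlation)
  pure <- bandpass_trace(generate_displacement(pulse_waveform_model(), cfg),
                         c(0.7, 10))
  expect_gt(stats::cor(filt$values, pure$values), 0.98)
})
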