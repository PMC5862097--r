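test_that("the source waveform is a windowed sinusoid with the right cycle count", {
  spec <- simulation_spec(1, "pial", n_trials = 2)
  w <- simulate_source_timecourse(spec)
  t_ms <- laminarmeg:::spec_time_axis(spec)
  act <- t_ms >= 100 & t_ms <= 500
  expect_equal(w[!act], rep(0, sum(!act)))
  expect_equal(w[act], 10 * sin(2 * pi * 20 * (t_ms[act] - 100) / 1000),
               tolerance = 1e-12)
  # 0.4 s at 20 Hz: eight full cycles; count sign changes independently
  wa <- w[act]
  crossings <- sum(diff(sign(wa[wa != 0])) != 0)
  ref <- sin(2 * pi * 20 * seq(0, 0.4, by = 1 / 250))
  ref_cross <- sum(diff(sign(ref[ref != 0])) != 0)
  expect_equal(crossings, ref_cross)
  expect_equal(crossings, 15)   # 16 half-periods -> 15 interior sign flips
  expect_error(
    simulation_spec(1, "pial", active_window = c(100, 700)),
    "inside the epoch"
  )
  expect_error(simulation_spec(1, "pial", frequency = 200), "Nyquist")
})

test_that("noiseless patch projection is trial-identical and respects the point limit", {
  ds <- tiny_dataset(n_trials = 5, snr_db = Inf)
  x <- ds$clean$data
  expect_equal(x[1, , ], x[5, , ], tolerance = 0)
  # point-source limit: a basis with near-zero FWHM gives L column x waveform
  ctx <- ds$ctx
  spec <- ds$spec
  spec$patch_fwhm <- 0.2
  b <- suppressWarnings(compute_patch_basis(ctx$pair$pial, 0.2))
  clean <- project_patch(spec, ctx$pair, context_leadfield_test(ctx, "pial"), b)
  L <- context_leadfield_test(ctx, "pial")$matrix
  w <- simulate_source_timecourse(spec)
  expect_equal(clean$data[1, , ], tcrossprod(L[, spec$vertex_index], w),
               tolerance = 1e-9)
  expect_error(
    project_patch(ds$spec, ctx$pair, context_leadfield_test(ctx, "pial"),
                  laminarmeg:::context_basis(ctx, "white", 5)),
    "different mesh"
  )
})

test_that("SNR-targeted noise hits the requested level across the grid", {
  ds <- tiny_dataset(n_trials = 12, snr_db = Inf)
  for (target in c(-100, -50, -20, -5, 0, 5)) {
    noisy <- add_noise_snr(ds$clean, target, seed = 3)
    expect_equal(realized_snr_db(ds$clean, noisy), target, tolerance = 0.1)
  }
  # 0 dB means noise RMS equal to signal RMS on average (ratio one)
  n0 <- add_noise_snr(ds$clean, 0, seed = 4)
  expect_equal(realized_snr_db(ds$clean, n0), 0, tolerance = 0.1)
  # noise-only control: signal replaced by zeros, noise kept
  ninf <- add_noise_snr(ds$clean, -Inf, seed = 5)
  act <- ninf$time_ms < 100   # any window; data are pure noise everywhere
  expect_gt(sd(ninf$data), 0)
  expect_equal(mean(ninf$data), 0, tolerance = 0.05 * sd(ninf$data))
  expect_equal(cor(as.vector(ninf$data[1, , ]), as.vector(ds$clean$data[1, , ])),
               0, tolerance = 0.05)
  zero <- ds$clean
  zero$data[] <- 0
  expect_error(add_noise_snr(zero, -20), "all zero")
})

test_that("fixed-RMS noise has the stated scale and zero level is a no-op", {
  ds <- tiny_dataset(n_trials = 12, snr_db = Inf)
  expect_identical(add_noise_fixed(ds$clean, 0)$data, ds$clean$data)
  nf <- add_noise_fixed(ds$clean, 120, seed = 9)
  expect_equal(sd(nf$data - ds$clean$data), 120, tolerance = 0.02 * 120)
  # sweep endpoints accepted
  expect_silent(add_noise_fixed(ds$clean, 10, seed = 1))
  expect_silent(add_noise_fixed(ds$clean, 2e6, seed = 1))
})

test_that("datasets are bit-identical under the same seed and round-trip to disk", {
  a <- tiny_dataset(n_trials = 6, snr_db = -20, seed = 33)
  b <- tiny_dataset(n_trials = 6, snr_db = -20, seed = 33)
  expect_identical(a$noisy$data, b$noisy$data)
  c2 <- tiny_dataset(n_trials = 6, snr_db = -20, seed = 34)
  expect_false(identical(a$noisy$data, c2$noisy$data))

  f <- tempfile(fileext = ".rds")
  write_trial_data(a$noisy, f)
  back <- read_trial_data(f)
  expect_identical(back$data, a$noisy$data)
  expect_true(file.exists(paste0(f, ".json")))
})
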