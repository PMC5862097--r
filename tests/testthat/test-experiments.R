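small_config <- function(...) {
  laminar_config(
    anatomy = list(n_vertices = 642, fold_amplitude = 8, fold_wavelength = 30,
                   base_radius = 70),
    n_sources_per_surface = 3, n_trials = 24,
    snr_grid_db = -10, include_noise_only = FALSE,
    n_msp_random = 5,
    patch_grid = list(simulate = c(5, 10), reconstruct = c(5, 10),
                      snr_db = 5, schemes = "EBB", n_sources_per_surface = 2),
    ...
  )
}

test_that("config round-trips through YAML and rejects unknown fields", {
  cfg <- small_config()
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$n_trials, 24)
  expect_equal(back$snr_grid_db, -10)
  expect_equal(back$anatomy$n_vertices, 642)
  expect_error(laminar_config(bogus_field = 1), "unknown config fields")
})

test_that("the SNR sweep is reproducible bit-for-bit and well-formed", {
  cfg <- small_config()
  s1 <- run_snr_sweep(cfg, seed = 5)
  s2 <- run_snr_sweep(cfg, seed = 5)
  expect_identical(s1$decisions, s2$decisions)
  # one row per simulation x scheme x analysis
  expect_equal(nrow(s1$decisions),
               6 * length(cfg$schemes) * length(cfg$analyses))
  expect_true(all(c("snr_db", "sim_id", "truth", "label", "significant")
                  %in% names(s1$decisions)))
  expect_equal(nrow(s1$aggregates),
               length(cfg$schemes) * length(cfg$analyses))
  s3 <- run_snr_sweep(cfg, seed = 6)
  expect_false(identical(s1$decisions$delta_F, s3$decisions$delta_F))
  # tidy methods expose the tables
  expect_identical(tidy(s1), s1$decisions)
  expect_identical(glance(s1), s1$aggregates)
  f <- tempfile(fileext = ".csv")
  write_decisions_csv(s1, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(s1$decisions))
  p <- autoplot(s1)
  expect_s3_class(p, "ggplot")
})

test_that("the patch-size grid reports per-cell decisions and a McNemar contrast", {
  cfg <- small_config()
  pg <- run_patch_size_grid(cfg, seed = 3)
  expect_equal(nrow(pg$decisions), 4 * 2 * 2)  # sims x sim_fwhm x rec_fwhm
  expect_true(all(c("sim_fwhm", "rec_fwhm") %in% names(pg$decisions)))
  expect_s3_class(pg$mcnemar, "tbl_df")
  expect_true(all(c("accuracy_matched", "accuracy_mismatched")
                  %in% names(pg$mcnemar)))
})

test_that("anatomy correlations produce four predictors and a df-3 Meng test", {
  cfg <- small_config(n_sources_per_surface = 5, schemes = "EBB")
  setup <- setup_experiment(cfg, 5)
  sw <- run_snr_sweep(cfg, seed = 5, setup = setup)
  an <- run_anatomy_correlation(sw, setup$context, scheme = "EBB",
                                snr_db = -10)
  expect_equal(nrow(an$correlations), 4)
  expect_setequal(an$correlations$predictor,
                  c("thickness", "curvature", "sulcal_depth", "leadfield_rms"))
  expect_equal(an$meng$heterogeneity$df, 3)
  expect_equal(nrow(an$meng$pairwise), 6)
})

test_that("the lead-field neighbour analysis has the right fixed points", {
  pair <- tiny_pair()
  n <- nrow(pair$pial$vertices)
  L <- matrix(rnorm(8 * n), 8, n)
  # identical lead fields: cross-surface difference is zero everywhere
  same <- leadfield_neighbour_analysis(pair, L, L)
  expect_equal(same$fraction_cross_smaller, c(100, 100))
  # constant within each surface but different between them
  Lc1 <- matrix(1, 8, n)
  Lc2 <- matrix(2, 8, n)
  diffc <- leadfield_neighbour_analysis(pair, Lc1, Lc2)
  expect_equal(diffc$fraction_cross_smaller, c(0, 0))
  ctx <- tiny_context()
  real <- leadfield_neighbour_analysis(
    pair, context_leadfield_test(ctx, "pial"), context_leadfield_test(ctx, "white")
  )
  expect_true(all(real$fraction_cross_smaller > 0 &
                    real$fraction_cross_smaller < 100))
})

test_that("inversion summaries expose tidy and glance views", {
  ds <- tiny_dataset(n_trials = 12, snr_db = -10)
  red <- reduce_modes(preprocess(ds$noisy, use_hann = TRUE),
                      context_leadfield_test(ds$ctx, "pial"))
  priors <- build_priors("EBB", ds$ctx$pair$pial,
                         laminarmeg:::context_basis(ds$ctx, "pial", 5),
                         context_leadfield_test(ds$ctx, "pial"), red)
  inv <- reml_optimize(priors, red)
  td <- tidy(inv)
  expect_equal(nrow(td), 2)
  gl <- glance(inv)
  expect_true(gl$converged)
  expect_gte(gl$variance_explained, 0)
  expect_lte(gl$variance_explained, 100)
})

test_that("the command-line interface prints usage without arguments", {
  expect_output(laminarmeg_cli(character(0)), "usage")
})
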