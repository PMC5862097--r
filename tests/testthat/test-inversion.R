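# helper: hand-built priors in the reduced space (identity source model)
identity_priors <- function(m, n_extra = 0, extra_A = NULL) {
  comps <- list(list(G = Matrix::Diagonal(m), A = diag(m), scale = 1,
                     label = "iid"))
  if (n_extra > 0) {
    comps <- c(comps, list(list(
      G = Matrix::Diagonal(m), A = extra_A,
      scale = sum(extra_A^2) / m, label = "extra"
    )))
  }
  structure(list(scheme = "IID", comps = comps, Lt = diag(m), n_vertices = m),
            class = "lam_priors")
}

reduced_from_samples <- function(X) {
  m <- nrow(X)
  structure(
    list(X = array(X, c(m, 1, ncol(X))), U = diag(m), V = matrix(1),
         RV = matrix(1), C = tcrossprod(X) / ncol(X),
         n_spatial_modes = m, n_temporal_modes = 1, n_eff = ncol(X),
         n_samples = 1, n_trials = ncol(X), sampling_rate = 1, time_ms = 0),
    class = "lam_reduced"
  )
}

test_that("ReML recovers a known noise variance from pure identity noise", {
  for (sig2 in c(0.5, 3.7)) {
    X <- withr::with_seed(8, matrix(rnorm(20 * 2e4, sd = sqrt(sig2)), 20))
    red <- reduced_from_samples(X)
    inv <- reml_optimize(identity_priors(20), red)
    total <- inv$cs * sum(inv$E)   # the two identity components share it
    expect_equal(total, sig2, tolerance = 0.02)
    expect_true(all(diff(inv$F_trace) >= -1e-9))
    expect_true(inv$converged)
  }
})

test_that("identical model fits give identical free energy, and F is order-invariant", {
  ds <- tiny_dataset(n_trials = 20, snr_db = -10)
  ctx <- ds$ctx
  red <- reduce_modes(
    preprocess(ds$noisy, use_hann = TRUE),
    context_leadfield_test(ctx, "pial")
  )
  mesh <- ctx$pair$pial
  basis <- laminarmeg:::context_basis(ctx, "pial", 5)
  L <- context_leadfield_test(ctx, "pial")
  centers <- tiny_candidates(6)
  p1 <- build_priors("MSP", mesh, basis, L, red, patch_centers = centers)
  p2 <- build_priors("MSP", mesh, basis, L, red, patch_centers = rev(centers))
  f1 <- reml_optimize(p1, red)
  f2 <- reml_optimize(p2, red)
  expect_identical(reml_optimize(p1, red)$F, f1$F)     # deterministic
  expect_equal(f1$F, f2$F, tolerance = 1e-6)           # component order
})

test_that("prior construction matches each scheme's contract", {
  ds <- tiny_dataset(n_trials = 20, snr_db = -10)
  ctx <- ds$ctx
  red <- reduce_modes(
    preprocess(ds$noisy, use_hann = TRUE),
    context_leadfield_test(ctx, "pial")
  )
  mesh <- ctx$pair$pial
  basis <- laminarmeg:::context_basis(ctx, "pial", 5)
  L <- context_leadfield_test(ctx, "pial")

  iid <- build_priors("IID", mesh, basis, L, red)
  expect_length(iid$comps, 1)
  expect_true(methods::is(iid$comps[[1]]$G, "diagonalMatrix"))

  msp <- build_priors("MSP", mesh, basis, L, red,
                      patch_centers = tiny_candidates(6),
                      n_random_patches = 84, seed = 2)
  expect_length(msp$comps, 90)

  ebb <- build_priors("EBB", mesh, basis, L, red)
  v <- ebb$comps[[1]]$beamformer_variance
  true_v <- ds$spec$vertex_index
  expect_gt(v[true_v], median(v))   # beamformer power peaks near the source
})

test_that("posterior estimates localise the source and shrink zero-prior vertices", {
  ds <- tiny_dataset(n_trials = 20, snr_db = 5)
  ctx <- ds$ctx
  red <- reduce_modes(
    preprocess(ds$noisy, use_hann = FALSE),
    context_leadfield_test(ctx, "pial")
  )
  mesh <- ctx$pair$pial
  basis <- laminarmeg:::context_basis(ctx, "pial", 5)
  L <- context_leadfield_test(ctx, "pial")
  centers <- tiny_candidates(6)
  priors <- build_priors("MSP", mesh, basis, L, red, patch_centers = centers)
  inv <- reml_optimize(priors, red)
  J <- posterior_sources(inv, priors, red)
  pow <- rowMeans(matrix(J^2, nrow(J)))
  # argmax at the true vertex or a patch neighbour
  g <- laminarmeg:::mesh_graph(mesh)
  dist_true <- igraph::distances(g, v = ds$spec$vertex_index)[1, which.max(pow)]
  expect_lt(dist_true, 6)
  # vertices outside every patch have exactly zero prior variance -> zero J
  support <- unique(unlist(lapply(centers, function(cv) {
    which(basis$basis[, cv] != 0)
  })))
  outside <- setdiff(seq_len(nrow(J)), support)
  expect_equal(max(abs(J[outside, , ])), 0)
  # zero data give zero estimates
  red0 <- red
  red0$X[] <- 0
  expect_equal(max(abs(posterior_sources(inv, priors, red0))), 0)
})

test_that("posterior error is orthogonal to the data under the fitted model", {
  ds <- tiny_dataset(n_trials = 20, snr_db = -10)
  ctx <- ds$ctx
  red <- reduce_modes(
    preprocess(ds$noisy, use_hann = TRUE),
    context_leadfield_test(ctx, "pial")
  )
  priors <- build_priors("EBB", ctx$pair$pial,
                         laminarmeg:::context_basis(ctx, "pial", 5),
                         context_leadfield_test(ctx, "pial"), red)
  inv <- reml_optimize(priors, red)
  m <- inv$n_spatial_modes
  # physical-scale fitted covariances reconstructed from the components
  S_src <- inv$cs * inv$gamma[1] * tcrossprod(priors$comps[[1]]$A)
  Sigma_fit <- inv$cs * inv$E[1] * diag(m) + S_src
  # orthogonality E[(s - s_hat) x'] = S - S Sigma^-1 Sigma = 0 holds only
  # if the estimator's P is consistent with the fitted components
  resid_cov <- S_src - (S_src %*% (inv$P / inv$cs)) %*% Sigma_fit
  expect_lt(max(abs(resid_cov)), 1e-6 * max(abs(S_src)))
})

test_that("variance explained is monotone for nested priors while F need not be", {
  X <- withr::with_seed(12, matrix(rnorm(16 * 5000), 16))
  red <- reduced_from_samples(X)
  base <- identity_priors(16)
  extra_A <- withr::with_seed(13, matrix(rnorm(16 * 3), 16))
  nested <- identity_priors(16, n_extra = 1, extra_A = extra_A)
  f_base <- reml_optimize(base, red)
  f_nest <- reml_optimize(nested, red)
  expect_gte(f_nest$variance_explained, f_base$variance_explained - 1e-6)
  expect_true(is.finite(f_base$F) && is.finite(f_nest$F))
})

test_that("mode reduction is an orthonormal projection with the stated SNR gain", {
  ds <- tiny_dataset(n_trials = 10, snr_db = -5)
  red <- reduce_modes(preprocess(ds$noisy), context_leadfield_test(ds$ctx, "pial"))
  expect_equal(crossprod(red$U), diag(red$n_spatial_modes), tolerance = 1e-10)
  expect_equal(crossprod(red$V), diag(red$n_temporal_modes), tolerance = 1e-10)
  expect_equal(red$n_temporal_modes, 4)
  # projecting an already-projected dataset is idempotent
  P <- tcrossprod(red$U)
  expect_equal(P %*% P, P, tolerance = 1e-10)
  expect_equal(temporal_mode_snr_gain(251, 4), sqrt(251 / 4))
  expect_lt(red$n_spatial_modes, dim(ds$noisy$data)[2])
})

test_that("preprocessing passes the band and rejects out-of-band power", {
  make_tone <- function(freq) {
    t_s <- seq(-0.5, 0.5, by = 1 / 250)
    arr <- array(0, c(2, 3, length(t_s)))
    for (tr in 1:2) for (s in 1:3) arr[tr, s, ] <- sin(2 * pi * freq * t_s)
    trial_sensor_data(arr, t_s * 1000, 250)
  }
  mid <- 60:192   # away from filter edge transients
  p20 <- preprocess(make_tone(20), use_hann = FALSE)
  expect_equal(sd(p20$data[1, 1, mid]) / sd(make_tone(20)$data[1, 1, mid]), 1,
               tolerance = 0.05)
  p50 <- preprocess(make_tone(50), use_hann = FALSE)
  atten <- 20 * log10(sd(make_tone(50)$data[1, 1, mid]) / sd(p50$data[1, 1, mid]))
  expect_gt(atten, 20)
  # the Hann taper tapers the epoch ends
  ph <- preprocess(make_tone(20), use_hann = TRUE)
  expect_lt(abs(ph$data[1, 1, 2]), abs(p20$data[1, 1, 2]))
  expect_error(preprocess(make_tone(20), band = c(30, 10)), "band")
  # the fused temporal-operator path equals preprocess-then-reduce exactly
  ds <- tiny_dataset(n_trials = 6, snr_db = -10)
  L <- context_leadfield_test(ds$ctx, "pial")
  R <- preprocessing_operator(251, 250, c(10, 30), use_hann = TRUE)
  r1 <- reduce_modes(preprocess(ds$noisy, use_hann = TRUE), L)
  r2 <- reduce_modes(ds$noisy, L, temporal_operator = R)
  expect_equal(r1$X, r2$X, tolerance = 1e-9)
  expect_equal(r1$C, r2$C, tolerance = 1e-9)
})
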