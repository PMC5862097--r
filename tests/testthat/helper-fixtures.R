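# Shared fixtures, built once per test run and cached. Small anatomy for
# unit tests; the full study-scale setup is built lazily by the
# acceptance helpers (helper-acceptance.R).

.fix <- new.env(parent = emptyenv())

tiny_pair <- function() {
  if (is.null(.fix$pair)) {
    .fix$pair <- generate_synthetic_cortex(642, seed = 11)
  }
  .fix$pair
}

tiny_context <- function() {
  if (is.null(.fix$ctx)) {
    .fix$ctx <- laminar_context(tiny_pair(), generate_sensor_array(64),
                                conductor_model(radius = 85))
  }
  .fix$ctx
}

# candidate source vertices with usable lead fields on both surfaces
tiny_candidates <- function(n = 8) {
  if (is.null(.fix$cands)) {
    ctx <- tiny_context()
    rms_p <- lead_field_rms(context_leadfield_test(ctx, "pial"))
    rms_w <- lead_field_rms(context_leadfield_test(ctx, "white"))
    ok <- which(rms_p > quantile(rms_p, 0.2) & rms_w > quantile(rms_w, 0.2))
    .fix$cands <- withr::with_seed(5, sample(ok, 12))
  }
  .fix$cands[seq_len(n)]
}

# access the context caches through exported surface (kept thin here)
context_leadfield_test <- function(ctx, surface) {
  laminarmeg:::context_leadfield(ctx, surface)
}

tiny_dataset <- function(vertex = NULL, surface = "pial", snr_db = -10,
                         n_trials = 40, patch_fwhm = 5, seed = 21) {
  ctx <- tiny_context()
  vertex <- vertex %||% tiny_candidates(1)
  spec <- simulation_spec(vertex, surface, n_trials = n_trials,
                          noise_value = snr_db, patch_fwhm = patch_fwhm,
                          seed = seed)
  clean <- project_patch(
    spec, ctx$pair, context_leadfield_test(ctx, surface),
    laminarmeg:::context_basis(ctx, surface, patch_fwhm)
  )
  list(clean = clean,
       noisy = add_noise_snr(clean, snr_db, seed = seed + 1),
       spec = spec, ctx = ctx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
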