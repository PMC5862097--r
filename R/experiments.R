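# Config-driven reproduction of the simulation studies: the SNR sweep,
# the patch-size grid and the anatomy correlation analysis.

#' Experiment configuration
#'
#' Builds the configuration list for the simulation experiments. Defaults
#' are the study conditions: 20 Hz patch sources (FWHM 5 mm, 10 nAm,
#' 100-500 ms) at 60 linked vertices per surface, 515 trials, SNR grid
#' -100..5 dB plus a noise-only control, MSP patch library of the 60
#' candidate centres plus 30 random vertices, 10-fold sensor
#' cross-validation, |delta F| > 3 and alpha = 0.05 thresholds. Anatomy
#' and sensor parameters are the desk-scale defaults of
#' [generate_synthetic_cortex()] and [generate_sensor_array()].
#'
#' @param ... overrides of the default fields (unknown names error).
#' @return a `lam_config` list.
#' @export
laminar_config <- function(...) {
  cfg <- list(
    anatomy = list(n_vertices = 2562, fold_amplitude = 8,
                   fold_wavelength = 30, base_radius = 70),
    sensors = list(n_sensors = 160, helmet_radius = 110, coverage = 0.5),
    conductor = list(radius = 95),
    n_sources_per_surface = 60,
    snr_grid_db = c(-100, -50, -20, -5, 0, 5),
    include_noise_only = TRUE,
    schemes = c("EBB", "MSP"),
    analyses = c("whole_brain", "roi"),
    frequency = 20, dipole_moment = 10,
    active_window = c(100, 500), baseline_window = c(-500, -100),
    n_trials = 515, sampling_rate = 250, epoch = c(-500, 500),
    sim_patch_fwhm = 5, rec_patch_fwhm = 5,
    patch_grid = list(simulate = c(5, 10), reconstruct = c(5, 10),
                      snr_db = 5, schemes = "EBB",
                      n_sources_per_surface = 16),
    band = c(10, 30), n_temporal = 4,
    n_msp_random = 30, k_folds = 10,
    delta_f_threshold = 3, alpha = 0.05,
    eligibility_rms_quantile = 0.01
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) abort(paste("unknown config fields:", paste(bad, collapse = ", ")))
  cfg[names(ov)] <- ov
  structure(cfg, class = "lam_config")
}

#' Read / write experiment configs as YAML
#' @param path YAML file.
#' @export
read_config <- function(path) {
  do.call(laminar_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a `lam_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# deterministic seed ladder: one experiment seed expands to a table of
# per-purpose seeds so any single simulation is reproducible in isolation
seed_ladder <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Build the experiment anatomy and source design
#'
#' Generates the synthetic cortex and sensor array of a config, chooses
#' the balanced source design (n linked vertices per surface, drawn from
#' vertices whose lead-field RMS on both surfaces is above the exclusion
#' quantile) and the MSP patch library (candidates + random patches).
#'
#' @param config a `lam_config`.
#' @param seed experiment seed.
#' @return list with `context`, `sources` (tibble: sim_id, surface,
#'   vertex), `msp_centers`, `seeds`.
#' @export
setup_experiment <- function(config, seed = 1) {
  seeds <- seed_ladder(seed, 8)
  pair <- generate_synthetic_cortex(
    n_vertices = config$anatomy$n_vertices,
    fold_amplitude = config$anatomy$fold_amplitude,
    fold_wavelength = config$anatomy$fold_wavelength,
    base_radius = config$anatomy$base_radius,
    seed = seeds[1]
  )
  sensors <- generate_sensor_array(
    n_sensors = config$sensors$n_sensors,
    helmet_radius = config$sensors$helmet_radius,
    coverage = config$sensors$coverage
  )
  ctx <- laminar_context(pair, sensors,
                         conductor_model(radius = config$conductor$radius))
  rms_p <- lead_field_rms(context_leadfield(ctx, "pial"))
  rms_w <- lead_field_rms(context_leadfield(ctx, "white"))
  q <- config$eligibility_rms_quantile
  eligible <- which(
    rms_p > quantile(rms_p, q) & rms_w > quantile(rms_w, q) &
      !ctx$pair$pial$boundary
  )
  ns <- config$n_sources_per_surface
  cand <- withr::with_seed(seeds[2], sample(eligible, ns))
  sources <- tibble(
    sim_id = seq_len(2 * ns),
    surface = rep(c("pial", "white"), each = ns),
    vertex = rep(cand, 2)
  )
  pool <- setdiff(seq_len(n_vertices(pair$pial)), cand)
  msp_centers <- c(cand, withr::with_seed(seeds[3], {
    sample(pool, config$n_msp_random)
  }))
  list(context = ctx, sources = sources, msp_centers = msp_centers,
       candidates = cand, seeds = seeds, config = config)
}

# noiseless projection of one design source (reused across SNR levels)
project_design_source <- function(setup, sim_row, sim_fwhm = NULL) {
  config <- setup$config
  sim_fwhm <- sim_fwhm %||% config$sim_patch_fwhm
  ctx <- setup$context
  spec <- simulation_spec(
    vertex_index = sim_row$vertex, surface_label = sim_row$surface,
    frequency = config$frequency, active_window = config$active_window,
    dipole_moment = config$dipole_moment, patch_fwhm = sim_fwhm,
    n_trials = config$n_trials, sampling_rate = config$sampling_rate,
    epoch = config$epoch,
    seed = setup$seeds[4] + sim_row$sim_id
  )
  project_patch(
    spec, ctx$pair, context_leadfield(ctx, sim_row$surface),
    context_basis(ctx, sim_row$surface, sim_fwhm)
  )
}

# seeded noise for one design dataset (seed derived from the ladder)
noise_design_dataset <- function(setup, sim_row, clean, snr_db,
                                 noise_seed_offset = 0) {
  add_noise_snr(clean, snr_db,
                seed = (setup$seeds[5] + 1000L * sim_row$sim_id +
                          noise_seed_offset) %% .Machine$integer.max)
}

# simulate one dataset of the design
simulate_design_dataset <- function(setup, sim_row, snr_db, sim_fwhm = NULL,
                                    noise_seed_offset = 0) {
  clean <- project_design_source(setup, sim_row, sim_fwhm)
  noise_design_dataset(setup, sim_row, clean, snr_db, noise_seed_offset)
}

# run the configured analyses of one dataset for all schemes, reusing the
# mode reduction across schemes
analyze_dataset <- function(noisy, setup, schemes, analyses,
                            rec_fwhm = NULL, with_cv = FALSE) {
  config <- setup$config
  ctx <- setup$context
  rec_fwhm <- rec_fwhm %||% config$rec_patch_fwhm
  rows <- NULL
  U <- context_stacked_modes(ctx)
  dd <- dim(noisy$data)
  red_wb <- if ("whole_brain" %in% analyses) {
    reduce_modes(noisy, NULL, config$n_temporal, U = U, per_trial = FALSE,
                 temporal_operator = preprocessing_operator(
                   dd[3], noisy$sampling_rate, config$band, use_hann = TRUE))
  }
  red_roi <- if ("roi" %in% analyses) {
    reduce_modes(noisy, NULL, config$n_temporal, U = U,
                 temporal_operator = preprocessing_operator(
                   dd[3], noisy$sampling_rate, config$band, use_hann = FALSE))
  }
  for (scheme in schemes) {
    if ("whole_brain" %in% analyses) {
      dec <- whole_brain_compare(
        noisy, ctx, scheme, patch_fwhm = rec_fwhm,
        msp_centers = setup$msp_centers, n_random_patches = 0,
        band = config$band, n_temporal = config$n_temporal,
        threshold = config$delta_f_threshold, reduced = red_wb
      )
      if (with_cv) {
        cvp <- cross_validation_error(
          noisy, ctx, "pial", scheme, k_folds = config$k_folds,
          seed = setup$seeds[6], patch_fwhm = rec_fwhm,
          msp_centers = setup$msp_centers,
          band = config$band, n_temporal = config$n_temporal
        )
        cvw <- cross_validation_error(
          noisy, ctx, "white", scheme, k_folds = config$k_folds,
          seed = setup$seeds[6], patch_fwhm = rec_fwhm,
          msp_centers = setup$msp_centers,
          band = config$band, n_temporal = config$n_temporal
        )
        dec$delta_cv <- cvw - cvp
        dec$cv_err_pial <- cvp
        dec$cv_err_white <- cvw
      }
      rows <- bind_rows(rows, dec)
    }
    if ("roi" %in% analyses) {
      roi <- roi_analysis(
        noisy, ctx, scheme, patch_fwhm = rec_fwhm,
        msp_centers = setup$msp_centers, n_random_patches = 0,
        band = config$band, active = config$active_window,
        baseline = config$baseline_window,
        n_temporal = config$n_temporal, alpha = config$alpha,
        reduced = red_roi
      )
      rows <- bind_rows(rows, roi)
    }
  }
  rows
}

#' Run the SNR sweep
#'
#' Simulates every source of the balanced design at every SNR of the grid
#' (plus the noise-only control when configured) and runs the configured
#' schemes and analyses. Fully seeded: the same config and seed reproduce
#' the table exactly.
#'
#' @param config a `lam_config`.
#' @param seed experiment seed.
#' @param setup optional pre-built [setup_experiment()] result (reused
#'   across experiments).
#' @param snr_grid_db optional override of the config grid.
#' @param with_cv also compute the whole-brain cross-validation error
#'   difference per simulation.
#' @param progress print per-condition progress.
#' @return a `lam_sweep`: list with `decisions` (one row per simulation x
#'   scheme x analysis), `aggregates` (accuracy / bias / significance per
#'   condition with exact binomial p-values), `sources`, `config`,
#'   `seed`.
#' @export
run_snr_sweep <- function(config = laminar_config(), seed = 1, setup = NULL,
                          snr_grid_db = NULL, with_cv = FALSE,
                          progress = FALSE) {
  setup <- setup %||% setup_experiment(config, seed)
  grid <- snr_grid_db %||% c(
    config$snr_grid_db, if (config$include_noise_only) -Inf
  )
  # sources outer, SNR inner: the noiseless projection of each source is
  # shared across the grid; noise seeds depend only on the sim id and the
  # SNR-independent ladder, so the result matches the per-level order
  decisions <- NULL
  for (i in seq_len(nrow(setup$sources))) {
    sim <- setup$sources[i, ]
    clean <- project_design_source(setup, sim)
    for (snr in grid) {
      noisy <- noise_design_dataset(setup, sim, clean, snr)
      rows <- analyze_dataset(noisy, setup, config$schemes, config$analyses,
                              with_cv = with_cv)
      rows$snr_db <- snr
      rows$sim_id <- sim$sim_id
      rows$truth <- sim$surface
      rows$vertex <- sim$vertex
      decisions <- bind_rows(decisions, rows)
    }
    if (progress && i %% 20 == 0) {
      message(sprintf("%d of %d sources done", i, nrow(setup$sources)))
    }
  }
  decisions <- arrange(decisions, .data$snr_db, .data$sim_id)
  new_sweep(decisions, setup, seed)
}

new_sweep <- function(decisions, setup, seed) {
  structure(
    list(
      decisions = decisions,
      aggregates = aggregate_decisions(decisions),
      sources = setup$sources,
      config = setup$config,
      seed = seed
    ),
    class = "lam_sweep"
  )
}

#' Aggregate a decision table
#'
#' Per condition (grouping columns present among `snr_db`, `scheme`,
#' `analysis`, `sim_fwhm`, `rec_fwhm`): classification accuracy, pial
#' bias, significant fraction and thresholded accuracy, with exact
#' two-sided binomial p-values against chance for accuracy and bias.
#'
#' @param decisions decision tibble with `label`, `significant`, `truth`.
#' @return aggregate tibble.
#' @export
aggregate_decisions <- function(decisions) {
  keys <- intersect(c("snr_db", "scheme", "analysis", "sim_fwhm", "rec_fwhm"),
                    names(decisions))
  decisions %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::group_modify(function(d, key) {
      cb <- classify_batch(d, d$truth)
      cb$p_accuracy <- binomial_two_sided(
        round(cb$accuracy / 100 * cb$n), cb$n
      )$p_value
      cb$p_pial_bias <- binomial_two_sided(
        round(cb$pial_bias / 100 * cb$n), cb$n
      )$p_value
      cb
    }) %>%
    ungroup()
}

#' @export
print.lam_sweep <- function(x, ...) {
  cat(sprintf("<lam_sweep> %d decisions over %d condition(s)\n",
              nrow(x$decisions), nrow(x$aggregates)))
  print(x$aggregates, n = 20)
  invisible(x)
}

#' Run the patch-size mismatch grid
#'
#' Simulates sources with each simulation patch size and reconstructs
#' with each reconstruction patch size (default 5 and 10 mm each way) at
#' the configured SNR, whole-brain analysis. Matched versus mismatched
#' accuracy is contrasted per scheme with an exact McNemar test.
#'
#' @inheritParams run_snr_sweep
#' @return a `lam_sweep` whose decisions carry `sim_fwhm` and `rec_fwhm`;
#'   the `mcnemar` element holds the matched-versus-mismatched contrasts.
#' @export
run_patch_size_grid <- function(config = laminar_config(), seed = 1,
                                setup = NULL, progress = FALSE) {
  pg <- config$patch_grid
  ns <- pg$n_sources_per_surface %||% config$n_sources_per_surface
  setup <- setup %||% setup_experiment(config, seed)
  src <- setup$sources %>%
    group_by(.data$surface) %>%
    dplyr::slice_head(n = ns) %>%
    ungroup()
  decisions <- NULL
  for (sf in pg$simulate) {
    for (i in seq_len(nrow(src))) {
      sim <- src[i, ]
      noisy <- simulate_design_dataset(setup, sim, pg$snr_db, sim_fwhm = sf,
                                       noise_seed_offset = round(100 * sf))
      for (rf in pg$reconstruct) {
        rows <- analyze_dataset(noisy, setup, pg$schemes, "whole_brain",
                                rec_fwhm = rf)
        rows$snr_db <- pg$snr_db
        rows$sim_id <- sim$sim_id
        rows$truth <- sim$surface
        rows$vertex <- sim$vertex
        rows$sim_fwhm <- sf
        rows$rec_fwhm <- rf
        decisions <- bind_rows(decisions, rows)
      }
    }
    if (progress) message(sprintf("simulate fwhm %g mm done", sf))
  }
  out <- new_sweep(decisions, setup, seed)
  out$mcnemar <- patch_grid_mcnemar(decisions)
  out
}

# matched vs mismatched accuracy contrast per scheme (paired by the
# simulated dataset)
patch_grid_mcnemar <- function(decisions) {
  res <- NULL
  for (sch in unique(decisions$scheme)) {
    d <- decisions %>% filter(.data$scheme == sch, .data$analysis == "whole_brain")
    d$correct <- !is.na(d$label) & d$label == d$truth
    d$matched <- d$sim_fwhm == d$rec_fwhm
    key <- paste(d$sim_id, d$sim_fwhm)
    ok_m <- d$correct[d$matched][order(key[d$matched])]
    ok_x <- d$correct[!d$matched][order(key[!d$matched])]
    mt <- mcnemar_exact(ok_m, ok_x)
    mt$scheme <- sch
    mt$accuracy_matched <- 100 * mean(ok_m)
    mt$accuracy_mismatched <- 100 * mean(ok_x)
    res <- bind_rows(res, mt)
  }
  res
}

#' Anatomy-discriminability correlations
#'
#' Relates the free-energy difference between the correct and incorrect
#' surface models (delta F = F_correct - F_incorrect) of each simulation
#' to the anatomical statistics at the source vertex (cortical thickness,
#' mean curvature, sulcal depth, lead-field RMS): Spearman correlations,
#' Meng's heterogeneity test over the absolute correlations, and pairwise
#' Z follow-ups.
#'
#' @param sweep a `lam_sweep` containing whole-brain decisions.
#' @param context the `lam_context` the sweep ran on.
#' @param scheme scheme whose delta F is analysed.
#' @param snr_db sweep SNR level to use.
#' @return list: `correlations` (Spearman tibble), `meng` (heterogeneity +
#'   pairwise), `data` (per-simulation table).
#' @export
run_anatomy_correlation <- function(sweep, context, scheme = "EBB",
                                    snr_db = -20) {
  d <- sweep$decisions %>%
    filter(.data$analysis == "whole_brain", .data$scheme == !!scheme,
           .data$snr_db == !!snr_db)
  if (!nrow(d)) abort("no whole-brain decisions at that scheme / SNR")
  d$delta_f_correct <- ifelse(d$truth == "pial", d$delta_F, -d$delta_F)

  stats <- surface_statistics(
    context$pair,
    lead_fields = list(pial = context_leadfield(context, "pial"),
                       white = context_leadfield(context, "white"))
  )
  d <- left_join(
    d, stats,
    by = c("vertex" = "vertex_index", "truth" = "surface")
  )
  preds <- list(
    thickness = d$thickness_mm,
    curvature = d$curvature_per_mm,
    sulcal_depth = d$sulcal_depth_mm,
    leadfield_rms = d$leadfield_rms
  )
  cors <- bind_rows(lapply(names(preds), function(nm) {
    ct <- spearman_test(preds[[nm]], d$delta_f_correct)
    ct$predictor <- nm
    ct
  }))
  constant <- vapply(preds, function(p) sd(p) == 0, TRUE)
  mg <- if (any(constant) || nrow(d) < 10) NULL else {
    meng_test(d$delta_f_correct, preds)
  }
  list(correlations = cors, meng = mg, data = d)
}

#' Lead-field similarity of linked pairs versus surface neighbours
#'
#' For every linked vertex pair, compares the absolute difference in
#' lead-field RMS between the pial and white vertex with the mean
#' absolute difference to the vertex's immediate same-surface mesh
#' neighbours, and reports the fraction of vertices (per surface) where
#' the cross-surface difference is the smaller one.
#'
#' @param pair a `lam_surface_pair`.
#' @param L_pial,L_white the two surfaces' lead fields.
#' @return tibble with `surface` and `fraction_cross_smaller` (percent).
#' @export
leadfield_neighbour_analysis <- function(pair, L_pial, L_white) {
  rms_p <- lead_field_rms(L_pial)
  rms_w <- lead_field_rms(L_white)
  cross <- abs(rms_p - rms_w)
  edges <- mesh_edges(pair$pial$faces)
  adj_diff <- function(rms) {
    dd <- abs(rms[edges[, 1]] - rms[edges[, 2]])
    num <- tapply_add(edges[, 1], dd, length(rms)) +
      tapply_add(edges[, 2], dd, length(rms))
    cnt <- tapply_add(edges[, 1], rep(1, nrow(edges)), length(rms)) +
      tapply_add(edges[, 2], rep(1, nrow(edges)), length(rms))
    keep <- cnt > 0
    list(mean = num[keep] / cnt[keep], keep = keep)
  }
  out <- NULL
  for (s in c("pial", "white")) {
    rms <- if (s == "pial") rms_p else rms_w
    nb <- adj_diff(rms)
    frac <- 100 * mean(cross[nb$keep] < nb$mean)
    out <- bind_rows(out, tibble(surface = s, fraction_cross_smaller = frac))
  }
  out
}
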