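# The three laminar-discrimination analyses. Conventions follow the sign
# rules: positive metrics favour the pial (superficial) surface.
#   delta_F  = F_pial - F_white        (whole-brain free energy)
#   delta_cv = cv_err_white - cv_err_pial  (percentage points)
#   roi_t    = paired t, pial vs white ROI power change over trials

#' Whole-brain laminar comparison by free energy
#'
#' Inverts the (Hann-windowed, 10-30 Hz band-passed) data separately on
#' the pial-only and white-only surface models with identical settings -
#' the same spatial modes, computed from the column-stacked lead field of
#' both surfaces, and the same temporal modes - and compares the ReML free
#' energies. `delta_F > 0` labels the source pial; `|delta_F| > 3`
#' (roughly a twenty-fold likelihood ratio) marks the decision
#' significant.
#'
#' @param data a `lam_trial_data` (raw; preprocessing is applied
#'   internally).
#' @param context a `lam_context` from [laminar_context()].
#' @param scheme inversion scheme (`"IID"`, `"COH"`, `"EBB"`, `"MSP"`).
#' @param patch_fwhm reconstruction patch FWHM, mm.
#' @param msp_centers candidate patch-centre vertex indices (per-surface
#'   indexing) for MSP.
#' @param n_random_patches extra random MSP patches (shared between the
#'   two surface models).
#' @param seed seed for the random patches.
#' @param use_hann,band preprocessing of the whole-brain path.
#' @param n_temporal temporal modes.
#' @param threshold significance threshold on `|delta_F|`.
#' @param details return the two inversions as attributes.
#' @return one-row tibble: `analysis`, `scheme`, `delta_F`, `label`
#'   (`"pial"`, `"white"` or `"undetermined"`), `significant`, `F_pial`,
#'   `F_white`, `cv_err_pial`, `cv_err_white` (NA here), `converged`.
#' @export
whole_brain_compare <- function(data, context, scheme = "MSP",
                                patch_fwhm = 5, msp_centers = NULL,
                                n_random_patches = 30, seed = 0,
                                use_hann = TRUE, band = c(10, 30),
                                n_temporal = 4, threshold = 3,
                                details = FALSE, reduced = NULL) {
  if (is.null(reduced)) {
    R <- preprocessing_operator(dim(data$data)[3], data$sampling_rate,
                                band, use_hann)
    reduced <- reduce_modes(data, NULL, n_temporal, temporal_operator = R,
                            U = context_stacked_modes(context),
                            per_trial = FALSE)
  }

  centers <- msp_centers
  if (identical(scheme, "MSP")) {
    if (is.null(centers)) abort("MSP requires msp_centers")
    if (n_random_patches > 0) {
      pool <- setdiff(seq_len(n_vertices(context$pair$pial)), centers)
      centers <- c(centers, withr::with_seed(seed, sample(pool, n_random_patches)))
    }
  }

  fit_surface <- function(surface) {
    mesh <- context_mesh(context, surface)
    priors <- build_priors(
      scheme, mesh, context_basis(context, surface, patch_fwhm),
      context_leadfield(context, surface), reduced,
      patch_centers = centers, n_random_patches = 0
    )
    list(inv = reml_optimize(priors, reduced), priors = priors)
  }
  fp <- fit_surface("pial")
  fw <- fit_surface("white")
  delta_F <- fp$inv$F - fw$inv$F
  converged <- fp$inv$converged && fw$inv$converged
  out <- tibble(
    analysis = "whole_brain", scheme = scheme,
    delta_F = delta_F,
    label = if (!converged) NA_character_ else if (delta_F > 0) "pial"
            else if (delta_F < 0) "white" else "undetermined",
    significant = converged && abs(delta_F) > threshold,
    F_pial = fp$inv$F, F_white = fw$inv$F,
    roi_t = NA_real_, delta_cv = NA_real_,
    converged = converged
  )
  if (details) {
    attr(out, "inversions") <- list(pial = fp, white = fw, reduced = reduced)
  }
  out
}

#' Held-out-sensor cross-validation error
#'
#' k-fold cross-validation over sensors: each fold removes a random tenth
#' (for `k = 10`) of the sensors, inverts the remaining data, and predicts
#' the held-out sensors through their lead-field rows and the posterior
#' sources. The fold error is the RMSE of the predicted held-out data as a
#' percentage of the RMS measured data per excluded sensor (both in the
#' band-passed, temporal-mode-projected representation used by the
#' inversion), averaged over excluded sensors; the returned error is the
#' mean over folds.
#'
#' @param data a `lam_trial_data`.
#' @param context a `lam_context`.
#' @param surface `"pial"`, `"white"` or `"combined"` - the surface model
#'   being scored.
#' @param scheme inversion scheme.
#' @param k_folds number of sensor folds (>= 2).
#' @param seed fold-assignment seed.
#' @inheritParams whole_brain_compare
#' @return cross-validation error, percent.
#' @export
cross_validation_error <- function(data, context, surface = "pial",
                                   scheme = "EBB", k_folds = 10, seed = 0,
                                   patch_fwhm = 5, msp_centers = NULL,
                                   use_hann = TRUE, band = c(10, 30),
                                   n_temporal = 4) {
  stopifnot(k_folds >= 2)
  d <- dim(data$data)
  n_sensors <- d[2]
  n_trials <- d[1]
  mesh <- context_mesh(context, surface)
  Lfull <- context_leadfield(context, surface)$matrix
  basis <- context_basis(context, surface, patch_fwhm)
  R <- preprocessing_operator(d[3], data$sampling_rate, band, use_hann)

  # temporal modes are computed once from the all-sensor trial average and
  # shared across folds (the same basis for fit, prediction and
  # measurement); spatial modes are re-derived per fold from the kept
  # sensors' lead field. Fit and prediction use the evoked response.
  K <- min(n_temporal, d[3])
  abar <- colMeans(data$data, dims = 1)
  V <- svd(abar %*% R, nu = 0, nv = K)$v
  RV <- R %*% V
  Wbar <- abar %*% RV                           # sensors x K evoked modes

  folds <- withr::with_seed(seed, {
    split(sample(n_sensors), rep_len(seq_len(k_folds), n_sensors))
  })
  fold_err <- vapply(folds, function(out_idx) {
    in_idx <- setdiff(seq_len(n_sensors), out_idx)
    L_in <- Lfull[in_idx, , drop = FALSE]
    U_in <- spatial_modes(L_in)
    m <- ncol(U_in)
    Xbar <- crossprod(U_in, Wbar[in_idx, , drop = FALSE])
    reduced <- structure(
      list(
        X = NULL, Xbar = Xbar, U = U_in, V = V, RV = RV,
        C = tcrossprod(Xbar) / K,
        n_spatial_modes = m, n_temporal_modes = K, n_eff = K,
        n_samples = d[3], n_trials = n_trials,
        sampling_rate = data$sampling_rate, time_ms = data$time_ms
      ),
      class = "lam_reduced"
    )
    priors <- build_priors(scheme, mesh, basis, L_in, reduced,
                           patch_centers = msp_centers, n_random_patches = 0)
    inv <- reml_optimize(priors, reduced)
    pred <- predict_held_out(inv, priors, reduced, Lfull[out_idx, , drop = FALSE])
    meas <- Wbar[out_idx, , drop = FALSE]
    num <- sqrt(rowSums((pred - meas)^2))
    den <- sqrt(rowSums(meas^2))
    keep <- den > 0
    if (!all(keep)) {
      warn("held-out sensor with zero RMS data skipped")
    }
    mean(100 * num[keep] / den[keep])
  }, 1)
  mean(fold_err)
}

#' ROI laminar comparison by paired t-statistic
#'
#' Inverts the data (10-30 Hz, no Hann taper) on the combined
#' white-plus-pial mesh, computes per-vertex, per-trial band power of the
#' posterior source time courses in the active and baseline windows, and
#' forms a functional ROI from the per-vertex active-versus-baseline
#' paired t-map: vertices of either surface with a t-statistic at or above
#' that surface's 75th percentile, together with their linked counterparts
#' on the other surface. Per trial, each surface's ROI value is the mean
#' absolute power change within the ROI; the returned statistic is the
#' paired t over trials of pial minus white ROI values. Per-vertex t-maps
#' use corrected noise variance estimates (variances floored at the 10th
#' across-vertex percentile) to attenuate artifactually high significance.
#'
#' @inheritParams whole_brain_compare
#' @param percentile ROI-defining t-map percentile (0.75 keeps the top
#'   quarter per surface).
#' @param active,baseline analysis windows, ms.
#' @param var_floor_quantile variance-floor quantile of the per-vertex
#'   variance distribution.
#' @param alpha significance level of the final paired t-test.
#' @return one-row tibble with `roi_t`, `label`, `significant`.
#' @export
roi_analysis <- function(data, context, scheme = "MSP", patch_fwhm = 5,
                         msp_centers = NULL, n_random_patches = 30,
                         seed = 0, percentile = 0.75, band = c(10, 30),
                         active = c(100, 500), baseline = c(-500, -100),
                         n_temporal = 4, var_floor_quantile = 0.1,
                         alpha = 0.05, details = FALSE, reduced = NULL) {
  n_trials <- dim(data$data)[1]
  stopifnot(n_trials >= 2)
  if (percentile <= 0 || percentile >= 1) abort("percentile must be in (0,1)")
  N <- n_vertices(context$pair$pial)
  mesh <- context_mesh(context, "combined")
  if (is.null(reduced)) {
    R <- preprocessing_operator(dim(data$data)[3], data$sampling_rate,
                                band, use_hann = FALSE)
    reduced <- reduce_modes(data, NULL, n_temporal, temporal_operator = R,
                            U = context_stacked_modes(context))
  }

  centers <- msp_centers
  if (identical(scheme, "MSP")) {
    if (is.null(centers)) abort("MSP requires msp_centers")
    if (n_random_patches > 0) {
      pool <- setdiff(seq_len(N), centers)
      centers <- c(centers, withr::with_seed(seed, sample(pool, n_random_patches)))
    }
    centers <- c(centers, centers + N)  # patches on both surfaces
  }
  priors <- build_priors(
    scheme, mesh, context_basis(context, "combined", patch_fwhm),
    context_leadfield(context, "combined"), reduced,
    patch_centers = centers, n_random_patches = 0
  )
  inv <- reml_optimize(priors, reduced)
  if (!inv$converged) {
    return(tibble(
      analysis = "roi", scheme = scheme, delta_F = NA_real_,
      label = NA_character_, significant = FALSE,
      F_pial = NA_real_, F_white = NA_real_, roi_t = NA_real_,
      delta_cv = NA_real_, converged = FALSE
    ))
  }
  J <- posterior_sources(inv, priors, reduced)          # 2N x K x T
  K <- dim(J)[2]
  Ja <- lapply(seq_len(K), function(a) J[, a, ])        # mode slices, 2N x T

  p_act <- mode_power(Ja, window_mode_cov(reduced$V, data$time_ms, active))
  p_base <- mode_power(Ja, window_mode_cov(reduced$V, data$time_ms, baseline))
  d <- p_act - p_base                                    # 2N x T

  mv <- rowMeans(d)
  vv <- rowSums((d - mv)^2) / (n_trials - 1)
  vfloor <- quantile(vv, var_floor_quantile)
  den <- sqrt(pmax(vv, vfloor) / n_trials)
  tmap <- ifelse(den > 0, mv / den, 0)  # sparse priors leave exact zeros

  surf_of <- rep(c("white", "pial"), each = N)
  roi_base <- integer(0)
  for (s in c("white", "pial")) {
    ts <- tmap[surf_of == s]
    thr <- quantile(ts, percentile)
    roi_base <- union(roi_base, which(ts >= thr))
  }
  if (!length(roi_base)) abort("empty ROI; degenerate percentile")

  white_vals <- colMeans(abs(d[roi_base, , drop = FALSE]))
  pial_vals <- colMeans(abs(d[roi_base + N, , drop = FALSE]))
  diffs <- pial_vals - white_vals
  sdd <- sd(diffs)
  roi_t <- if (sdd == 0) 0 else mean(diffs) / (sdd / sqrt(n_trials))
  crit <- qt(1 - alpha / 2, df = n_trials - 1)

  out <- tibble(
    analysis = "roi", scheme = scheme,
    delta_F = NA_real_,
    label = if (!inv$converged) NA_character_ else if (roi_t > 0) "pial"
            else if (roi_t < 0) "white" else "undetermined",
    significant = inv$converged && abs(roi_t) > crit,
    F_pial = NA_real_, F_white = NA_real_,
    roi_t = roi_t, delta_cv = NA_real_,
    converged = inv$converged
  )
  if (details) {
    attr(out, "roi") <- list(
      tmap = tmap, roi = roi_base, inversion = inv,
      power_change = d
    )
  }
  out
}

# covariance of the temporal modes restricted to a time window: the
# quadratic form turning mode coefficients into window variance (power)
window_mode_cov <- function(V, time_ms, window) {
  w <- which(time_ms >= window[1] & time_ms <= window[2])
  Vw <- V[w, , drop = FALSE]
  Vc <- sweep(Vw, 2, colMeans(Vw))
  crossprod(Vc) / (length(w) - 1)
}

# per-vertex, per-trial power from mode-coefficient slices Ja (list of K
# matrices n x T): quadratic form with the window's mode covariance
mode_power <- function(Ja, S) {
  K <- length(Ja)
  P <- S[1, 1] * Ja[[1]]^2
  for (a in seq_len(K)) {
    if (a > 1) P <- P + S[a, a] * Ja[[a]]^2
    if (a < K) {
      for (b in (a + 1):K) {
        P <- P + (2 * S[a, b]) * (Ja[[a]] * Ja[[b]])
      }
    }
  }
  P
}

#' Aggregate laminar decisions
#'
#' Classification summary of a batch of laminar decisions against the
#' ground-truth surfaces: percent accuracy (undetermined labels score as
#' incorrect), percent labelled pial (bias), percent significant, and
#' percent both correct and significant (thresholded accuracy).
#'
#' @param decisions tibble with `label` and `significant` columns (one row
#'   per simulation).
#' @param truth character vector of true surfaces (`"pial"`/`"white"`).
#' @return one-row tibble: `n`, `accuracy`, `pial_bias`,
#'   `significant_fraction`, `accuracy_thresholded` (all percent).
#' @export
classify_batch <- function(decisions, truth) {
  stopifnot(nrow(decisions) == length(truth))
  correct <- !is.na(decisions$label) & decisions$label == truth
  tibble(
    n = length(truth),
    accuracy = 100 * mean(correct),
    pial_bias = 100 * mean(!is.na(decisions$label) & decisions$label == "pial"),
    significant_fraction = 100 * mean(decisions$significant),
    accuracy_thresholded = 100 * mean(correct & decisions$significant),
    n_invalid = sum(is.na(decisions$label))
  )
}
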