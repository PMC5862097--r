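# Posterior source estimation and sensor-level prediction. The MAP
# estimator in the reduced space is
#   J = sum_k gamma_k G_k (A_k' P X)
# with G_k the source-side factor of component k, A_k its projected lead
# field and P the inverse of the fitted (normalised) model covariance.

#' Posterior source time courses
#'
#' Applies the maximum-a-posteriori linear estimator to the reduced data of
#' each trial, returning per-vertex coefficients in the temporal-mode basis
#' (multiply by `t(reduced$V)` to expand to sample time courses, in nAm).
#' Vertices with zero prior variance have exactly zero estimates.
#'
#' @param result a converged `lam_inversion`.
#' @param priors the `lam_priors` used for the fit.
#' @param reduced the `lam_reduced` data that were inverted.
#' @param trials trial indices (default: all).
#' @return array `n_vertices x n_temporal_modes x n_trials` of source
#'   coefficients (nAm scale).
#' @export
posterior_sources <- function(result, priors, reduced, trials = NULL) {
  if (!result$converged) abort("inversion did not converge")
  trials <- trials %||% seq_len(dim(reduced$X)[3])
  m <- result$n_spatial_modes
  K <- dim(reduced$X)[2]
  X <- matrix(reduced$X[, , trials, drop = FALSE], m, K * length(trials))
  PX <- result$P %*% X
  fac <- fitted_source_factor(result, priors)
  Atot <- do.call(cbind, lapply(priors$comps, function(cm) cm$A))
  Z <- crossprod(Atot, PX) * fac$w              # r_total x (K*T)
  J <- fac$G %*% Z
  array(as.matrix(J), c(priors$n_vertices, K, length(trials)))
}

# combined source-side factor and weights of the fitted prior:
# Q_J = Gc diag(wc) Gc' (physical scale up to the common factor that
# cancels in the estimator); used for CV sensor prediction
fitted_source_factor <- function(result, priors) {
  Gs <- lapply(priors$comps, function(cm) cm$G)
  ws <- lapply(seq_along(priors$comps), function(k) {
    rep(result$gamma[k], ncol(priors$comps[[k]]$A))
  })
  list(G = do.call(cbind, Gs), w = unlist(ws))
}

#' Predict held-out sensor data from a fitted inversion
#'
#' MAP prediction of the evoked (trial-averaged, preprocessed,
#' temporal-mode projected) data of sensors excluded from the fit:
#' `L_out Q_J L_in' Sigma^-1 Xbar`.
#'
#' @param result a `lam_inversion` fitted on the kept sensors.
#' @param priors the `lam_priors` used (built from the kept-sensor lead
#'   field).
#' @param reduced reduced data of the kept sensors.
#' @param L_out lead-field rows of the held-out sensors (matrix
#'   `n_out x n_vertices`).
#' @return matrix `n_out x K` of predicted evoked mode coefficients.
#' @export
predict_held_out <- function(result, priors, reduced, L_out) {
  PX <- result$P %*% reduced$Xbar               # evoked response, m x K
  fac <- fitted_source_factor(result, priors)
  LoG <- as.matrix(L_out %*% fac$G)             # n_out x r_total
  Atot <- do.call(cbind, lapply(priors$comps, function(cm) cm$A))
  Z <- crossprod(Atot, PX) * fac$w              # r_total x K
  LoG %*% Z                                     # n_out x K
}
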