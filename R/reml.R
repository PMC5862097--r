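# Restricted maximum likelihood over covariance-component hyperparameters.
#
# Model: reduced data samples x ~ N(0, Sigma), Sigma = sum_k exp(l_k) Q_k,
# with Q_1 the sensor identity and the remaining Q_k the projected source
# components. Hyperparameters live on the natural-log scale with Gaussian
# hyperpriors; Fisher scoring with step-halving makes the accepted
# free-energy sequence non-decreasing. The data second-moment matrix and
# every component are normalised to mean diagonal 1 before optimisation
# (recorded, undone where physical scales are needed); the free energy is
# reported including the hyperparameter complexity term, so differences
# between models fitted to the same data approximate log Bayes factors.

#' Optimize hyperparameters by ReML and return the free energy
#'
#' @param priors a `lam_priors` set.
#' @param reduced a `lam_reduced` dataset (same spatial projector the
#'   priors were built with).
#' @param hyper_mean,hyper_var Gaussian hyperprior mean and variance of
#'   each log hyperparameter.
#' @param tol convergence threshold on the accepted free-energy increase.
#' @param max_iter iteration cap (large component sets on wide mode spaces
#'   can need a few hundred scoring steps).
#' @return object of class `lam_inversion`: hyperparameters `lambda`,
#'   free energy `F`, convergence trace `F_trace`, posterior machinery and
#'   percent `variance_explained`.
#' @export
reml_optimize <- function(priors, reduced, hyper_mean = -5, hyper_var = 16,
                          tol = 0.01, max_iter = 512) {
  m <- reduced$n_spatial_modes
  stopifnot(nrow(priors$Lt) == m)
  n <- reduced$n_eff
  cs <- mean(diag(reduced$C))
  if (cs <= 0) abort("reduced data have zero energy")
  C <- reduced$C / cs

  # component list in the normalised space: first the sensor identity,
  # then the source components; rank-1 components kept as vectors
  scales <- vapply(priors$comps, function(x) x$scale, 1)
  is_r1 <- vapply(priors$comps, function(x) ncol(x$A) == 1L, TRUE)
  Qd <- list(diag(m))
  for (k in which(!is_r1)) {
    Qd <- c(Qd, list(tcrossprod(priors$comps[[k]]$A) / scales[k]))
  }
  Ar1 <- if (any(is_r1)) {
    A <- do.call(cbind, lapply(which(is_r1), function(k) priors$comps[[k]]$A))
    A * rep(sqrt(m) / sqrt(colSums(A^2)), each = m)  # columns to trace m
  } else NULL
  n_d <- length(Qd)
  n_r <- if (is.null(Ar1)) 0L else ncol(Ar1)
  K <- n_d + n_r
  prec <- 1 / hyper_var

  sigma_of <- function(E) {
    S <- matrix(0, m, m)
    for (i in seq_len(n_d)) S <- S + E[i] * Qd[[i]]
    if (n_r > 0) {
      S <- S + tcrossprod(Ar1 * rep(sqrt(E[n_d + seq_len(n_r)]), each = m))
    }
    S
  }
  f_of <- function(lambda) {
    E <- exp(pmin(pmax(lambda, -32), 32))
    S <- sigma_of(E)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(list(F = -Inf))
    logdet <- 2 * sum(log(diag(ch)))
    P <- chol2inv(ch)
    Fv <- -n / 2 * (logdet + sum(P * C) + m * log(2 * pi)) -
      0.5 * prec * sum((lambda - hyper_mean)^2)
    list(F = Fv, P = P, E = E)
  }

  lambda <- rep(-log(K), K)
  st <- f_of(lambda)
  if (!is.finite(st$F)) abort("non-finite free energy at initialisation")
  F_trace <- st$F
  converged <- FALSE
  info <- NULL

  for (iter in seq_len(max_iter)) {
    P <- st$P
    E <- st$E
    PC <- P %*% C
    g <- numeric(K)
    I <- matrix(0, K, K)
    PQd <- lapply(Qd, function(Q) P %*% Q)
    if (n_r > 0) {
      PA <- P %*% Ar1
      CPA <- C %*% PA
      Er <- E[n_d + seq_len(n_r)]
    }
    for (i in seq_len(n_d)) {
      t1 <- sum(diag(PQd[[i]]))
      t2 <- sum(PQd[[i]] * t(PC))
      g[i] <- -n / 2 * E[i] * (t1 - t2)
      for (j in i:n_d) {
        tij <- sum(PQd[[i]] * t(PQd[[j]]))
        I[i, j] <- I[j, i] <- n / 2 * E[i] * E[j] * tij
      }
      if (n_r > 0) {
        QdPA <- Qd[[i]] %*% PA
        tir <- colSums(PA * QdPA)
        idx <- n_d + seq_len(n_r)
        I[i, idx] <- I[idx, i] <- n / 2 * E[i] * Er * tir
      }
    }
    if (n_r > 0) {
      idx <- n_d + seq_len(n_r)
      t1r <- colSums(Ar1 * PA)
      t2r <- colSums(PA * CPA)
      g[idx] <- -n / 2 * Er * (t1r - t2r)
      APA <- crossprod(Ar1, PA)
      I[idx, idx] <- n / 2 * (outer(Er, Er) * APA^2)
    }
    g <- g - prec * (lambda - hyper_mean)
    I <- I + diag(prec, K)

    dl <- tryCatch(solve(I, g), error = function(e) NULL)
    if (is.null(dl)) {
      dl <- solve(I + diag(max(diag(I)) * 1e-8, K), g)
    }
    # cap the step to keep exp() well-behaved
    mx <- max(abs(dl))
    if (mx > 8) dl <- dl * (8 / mx)

    step <- 1
    accepted <- FALSE
    for (h in 1:16) {
      cand <- f_of(lambda + step * dl)
      if (is.finite(cand$F) && cand$F >= st$F - 1e-12) {
        lambda <- lambda + step * dl
        dF <- cand$F - st$F
        st <- cand
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    F_trace <- c(F_trace, st$F)
    info <- I
    if (!accepted || dF < tol || max(abs(step * dl)) < 1e-3) {
      converged <- TRUE
      break
    }
  }
  if (!is.finite(st$F)) {
    abort(paste0(
      "ReML produced a non-finite free energy; lambda trace: ",
      paste(sprintf("%.3f", lambda), collapse = ", ")
    ))
  }

  # hyperparameter complexity: + 1/2 log det(Pi * Cov_post)
  ch_i <- chol(info)
  logdet_cpost <- -2 * sum(log(diag(ch_i)))
  F_total <- st$F + 0.5 * (K * log(prec) + logdet_cpost)

  # map hyperparameters back to component order: sensor, then priors$comps
  lam_out <- numeric(1 + length(priors$comps))
  lam_out[1] <- lambda[1]
  lam_out[1 + which(!is_r1)] <- lambda[seq_len(n_d)][-1]
  if (n_r > 0) lam_out[1 + which(is_r1)] <- lambda[n_d + seq_len(n_r)]

  E_src <- exp(pmin(pmax(lam_out[-1], -32), 32))
  # multiplier of the unnormalised source factors G_k in the posterior
  # estimator M = sum_k gamma_k G_k A_k' P (the data-scale factor cancels)
  gamma <- E_src / scales

  res <- structure(
    list(
      scheme = priors$scheme,
      lambda = lam_out,
      F = F_total,
      F_trace = F_trace,
      converged = converged,
      P = st$P, E = st$E, C = C, cs = cs,
      n_eff = n, n_spatial_modes = m,
      gamma = gamma,
      sensor_noise_var = cs * st$E[1],
      variance_explained = NA_real_
    ),
    class = "lam_inversion"
  )
  res$variance_explained <- variance_explained(res, priors)
  res
}

#' @export
print.lam_inversion <- function(x, ...) {
  cat(sprintf(
    "<lam_inversion> %s: F = %.2f after %d step(s), %.1f%% variance explained\n",
    x$scheme, x$F, length(x$F_trace) - 1, x$variance_explained
  ))
  invisible(x)
}

#' Percent variance explained
#'
#' Goodness of fit without a complexity penalty: the percentage of reduced
#' data energy explained by the model's source-level prediction
#' (conditional expectation of the signal part).
#'
#' @param result a `lam_inversion`.
#' @param priors the `lam_priors` used for the fit.
#' @return percentage in `[0, 100]`.
#' @export
variance_explained <- function(result, priors) {
  m <- result$n_spatial_modes
  # projected source covariance in the normalised space
  S_src <- matrix(0, m, m)
  for (k in seq_along(priors$comps)) {
    S_src <- S_src + result$gamma[k] * tcrossprod(priors$comps[[k]]$A)
  }
  R <- diag(m) - S_src %*% result$P
  resid <- sum((R %*% result$C) * R)   # tr(R C R')
  100 * max(0, min(1, 1 - resid / sum(diag(result$C))))
}
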