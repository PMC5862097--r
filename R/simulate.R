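#' Simulation specification
#'
#' Parameters of one synthetic patch-source dataset. Defaults reproduce the
#' study conditions: a 20 Hz sinusoid of 10 nAm active from 100 to 500 ms
#' within a -500..+500 ms epoch sampled at 250 Hz (251 samples), patch FWHM
#' 5 mm, 515 trials.
#'
#' @param vertex_index centre vertex of the patch (index into the named
#'   surface).
#' @param surface_label `"pial"` or `"white"`.
#' @param frequency sinusoid frequency, Hz.
#' @param active_window two-element ms window of activity.
#' @param dipole_moment peak moment at the patch centre, nAm.
#' @param patch_fwhm patch dispersion FWHM, mm.
#' @param n_trials number of trials (>= 2).
#' @param sampling_rate Hz.
#' @param epoch two-element ms span of the epoch.
#' @param noise_mode `"target_snr_db"` or `"fixed_ft_rms"`.
#' @param noise_value target per-trial amplitude SNR in dB (may be `-Inf`
#'   for the noise-only control) or noise RMS in fT, by mode.
#' @param seed integer seed for the noise.
#' @return a `lam_sim_spec` list.
#' @export
simulation_spec <- function(vertex_index, surface_label = c("pial", "white"),
                            frequency = 20, active_window = c(100, 500),
                            dipole_moment = 10, patch_fwhm = 5,
                            n_trials = 515, sampling_rate = 250,
                            epoch = c(-500, 500),
                            noise_mode = c("target_snr_db", "fixed_ft_rms"),
                            noise_value = -20, seed = 0) {
  surface_label <- match.arg(surface_label)
  noise_mode <- match.arg(noise_mode)
  if (n_trials < 2) abort("n_trials must be at least 2")
  if (dipole_moment <= 0) abort("dipole_moment must be positive")
  if (active_window[1] < epoch[1] || active_window[2] > epoch[2]) {
    abort("active window must lie inside the epoch")
  }
  if (frequency >= sampling_rate / 2) {
    abort("frequency must be below the Nyquist rate")
  }
  structure(
    list(
      vertex_index = vertex_index, surface_label = surface_label,
      frequency = frequency, active_window = active_window,
      dipole_moment = dipole_moment, patch_fwhm = patch_fwhm,
      n_trials = n_trials, sampling_rate = sampling_rate, epoch = epoch,
      noise_mode = noise_mode, noise_value = noise_value, seed = seed
    ),
    class = "lam_sim_spec"
  )
}

# uniform time axis in ms for a spec
spec_time_axis <- function(spec) {
  step <- 1000 / spec$sampling_rate
  seq(spec$epoch[1], spec$epoch[2], by = step)
}

#' Source time course
#'
#' Sinusoid at the spec frequency, amplitude equal to the dipole moment,
#' nonzero only inside the active window (phase zero at window onset).
#'
#' @param spec a `lam_sim_spec`.
#' @return numeric waveform (nAm per sample) over the epoch.
#' @export
simulate_source_timecourse <- function(spec) {
  t_ms <- spec_time_axis(spec)
  w <- numeric(length(t_ms))
  act <- t_ms >= spec$active_window[1] & t_ms <= spec$active_window[2]
  w[act] <- spec$dipole_moment *
    sin(2 * pi * spec$frequency * (t_ms[act] - spec$active_window[1]) / 1000)
  w
}

#' Trial-structured sensor data
#'
#' Container for simulated (or measured) epoched MEG data: an
#' `n_trials x n_sensors x n_samples` array in fT with its time axis.
#'
#' @param data numeric array, trials x sensors x samples (fT).
#' @param time_ms time axis, ms.
#' @param sampling_rate Hz.
#' @param provenance list carrying the generating spec and seeds.
#' @export
trial_sensor_data <- function(data, time_ms, sampling_rate, provenance = list()) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(time_ms))
  if (!all(is.finite(data))) abort("sensor data must be finite")
  structure(
    list(data = data, time_ms = time_ms, sampling_rate = sampling_rate,
         provenance = provenance),
    class = "lam_trial_data"
  )
}

#' @export
print.lam_trial_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<lam_trial_data> %d trials x %d sensors x %d samples, %g Hz, %g..%g ms\n",
    d[1], d[2], d[3], x$sampling_rate, min(x$time_ms), max(x$time_ms)
  ))
  invisible(x)
}

#' Project a patch source to the sensors (noiseless)
#'
#' Sensor trials equal the lead field times the patch current distribution
#' times the source waveform; trials are identical before noise.
#'
#' @param spec a `lam_sim_spec`.
#' @param pair a `lam_surface_pair`.
#' @param L `lam_lead_field` of the surface named in the spec.
#' @param basis `lam_patch_basis` on that surface with
#'   `fwhm == spec$patch_fwhm` (must contain a column for the source
#'   vertex).
#' @return noiseless `lam_trial_data`.
#' @export
project_patch <- function(spec, pair, L, basis) {
  mesh <- pair[[spec$surface_label]]
  if (spec$vertex_index < 1 || spec$vertex_index > n_vertices(mesh)) {
    abort("source vertex is not on the named surface")
  }
  if (!is.null(basis$mesh_fingerprint) &&
      !identical(basis$mesh_fingerprint, mesh_fingerprint(mesh))) {
    abort("patch basis was built on a different mesh than the named surface")
  }
  if (abs(basis$fwhm - spec$patch_fwhm) > 1e-9) {
    abort("patch basis FWHM does not match the simulation spec")
  }
  q <- patch_column(basis, spec$vertex_index)
  topo <- as.vector(L$matrix %*% q)          # fT per nAm of centre moment
  w <- simulate_source_timecourse(spec)      # nAm
  one_trial <- tcrossprod(topo, w)           # sensors x samples, fT
  arr <- array(rep(one_trial, each = spec$n_trials),
               c(spec$n_trials, length(topo), length(w)))
  trial_sensor_data(arr, spec_time_axis(spec), spec$sampling_rate,
                    provenance = list(spec = spec))
}

# per-sensor RMS of the clean signal over the active window (trial 1;
# noiseless trials are identical)
active_window_rms <- function(clean) {
  spec <- clean$provenance$spec
  act <- clean$time_ms >= spec$active_window[1] &
    clean$time_ms <= spec$active_window[2]
  sqrt(rowMeans(clean$data[1, , act, drop = TRUE]^2))
}

#' Add Gaussian noise at a target per-trial amplitude SNR
#'
#' White Gaussian noise is added with a single scale chosen so that the
#' per-trial amplitude SNR - 20 log10(signal RMS / noise RMS) per sensor
#' over the active window, averaged across sensors - equals the target.
#' Sensors whose clean signal RMS is exactly zero are excluded from the
#' average. `target_snr_db = -Inf` produces the noise-only control: the
#' signal is replaced by zeros and the noise is kept at the scale a 0 dB
#' target would give.
#'
#' @param clean noiseless `lam_trial_data` (from [project_patch()]).
#' @param target_snr_db target SNR in dB (or `-Inf`).
#' @param seed integer noise seed.
#' @return noisy `lam_trial_data`.
#' @export
add_noise_snr <- function(clean, target_snr_db, seed = 0) {
  rms_s <- active_window_rms(clean)
  rms_s <- rms_s[rms_s > 0]
  if (!length(rms_s)) abort("clean data are all zero; SNR target is undefined")
  target <- if (is.infinite(target_snr_db) && target_snr_db < 0) 0 else target_snr_db
  # mean over sensors of 20 log10(rms_s / sigma) = target
  sigma <- 10^(mean(log10(rms_s)) - target / 20)
  noise <- withr::with_seed(seed, {
    rnorm(length(clean$data), sd = sigma)
  })
  out <- clean
  if (is.infinite(target_snr_db) && target_snr_db < 0) {
    out$data <- array(noise, dim(clean$data))
  } else {
    out$data <- clean$data + noise
  }
  out$provenance$noise <- list(mode = "target_snr_db", target = target_snr_db,
                               sigma = sigma, seed = seed)
  out
}

#' Add Gaussian noise of fixed RMS
#'
#' Adds i.i.d. Gaussian noise with the stated per-sensor-sample RMS (fT),
#' leaving the signal untouched. `noise_rms = 0` returns the input.
#'
#' @param clean a `lam_trial_data`.
#' @param noise_rms noise standard deviation, fT.
#' @param seed integer noise seed.
#' @export
add_noise_fixed <- function(clean, noise_rms, seed = 0) {
  if (noise_rms < 0) abort("noise_rms must be non-negative")
  if (noise_rms == 0) return(clean)
  noise <- withr::with_seed(seed, {
    rnorm(length(clean$data), sd = noise_rms)
  })
  out <- clean
  out$data <- clean$data + noise
  out$provenance$noise <- list(mode = "fixed_ft_rms", noise_rms = noise_rms,
                               seed = seed)
  out
}

#' Realized per-trial amplitude SNR
#'
#' Measures 20 log10(signal RMS / noise RMS) per sensor and trial over the
#' active window, averaged over sensors and trials, given the clean and
#' noisy datasets.
#'
#' @param clean,noisy matching `lam_trial_data` objects.
#' @return realized SNR, dB.
#' @export
realized_snr_db <- function(clean, noisy) {
  spec <- clean$provenance$spec
  act <- clean$time_ms >= spec$active_window[1] &
    clean$time_ms <= spec$active_window[2]
  sig <- clean$data[, , act, drop = FALSE]
  noi <- noisy$data[, , act, drop = FALSE] - sig
  rms_s <- sqrt(apply(sig^2, c(1, 2), mean))
  rms_n <- sqrt(apply(noi^2, c(1, 2), mean))
  keep <- rms_s > 0
  mean(20 * log10(rms_s[keep] / rms_n[keep]))
}

#' Trial data container I/O
#'
#' Persists a `lam_trial_data` as an RDS payload plus a JSON side-car
#' manifest (spec, seed, units, fingerprints).
#'
#' @param x a `lam_trial_data`.
#' @param path payload path (`.rds`); the manifest is `<path>.json`.
#' @export
write_trial_data <- function(x, path) {
  saveRDS(x, path)
  jsonlite::write_json(
    list(
      class = "lam_trial_data", units = "fT",
      n_trials = dim(x$data)[1], n_sensors = dim(x$data)[2],
      n_samples = dim(x$data)[3], sampling_rate = x$sampling_rate,
      spec = if (!is.null(x$provenance$spec)) unclass(x$provenance$spec),
      noise = x$provenance$noise
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "lam_trial_data")) abort("not a trial data container")
  x
}

#' Interface for user-supplied noise epochs
#'
#' Loader stub for structured (e.g. resting-state) noise: accepts epoched
#' noise with the same sensor count and epoch geometry as a simulation and
#' returns it as a `lam_trial_data` suitable for adding to projected
#' signal. Generation of realistic correlated noise is out of scope.
#'
#' @param data trials x sensors x samples array of noise (fT).
#' @param time_ms epoch time axis, ms.
#' @param sampling_rate Hz.
#' @export
load_noise_epochs <- function(data, time_ms, sampling_rate) {
  trial_sensor_data(data, time_ms, sampling_rate,
                    provenance = list(kind = "user_noise"))
}
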