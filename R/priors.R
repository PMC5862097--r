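#' Covariance prior components for source inversion
#'
#' Builds the sensor-level and source-level covariance components of one of
#' the four empirical-Bayes schemes:
#' \describe{
#'   \item{IID}{minimum norm: a single identity source component.}
#'   \item{COH}{locally coherent (LORETA-like): one component `G G'` built
#'     from the patch basis `G`.}
#'   \item{EBB}{empirical Bayes beamformer: one locally coherent component
#'     `G diag(v) G'` whose per-patch variance `v` is the unit-gain
#'     beamformer power estimate computed from the reduced data
#'     covariance.}
#'   \item{MSP}{multiple sparse priors: one rank-one component per patch
#'     (outer product of its patch-basis column); the patch set is the
#'     candidate centres plus `n_random_patches` random vertices.}
#' }
#' The sensor-level component is the identity for every scheme. Each source
#' component is stored both as a source-side factor (for posterior
#' estimation and sensor prediction) and in the projected spatial-mode
#' space (for ReML).
#'
#' @param scheme `"IID"`, `"COH"`, `"EBB"` or `"MSP"`.
#' @param mesh the source-space `lam_mesh`.
#' @param basis `lam_patch_basis` on `mesh` at the reconstruction FWHM
#'   (with columns for all vertices).
#' @param L `lam_lead_field` of `mesh`.
#' @param reduced `lam_reduced` data (needed by EBB; used for the spatial
#'   projector by all schemes).
#' @param patch_centers integer vertex indices of the MSP patch candidates.
#' @param n_random_patches extra random MSP patches (drawn seeded from the
#'   vertices not already in `patch_centers`).
#' @param seed seed for the random patches.
#' @return object of class `lam_priors`.
#' @export
build_priors <- function(scheme = c("IID", "COH", "EBB", "MSP"),
                         mesh, basis, L, reduced,
                         patch_centers = NULL, n_random_patches = 0,
                         seed = 0) {
  scheme <- match.arg(scheme)
  N <- n_vertices(mesh)
  Lm <- if (inherits(L, "lam_lead_field")) L$matrix else L
  stopifnot(ncol(Lm) == N)
  Lt <- crossprod(reduced$U, Lm)                # m x N reduced lead field
  m <- nrow(Lt)

  comp <- function(G, A, label) {
    sc <- sum(A * A) / m                        # trace of A A' over m
    if (sc <= 0) abort(sprintf("degenerate source component (%s)", label))
    list(G = G, A = A, scale = sc, label = label)
  }

  comps <- switch(
    scheme,
    IID = {
      list(comp(Diagonal(N), Lt, "iid"))
    },
    COH = {
      G <- basis$basis
      stopifnot(ncol(G) == N)
      list(comp(G, as.matrix(Lt %*% G), "coh"))
    },
    EBB = {
      G <- basis$basis
      stopifnot(ncol(G) == N)
      A0 <- as.matrix(Lt %*% G)
      Creg <- reduced$C + diag(1e-6 * mean(diag(reduced$C)), m)
      Ci <- chol2inv(chol(Creg))
      v <- 1 / pmax(colSums(A0 * (Ci %*% A0)), 1e-300)
      v <- v / max(v)
      cmp <- comp(G %*% Diagonal(x = sqrt(v)), A0 * rep(sqrt(v), each = m),
                  "ebb")
      cmp$beamformer_variance <- v
      cmp$regularization <- 1e-6 * mean(diag(reduced$C))
      list(cmp)
    },
    MSP = {
      if (is.null(patch_centers)) abort("MSP requires patch_centers")
      centers <- as.integer(patch_centers)
      if (n_random_patches > 0) {
        pool <- setdiff(seq_len(N), centers)
        extra <- withr::with_seed(seed, sample(pool, n_random_patches))
        centers <- c(centers, extra)
      }
      lapply(centers, function(cv) {
        q <- basis$basis[, cv, drop = FALSE]    # sparse N x 1
        comp(q, as.matrix(Lt %*% q), sprintf("patch_v%d", cv))
      })
    }
  )

  structure(
    list(
      scheme = scheme,
      sensor = list(label = "sensor_identity"),
      comps = comps,
      Lt = Lt,
      patch_centers = if (scheme == "MSP") {
        vapply(comps, function(x) as.integer(sub("patch_v", "", x$label)), 1L)
      } else NULL,
      mesh_fingerprint = mesh_fingerprint(mesh),
      n_vertices = N
    ),
    class = "lam_priors"
  )
}

#' @export
print.lam_priors <- function(x, ...) {
  cat(sprintf(
    "<lam_priors> scheme %s: sensor identity + %d source component(s)\n",
    x$scheme, length(x$comps)
  ))
  invisible(x)
}
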