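#' Synthetic MEG sensor array
#'
#' Quasi-uniform (Fibonacci lattice) point magnetometers on a spherical cap
#' of the helmet sphere, sensing along the local radial axis. A synthetic
#' stand-in for a whole-head axial array.
#'
#' @param n_sensors number of channels (32 or more).
#' @param helmet_radius sensor sphere radius, mm.
#' @param coverage fraction of the full sphere covered by the cap (0, 1],
#'   measured from the +z pole downward.
#' @param center helmet sphere centre, mm.
#' @param jitter angular jitter (radians RMS) applied to the lattice; 0 for
#'   a deterministic array.
#' @param seed seed for the jitter.
#' @return object of class `lam_sensor_array` with `names`, `positions`
#'   (n x 3, mm) and `orientations` (n x 3 unit vectors).
#' @export
generate_sensor_array <- function(n_sensors = 160, helmet_radius = 110,
                                  coverage = 0.5, center = c(0, 0, 0),
                                  jitter = 0, seed = 0) {
  if (n_sensors < 32) abort("n_sensors must be at least 32")
  if (coverage <= 0 || coverage > 1) abort("coverage must be in (0, 1]")
  i <- seq_len(n_sensors) - 0.5
  # z in [1 - 2*coverage, 1]: equal-area cap sampling
  z <- 1 - 2 * coverage * i / n_sensors
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n_sensors) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(r * cos(th), r * sin(th), z)
  if (jitter > 0) {
    withr::with_seed(seed, {
      u <- u + matrix(rnorm(3 * n_sensors, sd = jitter), n_sensors, 3)
    })
    u <- u / sqrt(rowSums(u^2))
  }
  structure(
    list(
      names = sprintf("MEG%03d", seq_len(n_sensors)),
      positions = sweep(u * helmet_radius, 2, center, "+"),
      orientations = u,
      helmet_radius = helmet_radius,
      center = center
    ),
    class = "lam_sensor_array"
  )
}

#' @export
print.lam_sensor_array <- function(x, ...) {
  cat(sprintf(
    "<lam_sensor_array> %d radial magnetometers, helmet radius %.0f mm\n",
    length(x$names), x$helmet_radius
  ))
  invisible(x)
}

#' Sensor array JSON I/O
#' @param sensors a `lam_sensor_array`.
#' @param path JSON file path.
#' @export
write_sensor_array <- function(sensors, path) {
  jsonlite::write_json(
    list(channels = purrr::pmap(
      list(
        sensors$names,
        asplit(sensors$positions, 1),
        asplit(sensors$orientations, 1)
      ),
      function(nm, p, o) list(name = nm, position = as.numeric(p),
                              orientation = as.numeric(o))
    )),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_sensor_array
#' @export
read_sensor_array <- function(path) {
  ch <- jsonlite::read_json(path)$channels
  structure(
    list(
      names = vapply(ch, function(x) x$name, ""),
      positions = do.call(rbind, lapply(ch, function(x) unlist(x$position))),
      orientations = do.call(rbind, lapply(ch, function(x) unlist(x$orientation))),
      helmet_radius = NA_real_, center = c(0, 0, 0)
    ),
    class = "lam_sensor_array"
  )
}

#' Spherical conductor model
#'
#' Homogeneous conducting sphere; its external magnetic field for a current
#' dipole has a closed form, and purely radial dipoles are magnetically
#' silent.
#'
#' @param center sphere centre, mm.
#' @param radius sphere radius, mm; all sources must lie strictly inside
#'   (the external field of the homogeneous sphere does not depend on the
#'   radius itself, only on the centre).
#' @export
conductor_model <- function(center = c(0, 0, 0), radius = 95) {
  structure(list(kind = "sphere", center = center, radius = radius),
            class = "lam_conductor")
}

#' Lead field of a surface mesh
#'
#' Gain matrix (sensors x vertices) mapping a unit dipole (1 nAm) at each
#' vertex, oriented along the vertex surface normal, to the field (fT)
#' sensed by each channel: the closed-form field of a current dipole in a
#' homogeneous conducting sphere, projected onto each sensor's sensing
#' axis.
#'
#' @param mesh a `lam_mesh` source space (dipoles at vertices, oriented
#'   along `mesh$normals`).
#' @param sensors a `lam_sensor_array`.
#' @param conductor a `lam_conductor` (sphere).
#' @return object of class `lam_lead_field`: `matrix` (n_sensors x
#'   n_vertices, fT/nAm), `orientations`, and mesh/sensor fingerprints.
#' @export
compute_lead_field <- function(mesh, sensors, conductor) {
  pos <- sweep(mesh$vertices, 2, conductor$center)
  rad <- sqrt(rowSums(pos^2))
  if (any(rad >= conductor$radius)) {
    abort("all source vertices must lie strictly inside the conductor sphere")
  }
  if (any(rad < 1e-9)) {
    abort("source at the sphere centre has no defined tangential frame")
  }
  sens <- sweep(sensors$positions, 2, conductor$center)
  L <- dipole_sphere_field(pos, mesh$normals, sens, sensors$orientations)
  structure(
    list(
      matrix = L,
      orientations = mesh$normals,
      mesh_fingerprint = mesh_fingerprint(mesh),
      n_sensors = nrow(sens)
    ),
    class = "lam_lead_field"
  )
}

#' @export
print.lam_lead_field <- function(x, ...) {
  cat(sprintf("<lam_lead_field> %d sensors x %d vertices (fT/nAm)\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# Field of current dipoles in a homogeneous conducting sphere centred at the
# origin (closed form). src: n x 3 (mm), q_dir: n x 3 unit moments,
# sens: s x 3 (mm), s_ori: s x 3 unit sensing axes.
# Returns s x n matrix in fT per nAm. Vectorised over source-sensor pairs.
dipole_sphere_field <- function(src, q_dir, sens, s_ori) {
  ns <- nrow(sens)
  nq <- nrow(src)
  mm <- .lam_const$mm
  # all pairs: index p = (sensor varies fastest)
  r <- sens[rep(seq_len(ns), nq), , drop = FALSE] * mm      # sensor pos (m)
  r0 <- src[rep(seq_len(nq), each = ns), , drop = FALSE] * mm
  q <- q_dir[rep(seq_len(nq), each = ns), , drop = FALSE] * .lam_const$nAm
  o <- s_ori[rep(seq_len(ns), nq), , drop = FALSE]

  a_vec <- r - r0
  a <- sqrt(rowSums(a_vec^2))
  rr <- sqrt(rowSums(r^2))
  adotr <- rowSums(a_vec * r)
  r0dotr <- rowSums(r0 * r)
  F <- a * (rr * a + rr^2 - r0dotr)
  cF <- a^2 / rr + adotr / a + 2 * a + 2 * rr
  cF0 <- a + 2 * rr + adotr / a
  gradF <- r * cF - r0 * cF0
  qxr0 <- cbind(
    q[, 2] * r0[, 3] - q[, 3] * r0[, 2],
    q[, 3] * r0[, 1] - q[, 1] * r0[, 3],
    q[, 1] * r0[, 2] - q[, 2] * r0[, 1]
  )
  qxr0_dot_r <- rowSums(qxr0 * r)
  B <- (.lam_const$mu0_over_4pi / F^2) * (F * qxr0 - qxr0_dot_r * gradF)
  val <- rowSums(B * o) * .lam_const$fT
  matrix(val, ns, nq)
}

#' Lead-field root-mean-square per vertex
#'
#' RMS over sensors of each lead-field column; the per-vertex forward gain
#' used in the anatomy analyses.
#'
#' @param L a `lam_lead_field` or a plain gain matrix.
#' @return numeric vector, fT/nAm per vertex.
#' @export
lead_field_rms <- function(L) {
  M <- if (inherits(L, "lam_lead_field")) L$matrix else L
  sqrt(colMeans(M^2))
}
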