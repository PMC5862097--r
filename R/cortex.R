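#' Linked two-layer cortical surface pair
#'
#' The anatomical hypothesis space: a pial (superficial) and a white-matter
#' (deep) triangle mesh with identical face topology and one-to-one vertex
#' linkage (vertex i on the pial surface is linked to vertex i on the white
#' surface).
#'
#' @param pial,white `lam_mesh` objects with equal vertex counts and
#'   identical faces.
#' @return object of class `lam_surface_pair`.
#' @export
linked_surface_pair <- function(pial, white) {
  if (n_vertices(pial) != n_vertices(white)) {
    abort("pial and white meshes must have the same vertex count")
  }
  if (!identical(pial$faces, white$faces)) {
    abort("linked surfaces must share face topology")
  }
  d <- sqrt(rowSums((pial$vertices - white$vertices)^2))
  if (any(d <= 0)) abort("linked-vertex distance must be positive everywhere")
  structure(list(pial = pial, white = white), class = "lam_surface_pair")
}

#' @export
print.lam_surface_pair <- function(x, ...) {
  cat(sprintf(
    "<lam_surface_pair> %d linked vertices per surface (%s)\n",
    n_vertices(x$pial), if (x$pial$open) "open sheets" else "closed"
  ))
  invisible(x)
}

#' Synthetic folded two-layer cortex
#'
#' Generates a linked pial/white surface pair emulating a folded cortical
#' sheet: an icosahedral sphere whose radius is modulated by a band-limited
#' random field (the folds), with the white surface offset inward from the
#' pial surface along the pial vertex normals by the local cortical
#' thickness. Folds produce both gyral (convex, positive curvature) and
#' sulcal (concave, negative curvature) vertices, and sulcal depth,
#' curvature and lead-field strength all vary over the sheet.
#'
#' Defaults give a desk-scale head: pial base radius 70 mm, folds of 8 mm
#' amplitude and 30 mm wavelength, spatially varying thickness within
#' 2-4 mm.
#'
#' @param n_vertices minimum vertices per surface (icosahedral ladder; 100
#'   or more).
#' @param fold_amplitude fold depth scale, mm (0 gives the unfolded sphere).
#' @param fold_wavelength characteristic fold wavelength, mm.
#' @param thickness_profile either a single positive thickness (mm), a
#'   per-vertex vector, or `NULL` for the default random 2-4 mm field.
#' @param base_radius radius of the unfolded pial sphere, mm.
#' @param seed integer seed for the fold and thickness fields.
#' @return a `lam_surface_pair`.
#' @export
generate_synthetic_cortex <- function(n_vertices = 2562,
                                      fold_amplitude = 8,
                                      fold_wavelength = 30,
                                      thickness_profile = NULL,
                                      base_radius = 70,
                                      seed = 0) {
  stopifnot(n_vertices >= 100)
  base <- icosphere(n_vertices, radius = 1)
  v <- base$vertices  # unit directions
  n <- nrow(v)

  withr::with_seed(seed, {
    disp <- if (fold_amplitude > 0) {
      f <- random_band_field(v * base_radius, fold_wavelength)
      fold_amplitude * f / 2
    } else {
      numeric(n)
    }
    thick <- if (is.null(thickness_profile)) {
      # smooth random field squashed into the 2-4 mm cortical range
      t0 <- random_band_field(v * base_radius, 2.5 * fold_wavelength)
      3 + 0.8 * tanh(t0)
    } else if (length(thickness_profile) == 1L) {
      rep(thickness_profile, n)
    } else {
      thickness_profile
    }
  })
  if (any(thick <= 0)) abort("thickness_profile must be positive")

  pial_v <- v * (base_radius + disp)
  pial <- lam_mesh(pial_v, base$faces, open = FALSE)
  white_v <- pial_v - pial$normals * thick
  white <- lam_mesh(white_v, base$faces, open = FALSE)

  # reject self-intersecting offsets: inward offset must stay below the
  # local radius of curvature, and white faces must keep outward orientation
  h <- compute_mean_curvature(pial)
  bad <- is.finite(h) & (thick * pmax(h, 0) > 0.9)
  if (any(bad)) {
    abort(sprintf(
      "offset surface self-intersects at %d vertex/vertices (thickness exceeds local radius of curvature); reduce fold_amplitude or thickness",
      sum(bad)
    ))
  }
  if (any(rowSums(face_normals(white_v, base$faces) *
                    face_normals(pial_v, base$faces)) < 0)) {
    abort("offset surface self-intersects (flipped faces)")
  }
  linked_surface_pair(pial, white)
}

# band-limited random field: superposition of random plane waves with
# |k| = 2 pi / wavelength, normalised to unit standard deviation
random_band_field <- function(pos, wavelength, n_waves = 24) {
  k <- 2 * pi / wavelength
  dirs <- matrix(rnorm(3 * n_waves), n_waves, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  phase <- runif(n_waves, 0, 2 * pi)
  f <- cos(pos %*% t(dirs) * k + rep(phase, each = nrow(pos))) %*%
    rep(1 / sqrt(n_waves), n_waves)
  as.vector(f) / max(sd(f), 1e-12)
}

#' Cortical thickness
#'
#' Euclidean distance between linked pial/white vertices, Gaussian-smoothed
#' along the surface.
#'
#' @param pair a `lam_surface_pair`.
#' @param smoothing_fwhm smoothing kernel FWHM in mm (default 8); 0 skips
#'   smoothing.
#' @param surface which surface's geometry the smoothing runs on.
#' @return per-vertex thickness, mm.
#' @export
compute_thickness <- function(pair, smoothing_fwhm = 8,
                              surface = c("pial", "white")) {
  surface <- match.arg(surface)
  d <- sqrt(rowSums((pair$pial$vertices - pair$white$vertices)^2))
  if (any(d == 0)) abort("degenerate linkage: zero distance between linked vertices")
  if (smoothing_fwhm > 0) {
    d <- smooth_field(pair[[surface]], d, smoothing_fwhm)
  }
  d
}

#' Combine the two surfaces into one source space
#'
#' Stacks white and pial meshes into a single mesh of 2N vertices. Index
#' convention: white-matter vertices come first (1..N), pial vertices second
#' (N+1..2N), so combined vertices i and i+N form a linked pair. The
#' surface of origin is retained in the `surface` attribute.
#'
#' @param pair a `lam_surface_pair`.
#' @return a `lam_mesh` with 2N vertices and a per-vertex `surface` label
#'   field (`"white"` / `"pial"`).
#' @export
combine_surfaces <- function(pair) {
  nw <- n_vertices(pair$white)
  m <- lam_mesh(
    rbind(pair$white$vertices, pair$pial$vertices),
    rbind(pair$white$faces, pair$pial$faces + nw),
    open = pair$white$open
  )
  m$surface <- rep(c("white", "pial"), each = nw)
  m
}

#' Per-vertex anatomical statistics of a linked pair
#'
#' Thickness, signed mean curvature, sulcal depth (hull built from the pial
#' surface) and, when a lead field is supplied, lead-field RMS - for both
#' surfaces.
#'
#' @param pair a `lam_surface_pair`.
#' @param lead_fields optional named list with `pial` and `white`
#'   [lam_lead_field] objects.
#' @param smoothing_fwhm thickness smoothing FWHM, mm.
#' @return tibble with columns `vertex_index`, `surface`, `thickness_mm`,
#'   `curvature_per_mm`, `sulcal_depth_mm` and `leadfield_rms`.
#' @export
surface_statistics <- function(pair, lead_fields = NULL, smoothing_fwhm = 8) {
  n <- n_vertices(pair$pial)
  hull_mesh <- pair$pial
  tib <- function(surf) {
    mesh <- pair[[surf]]
    tibble(
      vertex_index = seq_len(n),
      surface = surf,
      thickness_mm = compute_thickness(pair, smoothing_fwhm, surface = surf),
      curvature_per_mm = compute_mean_curvature(mesh),
      sulcal_depth_mm = compute_sulcal_depth(mesh, hull_mesh = hull_mesh),
      leadfield_rms = if (!is.null(lead_fields)) {
        lead_field_rms(lead_fields[[surf]])
      } else {
        NA_real_
      }
    )
  }
  bind_rows(tib("white"), tib("pial"))
}

#' Write / read linked surface pairs
#'
#' The two meshes are written in the chosen format with a JSON side-car
#' recording the linkage (vertex count equality is asserted on load).
#'
#' @param pair a `lam_surface_pair`.
#' @param stem path stem: files `<stem>.pial.gii`, `<stem>.white.gii` and
#'   `<stem>.link.json` are produced (or `.obj` when `format = "obj"`).
#' @param format `"gii"` or `"obj"`.
#' @export
write_surface_pair <- function(pair, stem, format = c("gii", "obj")) {
  format <- match.arg(format)
  pf <- sprintf("%s.pial.%s", stem, format)
  wf <- sprintf("%s.white.%s", stem, format)
  write_mesh(pair$pial, pf)
  write_mesh(pair$white, wf)
  jsonlite::write_json(
    list(
      pial = basename(pf), white = basename(wf),
      n_vertices = n_vertices(pair$pial), linkage = "index"
    ),
    sprintf("%s.link.json", stem),
    auto_unbox = TRUE
  )
  invisible(stem)
}

#' @rdname write_surface_pair
#' @export
read_surface_pair <- function(stem, format = c("gii", "obj")) {
  format <- match.arg(format)
  side <- jsonlite::read_json(sprintf("%s.link.json", stem))
  pial <- read_mesh(file.path(dirname(stem), side$pial))
  white <- read_mesh(file.path(dirname(stem), side$white))
  if (n_vertices(pial) != side$n_vertices) {
    abort("side-car vertex count does not match the pial mesh")
  }
  linked_surface_pair(pial, white)
}
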