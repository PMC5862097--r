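#' Anatomy context: surfaces, sensors, lead fields and patch bases
#'
#' Bundles a linked surface pair with a sensor array and conductor model,
#' caching the per-surface and combined-mesh lead fields and the patch
#' bases per FWHM so repeated analyses do not recompute them.
#'
#' @param pair a `lam_surface_pair`.
#' @param sensors a `lam_sensor_array`.
#' @param conductor a `lam_conductor`.
#' @return object of class `lam_context`.
#' @export
laminar_context <- function(pair, sensors, conductor) {
  ctx <- new.env(parent = emptyenv())
  ctx$pair <- pair
  ctx$sensors <- sensors
  ctx$conductor <- conductor
  ctx$combined <- combine_surfaces(pair)
  ctx$leadfields <- list()
  ctx$bases <- list()
  ctx$graphs <- list()
  class(ctx) <- "lam_context"
  ctx
}

#' @export
print.lam_context <- function(x, ...) {
  cat(sprintf(
    "<lam_context> %d vertices/surface, %d sensors\n",
    n_vertices(x$pair$pial), length(x$sensors$names)
  ))
  invisible(x)
}

context_mesh <- function(ctx, surface = c("pial", "white", "combined")) {
  surface <- match.arg(surface)
  if (surface == "combined") ctx$combined else ctx$pair[[surface]]
}

context_leadfield <- function(ctx, surface) {
  lf <- ctx$leadfields[[surface]]
  if (is.null(lf)) {
    lf <- compute_lead_field(context_mesh(ctx, surface), ctx$sensors,
                             ctx$conductor)
    ctx$leadfields[[surface]] <- lf
  }
  lf
}

context_graph <- function(ctx, surface) {
  g <- ctx$graphs[[surface]]
  if (is.null(g)) {
    g <- mesh_graph(context_mesh(ctx, surface))
    ctx$graphs[[surface]] <- g
  }
  g
}

context_basis <- function(ctx, surface, fwhm) {
  key <- sprintf("%s_%g", surface, fwhm)
  b <- ctx$bases[[key]]
  if (is.null(b)) {
    b <- suppressWarnings(compute_patch_basis(
      context_mesh(ctx, surface), fwhm, graph = context_graph(ctx, surface)
    ))
    ctx$bases[[key]] <- b
  }
  b
}

# cached spatial modes of the canonical stacked lead field
context_stacked_modes <- function(ctx, energy = 0.9999) {
  key <- sprintf("stacked_%g", energy)
  u <- ctx$bases[[key]]
  if (is.null(u)) {
    u <- spatial_modes(canonical_stacked_leadfield(ctx), energy)
    ctx$bases[[key]] <- u
  }
  u
}

# column-stacked lead field of both surfaces in a content-canonical order,
# so that swapping the pair's surface labels yields the identical matrix
# (and hence bit-identical spatial modes)
canonical_stacked_leadfield <- function(ctx) {
  Lw <- context_leadfield(ctx, "white")$matrix
  Lp <- context_leadfield(ctx, "pial")$matrix
  sw <- sum(Lw)
  sp <- sum(Lp)
  if (sw < sp || (sw == sp && sum(abs(Lw)) <= sum(abs(Lp)))) {
    cbind(Lw, Lp)
  } else {
    cbind(Lp, Lw)
  }
}
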