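#' Discrete mean curvature
#'
#' Mean of the two principal curvatures at each vertex, computed from the
#' cotangent-weighted Laplacian of the embedding (mean-curvature normal).
#' Sign convention: convex-outward regions (gyral crowns, spheres seen from
#' outside) are positive; concave (sulcal fundi) negative. On open sheets
#' the boundary ring has no well-defined curvature and is returned as `NA`
#' (flagged via the mesh's `boundary` field).
#'
#' @param mesh a `lam_mesh` (manifold).
#' @return numeric vector, 1/mm per vertex; `NA` on boundary vertices.
#' @export
compute_mean_curvature <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)

  # cotangents at each face corner
  cot_at <- function(a, b, c) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dotp <- rowSums(u * w)
    cr <- cbind(
      u[, 2] * w[, 3] - u[, 3] * w[, 2],
      u[, 3] * w[, 1] - u[, 1] * w[, 3],
      u[, 1] * w[, 2] - u[, 2] * w[, 1]
    )
    dotp / sqrt(pmax(rowSums(cr^2), 1e-300))
  }
  c1 <- cot_at(f[, 1], f[, 2], f[, 3])  # angle at v1, opposite edge (2,3)
  c2 <- cot_at(f[, 2], f[, 3], f[, 1])
  c3 <- cot_at(f[, 3], f[, 1], f[, 2])

  ii <- c(f[, 2], f[, 3], f[, 3], f[, 1], f[, 1], f[, 2])
  jj <- c(f[, 3], f[, 2], f[, 1], f[, 3], f[, 2], f[, 1])
  ww <- 0.5 * c(c1, c1, c2, c2, c3, c3)
  W <- sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  lap <- as.matrix(W %*% v) - as.vector(W %*% rep(1, n)) * v  # sum w_ij (p_j - p_i)

  amix <- mixed_voronoi_area(v, f, n)
  kvec <- lap / (2 * amix)              # mean-curvature normal, magnitude H
  h <- sqrt(rowSums(kvec^2))
  # sign: K points inward (-n) on convex-outward surfaces
  h <- h * ifelse(rowSums(kvec * mesh$normals) <= 0, 1, -1)
  if (any(mesh$boundary)) h[mesh$boundary] <- NA_real_
  h
}

# Meyer et al. mixed Voronoi cell areas: the Voronoi area for non-obtuse
# triangles, area/2 at the obtuse corner and area/4 elsewhere otherwise.
mixed_voronoi_area <- function(v, f, n) {
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e23 <- rowSums((p2 - p3)^2)  # squared edge opposite vertex 1
  e13 <- rowSums((p1 - p3)^2)
  e12 <- rowSums((p1 - p2)^2)
  area <- face_areas(v, f)
  cot1 <- (e12 + e13 - e23) / (4 * area)
  cot2 <- (e12 + e23 - e13) / (4 * area)
  cot3 <- (e13 + e23 - e12) / (4 * area)
  ob1 <- cot1 < 0
  ob2 <- cot2 < 0
  ob3 <- cot3 < 0
  any_ob <- ob1 | ob2 | ob3
  # Voronoi contribution of each corner for non-obtuse faces
  a1 <- (e12 * cot3 + e13 * cot2) / 8
  a2 <- (e12 * cot3 + e23 * cot1) / 8
  a3 <- (e13 * cot2 + e23 * cot1) / 8
  a1[any_ob] <- ifelse(ob1[any_ob], area[any_ob] / 2, area[any_ob] / 4)
  a2[any_ob] <- ifelse(ob2[any_ob], area[any_ob] / 2, area[any_ob] / 4)
  a3[any_ob] <- ifelse(ob3[any_ob], area[any_ob] / 2, area[any_ob] / 4)
  tapply_add(f[, 1], a1, n) + tapply_add(f[, 2], a2, n) +
    tapply_add(f[, 3], a3, n)
}
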