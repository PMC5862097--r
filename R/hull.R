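# 3-D convex hull (quickhull-style incremental insertion).
# No installed package provides a 3-D hull, and sulcal depth needs one.

#' Convex hull of a 3-D point set
#'
#' Incremental (quickhull-style) convex hull. Returns the hull triangulation
#' and the set of input points lying on the hull surface within tolerance.
#'
#' @param pts numeric n x 3 matrix.
#' @param tol points closer than `tol` (mm) to a hull face plane are counted
#'   as lying on the hull surface.
#' @return list with `faces` (m x 3 indices into `pts`, outward CCW),
#'   `normals`, `offsets` (plane n.x = d), `on_hull` (logical per input
#'   point) and `dist_to_hull` (non-negative distance from each point to the
#'   hull boundary).
#' @export
convex_hull3 <- function(pts, tol = NULL) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4) abort("convex hull needs at least 4 points")
  scale <- max(apply(pts, 2, function(x) diff(range(x))))
  if (is.null(tol)) tol <- 1e-6 * scale
  eps <- 1e-9 * scale

  # --- initial simplex: extremes, then farthest from line, then from plane
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) abort("degenerate point set")
  d12 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(
    rel[, 2] * d12[3] - rel[, 3] * d12[2],
    rel[, 3] * d12[1] - rel[, 1] * d12[3],
    rel[, 1] * d12[2] - rel[, 2] * d12[1]
  )
  i3 <- which.max(rowSums(cr^2))
  nrm <- vcross(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  h <- abs(rel %*% nrm)
  i4 <- which.max(h)
  if (h[i4] < eps) abort("point set is coplanar; hull undefined")
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])

  max_faces <- 8L * n + 16L
  fv <- matrix(NA_integer_, max_faces, 3)
  fn <- matrix(NA_real_, max_faces, 3)
  foff <- rep(NA_real_, max_faces)
  alive <- logical(max_faces)
  outside <- vector("list", max_faces)
  nf <- 0L

  orient_face <- function(tri) {
    nrm <- vcross(pts[tri[2], ] - pts[tri[1], ], pts[tri[3], ] - pts[tri[1], ])
    ln <- sqrt(sum(nrm^2))
    if (ln < eps^2) return(NULL)
    nrm <- nrm / ln
    d <- sum(nrm * pts[tri[1], ])
    if (sum(nrm * interior) > d) {  # flip to outward
      tri <- tri[c(1, 3, 2)]
      nrm <- -nrm
      d <- -d
    }
    list(tri = tri, nrm = nrm, d = d)
  }
  add_face <- function(tri, cand) {
    of <- orient_face(tri)
    if (is.null(of)) return(invisible(NULL))
    nf <<- nf + 1L
    fv[nf, ] <<- of$tri
    fn[nf, ] <<- of$nrm
    foff[nf] <<- of$d
    alive[nf] <<- TRUE
    if (length(cand)) {
      s <- pts[cand, , drop = FALSE] %*% of$nrm - of$d
      outside[[nf]] <<- cand[s > eps]
    } else {
      outside[[nf]] <<- integer(0)
    }
    invisible(NULL)
  }

  first <- c(i1, i2, i3, i4)
  cand0 <- setdiff(seq_len(n), first)
  add_face(c(i1, i2, i3), cand0)
  add_face(c(i1, i2, i4), cand0)
  add_face(c(i1, i3, i4), cand0)
  add_face(c(i2, i3, i4), cand0)

  repeat {
    live <- which(alive[seq_len(nf)])
    pending <- live[vapply(outside[live], length, 1L) > 0L]
    if (!length(pending)) break
    fid <- pending[1]
    cand <- outside[[fid]]
    s <- pts[cand, , drop = FALSE] %*% fn[fid, ] - foff[fid]
    p <- cand[which.max(s)]

    # faces visible from p (plane test over all alive faces)
    sv <- fn[live, , drop = FALSE] %*% pts[p, ] - foff[live]
    vis <- live[sv > eps]
    if (!length(vis)) {  # numerically interior after all; drop it
      outside[[fid]] <- setdiff(outside[[fid]], p)
      next
    }
    # horizon: undirected edges of visible faces appearing exactly once
    ve <- rbind(
      fv[vis, c(1, 2), drop = FALSE],
      fv[vis, c(2, 3), drop = FALSE],
      fv[vis, c(3, 1), drop = FALSE]
    )
    ue <- cbind(pmin(ve[, 1], ve[, 2]), pmax(ve[, 1], ve[, 2]))
    key <- paste(ue[, 1], ue[, 2])
    once <- key %in% names(which(table(key) == 1L))
    horizon <- ve[once, , drop = FALSE]
    orphans <- unique(unlist(outside[vis]))
    orphans <- setdiff(orphans, p)
    alive[vis] <- FALSE
    outside[vis] <- list(integer(0))
    for (k in seq_len(nrow(horizon))) {
      add_face(c(horizon[k, 1], horizon[k, 2], p), orphans)
    }
  }

  live <- which(alive[seq_len(nf)])
  faces <- fv[live, , drop = FALSE]
  normals <- fn[live, , drop = FALSE]
  offsets <- foff[live]
  # distance of every point to the hull boundary (points are inside the
  # hull, so it is the largest signed plane distance); blocked over faces
  smax <- rep(-Inf, n)
  for (s in seq(1, nrow(faces), by = 256L)) {
    e <- min(s + 255L, nrow(faces))
    blk <- pts %*% t(normals[s:e, , drop = FALSE])
    blk <- sweep(blk, 2, offsets[s:e])
    smax <- pmax(smax, blk[cbind(seq_len(n), max.col(blk))])
  }
  dist_to_hull <- pmax(0, -smax)
  on_hull <- smax > -tol
  list(
    faces = faces, normals = normals, offsets = offsets,
    on_hull = on_hull, dist_to_hull = dist_to_hull
  )
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Sulcal depth
#'
#' Depth of each vertex below the convex hull: the Euclidean distance from
#' the vertex to the nearest mesh vertex lying on the hull surface. Vertices
#' on the hull (gyral crowns) have depth 0. The hull is built from
#' `hull_mesh` (by convention the pial surface) when supplied, otherwise
#' from `mesh` itself.
#'
#' @param mesh a `lam_mesh` whose vertices are queried.
#' @param hull_mesh optional `lam_mesh` whose vertices define the hull.
#' @return numeric vector of depths (mm, >= 0), one per vertex of `mesh`.
#' @export
compute_sulcal_depth <- function(mesh, hull_mesh = NULL) {
  if (is.null(hull_mesh)) hull_mesh <- mesh
  hp <- hull_mesh$vertices
  hull <- convex_hull3(hp)
  hv <- hp[hull$on_hull, , drop = FALSE]
  nearest_dist(mesh$vertices, hv)
}

# min Euclidean distance from each row of a to any row of b (blocked)
nearest_dist <- function(a, b) {
  out <- numeric(nrow(a))
  bb <- rowSums(b^2)
  block <- 512L
  for (s in seq(1, nrow(a), by = block)) {
    e <- min(s + block - 1L, nrow(a))
    ab <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ab^2), bb, "+") - 2 * ab %*% t(b)
    out[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}
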