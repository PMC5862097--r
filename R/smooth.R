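# Geodesic Gaussian kernels on the mesh graph: used both for surface
# smoothing of per-vertex fields and for the patch basis (local current
# dispersion). Geodesic distances are shortest paths on the edge graph.

# sparse matrix of exp(-d^2 / 2 sigma^2) for geodesic d <= cutoff,
# rows = centers, cols = all vertices
geodesic_gaussian <- function(mesh, centers, sigma, cutoff = 3.5 * sigma,
                              graph = NULL) {
  if (is.null(graph)) graph <- mesh_graph(mesh)
  n <- n_vertices(mesh)
  ii <- list(); jj <- list(); xx <- list()
  block <- 512L
  nb <- 0L
  for (s in seq(1, length(centers), by = block)) {
    e <- min(s + block - 1L, length(centers))
    d <- igraph::distances(graph, v = centers[s:e], algorithm = "dijkstra")
    idx <- which(is.finite(d) & d <= cutoff, arr.ind = TRUE)
    nb <- nb + 1L
    ii[[nb]] <- idx[, 1] + (s - 1L)
    jj[[nb]] <- idx[, 2]
    xx[[nb]] <- exp(-d[idx]^2 / (2 * sigma^2))
  }
  sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(length(centers), n)
  )
}

#' Gaussian surface smoothing operator
#'
#' Smoothing of per-vertex fields with a Gaussian kernel of geodesic
#' distance, calibrated by its full width at half maximum. The raw kernel is
#' symmetrised to a doubly stochastic operator (Sinkhorn balancing), so a
#' constant field is exactly invariant and the field total (and mean) is
#' exactly conserved.
#'
#' @param mesh a `lam_mesh`.
#' @param fwhm kernel full width at half maximum, mm.
#' @return a sparse, doubly stochastic n x n smoothing matrix.
#' @export
smoothing_operator <- function(mesh, fwhm) {
  stopifnot(fwhm > 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  W <- geodesic_gaussian(mesh, seq_len(n_vertices(mesh)), sigma)
  W <- (W + Matrix::t(W)) / 2
  # Sinkhorn balancing; symmetric scaling keeps W symmetric
  d <- rep(1, nrow(W))
  for (k in 1:60) {
    r <- as.vector(W %*% d) * d
    d <- d / sqrt(r)
    if (max(abs(r - 1)) < 1e-10) break
  }
  W <- Diagonal(x = d) %*% W %*% Diagonal(x = d)
  methods::as(W, "CsparseMatrix")
}

#' Smooth a per-vertex field
#'
#' @param mesh a `lam_mesh`.
#' @param x numeric per-vertex field.
#' @param fwhm Gaussian full width at half maximum, mm.
#' @param op optional precomputed [smoothing_operator()].
#' @return smoothed field (same length).
#' @export
smooth_field <- function(mesh, x, fwhm, op = NULL) {
  if (is.null(op)) op <- smoothing_operator(mesh, fwhm)
  as.vector(op %*% x)
}

#' Patch basis: local current dispersion on the cortical sheet
#'
#' Column j holds the weights of a source patch centred at vertex j,
#' decaying as a Gaussian of geodesic distance along the mesh. The decay
#' rate is calibrated so the geodesic half-maximum radius equals `fwhm / 2`;
#' the centre weight is 1. In the `fwhm -> 0` limit the basis tends to the
#' identity (single-vertex patches).
#'
#' @param mesh a `lam_mesh`.
#' @param fwhm patch full width at half maximum, mm.
#' @param centers vertices for which patch columns are built (default: all).
#' @param graph optional precomputed mesh graph (internal reuse).
#' @return object of class `lam_patch_basis`: sparse n x length(centers)
#'   matrix `basis` with `fwhm`, `centers`, and the mesh fingerprint.
#' @export
compute_patch_basis <- function(mesh, fwhm, centers = seq_len(n_vertices(mesh)),
                                graph = NULL) {
  stopifnot(fwhm > 0)
  mel <- mean_edge_length(mesh)
  if (fwhm < mel) {
    warn(sprintf(
      "patch FWHM (%.2f mm) below mean edge length (%.2f mm): patches are under-resolved on this mesh",
      fwhm, mel
    ))
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  B <- Matrix::t(geodesic_gaussian(mesh, centers, sigma, graph = graph))
  structure(
    list(
      basis = B, fwhm = fwhm, centers = centers,
      mesh_fingerprint = mesh_fingerprint(mesh)
    ),
    class = "lam_patch_basis"
  )
}

#' @export
print.lam_patch_basis <- function(x, ...) {
  cat(sprintf(
    "<lam_patch_basis> %d x %d, FWHM %.1f mm\n",
    nrow(x$basis), ncol(x$basis), x$fwhm
  ))
  invisible(x)
}

# single patch column (n-vector, centre weight 1)
patch_column <- function(basis, vertex) {
  j <- match(vertex, basis$centers)
  if (is.na(j)) abort("vertex has no patch column in this basis")
  as.vector(basis$basis[, j])
}
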