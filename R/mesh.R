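#' Triangle surface meshes
#'
#' A `lam_mesh` is a triangle mesh in RAS coordinates (mm): a numeric
#' `vertices` matrix (n x 3), an integer `faces` matrix (m x 3, 1-based,
#' counter-clockwise when seen from outside) and unit per-vertex `normals`.
#' Open sheets carry `open = TRUE` and a logical `boundary` vector marking
#' the boundary ring.
#'
#' @param vertices numeric n x 3 matrix of positions (mm).
#' @param faces integer m x 3 matrix of vertex indices (1-based).
#' @param open logical; `TRUE` for an open sheet, `FALSE` for a watertight
#'   (closed) surface. Detected from edge-face incidence when `NULL`.
#' @return an object of class `lam_mesh`.
#' @export
lam_mesh <- function(vertices, faces, open = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L) {
    abort("vertices and faces must have three columns")
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    abort("face indices out of range")
  }
  a <- face_areas(vertices, faces)
  if (any(a <= 0)) {
    abort(sprintf("mesh has %d degenerate face(s) with zero area", sum(a <= 0)))
  }
  bd <- boundary_vertices(nrow(vertices), faces)
  if (is.null(open)) open <- any(bd)
  m <- structure(
    list(
      vertices = vertices,
      faces = faces,
      normals = vertex_normals(vertices, faces),
      open = isTRUE(open),
      boundary = bd
    ),
    class = "lam_mesh"
  )
  m
}

#' @export
print.lam_mesh <- function(x, ...) {
  cat(sprintf(
    "<lam_mesh> %d vertices, %d faces, %s\n",
    nrow(x$vertices), nrow(x$faces),
    if (x$open) "open sheet" else "closed"
  ))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

face_areas <- function(vertices, faces) {
  e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(vertices, faces) {
  e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  cr / sqrt(rowSums(cr^2))
}

# area-weighted vertex normals, unit length
vertex_normals <- function(vertices, faces) {
  fn <- face_normals(vertices, faces)
  a <- face_areas(vertices, faces)
  n <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    idx <- faces[, k]
    n[, 1] <- n[, 1] + tapply_add(idx, fn[, 1] * a, nrow(vertices))
    n[, 2] <- n[, 2] + tapply_add(idx, fn[, 2] * a, nrow(vertices))
    n[, 3] <- n[, 3] + tapply_add(idx, fn[, 3] * a, nrow(vertices))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tapply_add <- function(index, values, n) {
  out <- numeric(n)
  s <- rowsum(values, index)
  out[as.integer(rownames(s))] <- s
  out
}

# unique undirected edges as a 2-column matrix
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

# vertices incident to an edge adjacent to exactly one face
boundary_vertices <- function(n, faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  open_edges <- e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  bd <- logical(n)
  bd[unique(as.vector(open_edges))] <- TRUE
  bd
}

# weighted adjacency graph of the mesh (edge weight = Euclidean edge length)
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh$faces)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh$faces)
  mean(sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2)))
}

# short content fingerprint, used to detect stale lead-field reuse
mesh_fingerprint <- function(mesh) {
  v <- mesh$vertices
  sprintf(
    "n%d-f%d-%.6e-%.6e", nrow(v), nrow(mesh$faces),
    sum(v * rep(c(1, 2, 3), each = nrow(v))), sum(abs(v))
  )
}

#' Icosahedral sphere mesh
#'
#' Repeatedly subdivided icosahedron projected onto a sphere; vertex counts
#' follow the ladder 12, 42, 162, 642, 2562, 10242, ...
#'
#' @param n_vertices minimum number of vertices; the smallest icosahedral
#'   level with at least this many vertices is returned.
#' @param radius sphere radius in mm.
#' @return a closed `lam_mesh`.
#' @export
icosphere <- function(n_vertices, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  while (nrow(v) < n_vertices) {
    res <- subdivide_sphere(v, f)
    v <- res$v
    f <- res$f
  }
  lam_mesh(v * radius, f, open = FALSE)
}

subdivide_sphere <- function(v, f) {
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- edge_key(e[, 1], e[, 2])
  uk <- unique(key)
  mid_index <- setNames(seq_along(uk) + nrow(v), uk)
  ue <- e[!duplicated(key), , drop = FALSE]
  mid <- (v[ue[, 1], ] + v[ue[, 2], ]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  v2 <- rbind(v, mid)
  m12 <- mid_index[edge_key(f[, 1], f[, 2])]
  m23 <- mid_index[edge_key(f[, 2], f[, 3])]
  m31 <- mid_index[edge_key(f[, 3], f[, 1])]
  f2 <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  list(v = v2, f = unname(f2))
}

#' Flat rectangular sheet mesh
#'
#' Regular grid in the x-y plane with upward (+z) normals; an open sheet used
#' in tests and in the unfolded limit of the cortex generator.
#'
#' @param nx,ny grid points along x and y.
#' @param spacing grid spacing in mm.
#' @export
flat_sheet <- function(nx = 10, ny = 10, spacing = 1) {
  g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1)) {
    i <- seq_len(nx - 1)
    f <- rbind(
      f,
      cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
      cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    )
  }
  lam_mesh(v, f, open = TRUE)
}

#' Read / write meshes
#'
#' Wavefront OBJ and ASCII GIfTI (`.surf.gii`) readers and writers. GIfTI
#' support is limited to ASCII-encoded POINTSET/TRIANGLE arrays.
#'
#' @param mesh a `lam_mesh`.
#' @param path file path; format chosen from the extension (`.obj` or `.gii`).
#' @return `read_mesh` returns a `lam_mesh`; `write_mesh` returns `path`
#'   invisibly.
#' @export
write_mesh <- function(mesh, path) {
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(
      "v %.9g %.9g %.9g",
      mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]
    ), con)
    writeLines(sprintf(
      "f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]
    ), con)
  } else if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    write_gifti_ascii(mesh, path)
  } else {
    abort("unsupported mesh format (use .obj or .gii)")
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    vt <- ln[startsWith(ln, "v ")]
    fc <- ln[startsWith(ln, "f ")]
    v <- do.call(rbind, lapply(strsplit(vt, "\\s+"), function(x) {
      as.numeric(x[2:4])
    }))
    f <- do.call(rbind, lapply(strsplit(fc, "\\s+"), function(x) {
      as.integer(sub("/.*", "", x[2:4]))
    }))
    lam_mesh(v, f)
  } else if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    read_gifti_ascii(path)
  } else {
    abort("unsupported mesh format (use .obj or .gii)")
  }
}

write_gifti_ascii <- function(mesh, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "2")
  add_array <- function(intent, type, mat, text) {
    da <- xml2::xml_add_child(
      doc, "DataArray",
      Intent = intent, DataType = type, ArrayIndexingOrder = "RowMajorOrder",
      Dimensionality = "2", Dim0 = as.character(nrow(mat)), Dim1 = "3",
      Encoding = "ASCII", Endian = "LittleEndian"
    )
    xml2::xml_add_child(da, "Data", text)
  }
  add_array(
    "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32", mesh$vertices,
    paste(apply(mesh$vertices, 1, function(r) paste(sprintf("%.9g", r), collapse = " ")),
          collapse = "\n")
  )
  f0 <- mesh$faces - 1L  # GIfTI triangles are 0-based
  add_array(
    "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32", f0,
    paste(apply(f0, 1, paste, collapse = " "), collapse = "\n")
  )
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gifti_ascii <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  v <- NULL
  f <- NULL
  for (a in arrays) {
    intent <- xml2::xml_attr(a, "Intent")
    if (xml2::xml_attr(a, "Encoding") != "ASCII") {
      abort("only ASCII-encoded GIfTI is supported")
    }
    txt <- xml2::xml_text(xml2::xml_find_first(a, ".//Data"))
    vals <- scan(text = txt, quiet = TRUE)
    if (identical(intent, "NIFTI_INTENT_POINTSET")) {
      v <- matrix(vals, ncol = 3, byrow = TRUE)
    } else if (identical(intent, "NIFTI_INTENT_TRIANGLE")) {
      f <- matrix(as.integer(vals), ncol = 3, byrow = TRUE) + 1L
    }
  }
  if (is.null(v) || is.null(f)) abort("GIfTI file lacks POINTSET or TRIANGLE array")
  lam_mesh(v, f)
}
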