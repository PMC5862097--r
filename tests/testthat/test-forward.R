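test_that("sensor arrays sit on the helmet cap with positive spacing", {
  s <- generate_sensor_array(275, helmet_radius = 110, coverage = 0.5)
  expect_length(s$names, 275)
  expect_equal(sqrt(rowSums(s$positions^2)), rep(110, 275), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(s$orientations^2)), rep(1, 275), tolerance = 1e-12)
  for (n in c(64, 400)) {
    arr <- generate_sensor_array(n)
    dmin <- min(dist(arr$positions))
    expect_gt(dmin, 0)
  }
  expect_error(generate_sensor_array(64, coverage = 0), "coverage")
  expect_error(generate_sensor_array(16), "at least 32")
  f <- tempfile(fileext = ".json")
  write_sensor_array(s, f)
  s2 <- read_sensor_array(f)
  expect_equal(s2$positions, unname(s$positions), tolerance = 1e-12)
})

test_that("radial dipoles in a spherical conductor are magnetically silent", {
  m <- icosphere(162, radius = 60)
  m$normals <- m$vertices / sqrt(rowSums(m$vertices^2))  # exactly radial
  L <- compute_lead_field(m, generate_sensor_array(64), conductor_model(radius = 85))
  # tangential reference scale at the same vertices
  mt <- m
  e <- c(0.267, 0.534, 0.802)
  tang <- cbind(
    m$vertices[, 2] * e[3] - m$vertices[, 3] * e[2],
    m$vertices[, 3] * e[1] - m$vertices[, 1] * e[3],
    m$vertices[, 1] * e[2] - m$vertices[, 2] * e[1]
  )
  mt$normals <- tang / sqrt(rowSums(tang^2))
  Lt <- compute_lead_field(mt, generate_sensor_array(64), conductor_model(radius = 85))
  expect_lt(max(abs(L$matrix)), 1e-12 * max(abs(Lt$matrix)))
})

test_that("the sphere dipole field matches an independent gradient-based oracle", {
  skip_if_not_installed("pracma")
  cst <- laminarmeg:::.lam_const
  oracle_field <- function(r0_mm, q_dir, r_mm, ori) {
    r0 <- r0_mm * cst$mm
    r <- r_mm * cst$mm
    q <- q_dir * cst$nAm
    Ffun <- function(rv) {
      a <- sqrt(sum((rv - r0)^2))
      a * (sqrt(sum(rv^2)) * a + sum(rv^2) - sum(r0 * rv))
    }
    Fv <- Ffun(r)
    gradF <- pracma::grad(Ffun, r)      # numerical, replaces the closed form
    qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
              q[3] * r0[1] - q[1] * r0[3],
              q[1] * r0[2] - q[2] * r0[1])
    B <- cst$mu0_over_4pi / Fv^2 * (Fv * qxr0 - sum(qxr0 * r) * gradF)
    sum(B * ori) * cst$fT
  }
  set.seed(7)
  for (i in 1:6) {
    r0 <- rnorm(3); r0 <- r0 / sqrt(sum(r0^2)) * runif(1, 20, 60)
    qd <- rnorm(3); qd <- qd / sqrt(sum(qd^2))
    rs <- rnorm(3); rs <- rs / sqrt(sum(rs^2)) * 110
    ori <- rs / sqrt(sum(rs^2))
    got <- laminarmeg:::dipole_sphere_field(
      rbind(r0), rbind(qd), rbind(rs), rbind(ori)
    )[1, 1]
    want <- oracle_field(r0, qd, rs, ori)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("lead fields are linear and invariant under global rotation", {
  ds <- tiny_dataset(n_trials = 4, snr_db = Inf)
  spec2 <- ds$spec
  spec2$dipole_moment <- 2 * spec2$dipole_moment
  ctx <- ds$ctx
  clean2 <- project_patch(spec2, ctx$pair, context_leadfield_test(ctx, "pial"),
                          laminarmeg:::context_basis(ctx, "pial", 5))
  expect_equal(clean2$data, 2 * ds$clean$data, tolerance = 1e-12)

  # rotate sensors + mesh + conductor together: readings unchanged
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m <- tiny_pair()$pial
  mr <- m
  mr$vertices <- m$vertices %*% t(Rz)
  mr$normals <- m$normals %*% t(Rz)
  sens <- generate_sensor_array(64)
  sensr <- sens
  sensr$positions <- sens$positions %*% t(Rz)
  sensr$orientations <- sens$orientations %*% t(Rz)
  cond <- conductor_model(radius = 85)
  L1 <- compute_lead_field(m, sens, cond)
  L2 <- compute_lead_field(mr, sensr, cond)
  expect_equal(L1$matrix, L2$matrix, tolerance = 1e-9)

  expect_error(
    compute_lead_field(icosphere(162, radius = 90), sens, cond),
    "inside the conductor"
  )
})

test_that("patch basis decays from its centre at the calibrated radius", {
  sheet <- flat_sheet(21, 21, 1)     # 1 mm grid, fine relative to 5 mm
  b <- compute_patch_basis(sheet, 5)
  expect_true(all(b$basis@x >= 0))
  center <- 21 * 10 + 11             # middle vertex
  col <- b$basis[, center]
  expect_equal(which.max(col), center)
  # geodesic half-max radius = fwhm/2 within 20 percent, with distances
  # from an exhaustive independent Dijkstra over the edge graph
  nv <- nrow(sheet$vertices)
  edges <- laminarmeg:::mesh_edges(sheet$faces)
  wlen <- sqrt(rowSums((sheet$vertices[edges[, 1], ] -
                          sheet$vertices[edges[, 2], ])^2))
  dist0 <- rep(Inf, nv)
  dist0[center] <- 0
  done <- logical(nv)
  for (it in seq_len(nv)) {
    u <- which(!done)[which.min(dist0[!done])]
    if (!is.finite(dist0[u])) break
    done[u] <- TRUE
    for (r in which(edges[, 1] == u | edges[, 2] == u)) {
      v2 <- if (edges[r, 1] == u) edges[r, 2] else edges[r, 1]
      dist0[v2] <- min(dist0[v2], dist0[u] + wlen[r])
    }
  }
  r_half <- max(dist0[col >= 0.5])
  expect_lt(abs(r_half - 2.5) / 2.5, 0.2)
  # fwhm below the grid spacing: near-identity columns plus a warning
  expect_warning(b0 <- compute_patch_basis(sheet, 0.2), "under-resolved")
  expect_equal(max(abs(as.matrix(b0$basis) - diag(nrow(sheet$vertices)))), 0,
               tolerance = 1e-6)
})

test_that("lead-field RMS behaves and weakens with sulcal depth under the helmet", {
  M <- cbind(rep(0, 8), rep(3, 8))
  expect_equal(lead_field_rms(M), c(0, 3))
  pair <- tiny_pair()
  ctx <- tiny_context()
  rms <- lead_field_rms(context_leadfield_test(ctx, "pial"))
  sdep <- compute_sulcal_depth(pair$pial)
  covered <- pair$pial$vertices[, 3] > 0    # under the sensor cap
  expect_lt(cor(sdep[covered], rms[covered], method = "spearman"), -0.1)
})
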