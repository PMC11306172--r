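test_that("geometry validation rejects degenerate configurations", {
  expect_error(eye_geometry_config(CCT = -5), "positive")
  expect_error(eye_geometry_config(CCT = 250), "override")
  expect_s3_class(eye_geometry_config(CCT = 250, allow_extreme_cct = TRUE),
                  "eye_geometry_config")
  expect_error(eye_geometry_config(anterior_corneal_radius = 5,
                                   corneal_diameter = 11.5), "degenerate")
  expect_error(eye_geometry_config(corneal_diameter = 25), "scleral")
})

test_that("the mesh realises the requested thickness and fixed topology", {
  m558 <- build_eye_mesh(eye_geometry_config(CCT = 558))
  expect_equal(m558$thickness[1L], 0.558, tolerance = 0.01)
  m600 <- build_eye_mesh(eye_geometry_config(CCT = 600))
  m484 <- build_eye_mesh(eye_geometry_config(CCT = 484))
  # same node count and connectivity, different thickness field
  expect_identical(dim(m600$nodes), dim(m484$nodes))
  expect_identical(m600$elements, m484$elements)
  expect_false(isTRUE(all.equal(m600$thickness, m484$thickness)))
  # apex on the axis, anterior set non-empty, regions cover the domain
  expect_identical(m558$nodes[m558$apex, "r"], c(r = 0))
  expect_gt(length(m558$anterior), 0L)
  expect_false(anyNA(m558$region))
})

test_that("corneal fibre pairs are orthonormal", {
  mesh <- fix_mesh()
  for (e in which(mesh$region == "cornea")) {
    f <- mesh$fibres[[e]]
    expect_equal(sum(f$meridional^2), 1, tolerance = 1e-12)
    expect_equal(sum(f$circumferential^2), 1, tolerance = 1e-12)
    expect_lt(abs(sum(f$meridional * f$circumferential)), 1e-8)
  }
  for (e in which(mesh$region == "limbus"))
    expect_length(mesh$fibres[[e]], 1L)
})

test_that("anterior nodal areas reproduce the spherical-cap closed form", {
  mesh <- fix_mesh()
  A <- anterior_nodal_areas(mesh)
  Ra <- mesh$config$anterior_corneal_radius
  r_out <- unname(mesh$nodes[max(mesh$anterior), 1L])
  cap <- 2 * pi * Ra^2 * (1 - cos(asin(r_out / Ra)))
  expect_lt(abs(sum(A) - cap) / cap, 0.01)
  expect_true(all(A >= 0))
  # projected areas telescope exactly to the rim disc
  Ay <- anterior_nodal_areas(mesh, projected = TRUE)
  expect_equal(sum(Ay), pi * r_out^2, tolerance = 1e-10)
})

test_that("mesh refinement converges and halves interior nodal areas", {
  m1 <- build_eye_mesh(eye_geometry_config(mesh_resolution = 1))
  m2 <- build_eye_mesh(eye_geometry_config(mesh_resolution = 2))
  A1 <- anterior_nodal_areas(m1)
  A2 <- anterior_nodal_areas(m2)
  # the anterior patch of each mesh ends at its own outermost corneal node;
  # compare each discrete estimate against the analytic cap it discretises
  cap_of <- function(m, A) {
    Ra <- m$config$anterior_corneal_radius
    r_out <- unname(m$nodes[max(m$anterior), 1L])
    sum(A) / (2 * pi * Ra^2 * (1 - cos(asin(r_out / Ra))))
  }
  expect_lt(abs(cap_of(m2, A2) - cap_of(m1, A1)), 0.005)
  # on the uniformly spaced corneal arc, refinement by 2 halves the area of
  # a node at the same location (compare node 3 of m1 with node 5 of m2)
  expect_equal(unname(A2[5L]), unname(A1[3L]) / 2, tolerance = 0.02)
})

test_that("areas recomputed in a deformed state match a fine triangulation", {
  mesh <- fix_mesh()
  coords <- mesh$nodes
  sel <- coords[, 1L] < 3
  coords[sel, 2L] <- coords[sel, 2L] - 0.4 * exp(-(coords[sel, 1L] / 1.5)^2)
  A <- anterior_nodal_areas(mesh, coords = coords)
  # oracle: dense triangulated surface of revolution over the same polyline
  ant <- mesh$anterior
  r <- coords[ant, 1L]; y <- coords[ant, 2L]
  n_th <- 720L
  th <- seq(0, 2 * pi, length.out = n_th + 1L)
  area_orc <- 0
  for (k in seq_len(length(ant) - 1L)) {
    p1 <- cbind(r[k] * cos(th), y[k], r[k] * sin(th))
    p2 <- cbind(r[k + 1L] * cos(th), y[k + 1L], r[k + 1L] * sin(th))
    for (j in seq_len(n_th)) {
      a <- p1[j, ]; b <- p1[j + 1L, ]; c1 <- p2[j, ]; d <- p2[j + 1L, ]
      tri <- function(u, v, w) {
        cr <- c((v - u)[2] * (w - u)[3] - (v - u)[3] * (w - u)[2],
                (v - u)[3] * (w - u)[1] - (v - u)[1] * (w - u)[3],
                (v - u)[1] * (w - u)[2] - (v - u)[2] * (w - u)[1])
        sqrt(sum(cr^2)) / 2
      }
      area_orc <- area_orc + tri(a, b, c1) + tri(b, d, c1)
    }
  }
  expect_lt(abs(sum(A) - area_orc) / area_orc, 0.005)
  # sum changed relative to the undeformed surface (stretch changes area)
  expect_false(isTRUE(all.equal(sum(A),
                                sum(anterior_nodal_areas(mesh)),
                                tolerance = 1e-4)))
})

test_that("nodal areas are continuous in the nodal coordinates", {
  mesh <- fix_mesh()
  A0 <- anterior_nodal_areas(mesh)
  coords <- mesh$nodes
  set.seed(3)
  coords[mesh$anterior, ] <- coords[mesh$anterior, ] +
    matrix(stats::runif(2 * length(mesh$anterior), -1e-9, 1e-9), ncol = 2)
  A1 <- anterior_nodal_areas(mesh, coords = coords)
  expect_lt(max(abs(A1 - A0)), 1e-6)
})

test_that("geometry configurations round-trip through YAML", {
  cfg <- eye_geometry_config(CCT = 525, mesh_resolution = 2)
  path <- tempfile(fileext = ".yaml")
  write_eye_config(cfg, path)
  back <- read_eye_config(path)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("the revolved surface export is mirror-symmetric and valid VTK", {
  mesh <- fix_mesh()
  path <- tempfile(fileext = ".vtk")
  write_vtk_mesh(mesh, path, n_theta = 8L)
  lines <- readLines(path)
  expect_identical(lines[1L], "# vtk DataFile Version 3.0")
  i_pts <- grep("^POINTS", lines)
  n_pts <- as.integer(strsplit(lines[i_pts], " ")[[1L]][2L])
  pts <- utils::read.table(text = lines[(i_pts + 1L):(i_pts + n_pts)])
  # reflecting x -> -x permutes the point set onto itself (axisymmetry)
  key <- function(m) sort(paste(round(m[, 1L], 6L), round(m[, 2L], 6L),
                                round(m[, 3L], 6L)))
  refl <- pts; refl[, 1L] <- -refl[, 1L]
  expect_identical(key(pts), key(refl))
})
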