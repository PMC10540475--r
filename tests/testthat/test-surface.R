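test_that("the Gaussian sphere isosurface matches its closed form", {
  g <- gaussian_sphere(amplitude = 1, alpha = 1, box = 14, spacing = 0.25)
  s <- extract_isosurface(g, 0.001)
  exact <- attr(g, "surface_area")
  expect_equal(exact, 4 * pi * log(1000))
  expect_lt(abs(s$area - exact) / exact, 0.01)
  expect_false(s$open)
  expect_equal(s$area, sum(s$triangle_area))

  # refinement reduces the area error monotonically
  errs <- vapply(c(0.5, 0.25), function(sp) {
    gg <- gaussian_sphere(box = 14, spacing = sp)
    abs(extract_isosurface(gg, 0.001)$area - exact) / exact
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("degenerate grids yield empty or flagged-open surfaces", {
  low <- volumetric_grid(c(0, 0, 0), diag(0.5, 3),
                         array(1e-6, c(5, 5, 5)), "density")
  s <- extract_isosurface(low, 0.001)
  expect_equal(nrow(s$triangles), 0L)
  expect_equal(s$area, 0)

  # half-space crossing the boundary: open surface, warned about
  n <- 9
  co <- seq(-1, 1, length.out = n)
  plane <- volumetric_grid(rep(-1, 3), diag(2 / (n - 1), 3),
                           array(rep(1 - co, times = n * n), c(n, n, n)),
                           "density")
  expect_warning(sp <- extract_isosurface(plane, 0.5), "open")
  expect_true(sp$open)
  expect_gt(sp$area, 0)

  expect_error(extract_isosurface(
    volumetric_grid(c(0, 0, 0), diag(1, 3), array(1, c(3, 3, 3)), "esp"),
    0.001), "density")
})

test_that("surface area is invariant under grid rotation", {
  spacing <- 0.25
  box <- 14
  n <- as.integer(round(box / spacing)) + 1L
  th <- pi / 7; ph <- pi / 5
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  R <- Rz %*% Rx
  axes <- spacing * R
  origin <- as.vector(-(box / 2) * (R[1, ] + R[2, ] + R[3, ]))
  idx <- seq_len(n) - 1L
  # density evaluated at the rotated grid points
  ii <- array(rep(idx, times = n * n), c(n, n, n))
  jj <- array(rep(rep(idx, each = n), times = n), c(n, n, n))
  kk <- array(rep(idx, each = n * n), c(n, n, n))
  px <- origin[1] + ii * axes[1, 1] + jj * axes[2, 1] + kk * axes[3, 1]
  py <- origin[2] + ii * axes[1, 2] + jj * axes[2, 2] + kk * axes[3, 2]
  pz <- origin[3] + ii * axes[1, 3] + jj * axes[2, 3] + kk * axes[3, 3]
  vals <- exp(-(px^2 + py^2 + pz^2))
  grot <- volumetric_grid(origin, axes, vals, "density")
  srot <- extract_isosurface(grot, 0.001)

  gax <- gaussian_sphere(box = box, spacing = spacing)
  sax <- extract_isosurface(gax, 0.001)
  expect_lt(abs(srot$area - sax$area) / sax$area, 0.005)
})

test_that("marching tetrahedra agree with a voxel-face oracle on blobs", {
  set.seed(42)
  n <- 49
  co <- seq(-6, 6, length.out = n)
  centers <- matrix(runif(9, -1.5, 1.5), 3, 3)
  widths <- runif(3, 0.6, 1.2)
  vals <- array(0, c(n, n, n))
  ii <- array(rep(co, times = n * n), c(n, n, n))
  jj <- array(rep(rep(co, each = n), times = n), c(n, n, n))
  kk <- array(rep(co, each = n * n), c(n, n, n))
  for (b in 1:3)
    vals <- vals + exp(-widths[b] * ((ii - centers[b, 1])^2 +
                                       (jj - centers[b, 2])^2 +
                                       (kk - centers[b, 3])^2))
  blob <- volumetric_grid(rep(-6, 3), diag(co[2] - co[1], 3), vals,
                          "density")
  s <- extract_isosurface(blob, 0.01)
  oracle <- voxel_face_area(blob, 0.01)
  expect_lt(abs(s$area - oracle) / s$area, 0.15)
})

test_that("field mapping is exact for constant and linear fields", {
  g <- gaussian_sphere(box = 12, spacing = 0.5)
  s <- extract_isosurface(g, 0.001)

  const <- volumetric_grid(g$origin, g$axes,
                           array(0.37, dim = dim(g$values)), "esp")
  sc <- map_field(s, const)
  expect_equal(sc$vertex_scalar, rep(0.37, nrow(s$vertices)))

  n <- dim(g$values)[1]
  co <- seq(g$origin[1], by = 0.5, length.out = n)
  linx <- volumetric_grid(g$origin, g$axes,
                          array(rep(co, times = n * n), c(n, n, n)), "esp")
  sl <- map_field(s, linx)
  expect_equal(sl$vertex_scalar, s$vertices[, 1], tolerance = 1e-12)

  # point-charge potential q/r maps to q/r* on the sphere fixture
  gq <- gaussian_sphere(box = 14, spacing = 0.25)
  sq <- extract_isosurface(gq, 0.001)
  nq <- dim(gq$values)[1]
  cq <- seq(gq$origin[1], by = 0.25, length.out = nq)
  iiq <- array(rep(cq, times = nq * nq), c(nq, nq, nq))
  jjq <- array(rep(rep(cq, each = nq), times = nq), c(nq, nq, nq))
  kkq <- array(rep(cq, each = nq * nq), c(nq, nq, nq))
  r <- sqrt(iiq^2 + jjq^2 + kkq^2)
  r[r < 0.125] <- 0.125
  esp <- volumetric_grid(gq$origin, gq$axes, 2 / r, "esp")
  sm <- map_field(sq, esp)
  rstar <- attr(gq, "surface_radius")
  expect_lt(max(abs(sm$vertex_scalar - 2 / rstar)) / (2 / rstar), 0.01)

  # a vertex outside the field domain is named
  tiny <- volumetric_grid(c(0, 0, 0), diag(0.5, 3),
                          array(0, c(3, 3, 3)), "esp")
  expect_error(map_field(s, tiny), "outside")
})

test_that("%NPSA classifies by mean |ESP| and splits the hemisphere", {
  g <- gaussian_sphere(box = 12, spacing = 0.5)
  s <- extract_isosurface(g, 0.001)
  thr_au <- 10 / 627.509474

  all_low <- map_field(s, volumetric_grid(
    g$origin, g$axes, array(0.1 * thr_au, dim(g$values)), "esp"))
  expect_equal(npsa(all_low)$npsa_percent, 100)

  all_high <- map_field(s, volumetric_grid(
    g$origin, g$axes, array(-5 * thr_au, dim(g$values)), "esp"))
  expect_equal(npsa(all_high)$npsa_percent, 0)

  fx <- dipole_esp_sphere(box = 14, spacing = 0.25)
  sh <- map_field(extract_isosurface(fx$density, 0.001), fx$esp)
  expect_equal(npsa(sh, 10)$npsa_percent, 50, tolerance = 0.02)

  # monotone non-decreasing in the polarity threshold
  vals <- vapply(c(2, 5, 10, 20, 40),
                 function(th) npsa(sh, th)$npsa_percent, numeric(1))
  expect_true(all(diff(vals) >= 0))

  expect_error(npsa(extract_isosurface(fx$density, 0.001)), "map_field")
})

test_that("surfaces export as plain-text OBJ meshes", {
  g <- gaussian_sphere(box = 12, spacing = 0.75)
  s <- extract_isosurface(g, 0.001)
  f <- tempfile(fileext = ".obj")
  write_surface_obj(s, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^v ", lines)), nrow(s$vertices))
  expect_equal(sum(grepl("^f ", lines)), nrow(s$triangles))
})
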