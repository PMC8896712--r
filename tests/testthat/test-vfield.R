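# Planar vector-field calculus: canonical fields, divergence/curl,
# scattered interpolation and streamline advection.

test_that("canonical fields match their defining velocities", {
  f <- make_canonical_field("expansion", 6, 1)
  i <- which(f$x == 3); j <- which(f$y == -2)
  expect_equal(c(f$vx[i, j], f$vy[i, j]), c(3, -2))
  r <- make_canonical_field("rotation_ccw", 6, 1)
  i <- which(r$x == 1); j <- which(r$y == 0)
  expect_equal(c(r$vx[i, j], r$vy[i, j]), c(0, 1))
  s <- make_canonical_field("spiral", 6, 1)
  o <- which(s$x == 0)
  expect_equal(c(s$vx[o, o], s$vy[o, o]), c(0, 0))
  expect_error(make_canonical_field("vortex"), class = "rf_kind_error")
})

test_that("divergence and curl are uniform on the canonical fields", {
  expect_equal(range(divergence(make_canonical_field("expansion", 6))$value), c(2, 2))
  expect_equal(range(curl_z(make_canonical_field("expansion", 6))$value), c(0, 0))
  expect_equal(range(curl_z(make_canonical_field("rotation_ccw", 6))$value), c(2, 2))
  expect_equal(range(divergence(make_canonical_field("rotation_ccw", 6))$value), c(0, 0))
  s <- make_canonical_field("spiral", 6)
  expect_equal(range(divergence(s)$value), c(2, 2))
  expect_equal(range(curl_z(s)$value), c(2, 2))
  # zero field
  ax <- -3:3
  z <- vector_field(ax, ax, matrix(0, 7, 7), matrix(0, 7, 7))
  expect_equal(range(divergence(z)$value), c(0, 0))
  expect_equal(range(curl_z(z)$value), c(0, 0))
})

test_that("curl sign convention: counter-clockwise positive, clockwise negative", {
  expect_true(all(curl_z(make_canonical_field("rotation_ccw", 4))$value > 0))
  expect_true(all(curl_z(make_canonical_field("rotation_cw", 4))$value < 0))
})

test_that("difference operators are linear and exact on linear fields", {
  set.seed(11)
  for (k in 1:10) {
    A <- matrix(rnorm(4), 2); b <- rnorm(2)
    f <- linear_field(A, b)
    expect_equal(max(abs(divergence(f)$value - (A[1, 1] + A[2, 2]))), 0,
                 tolerance = 1e-12)
    expect_equal(max(abs(curl_z(f)$value - (A[2, 1] - A[1, 2]))), 0,
                 tolerance = 1e-12)
    # linearity at interior nodes
    A2 <- matrix(rnorm(4), 2); b2 <- rnorm(2)
    g <- linear_field(A2, b2)
    a1 <- rnorm(1); a2 <- rnorm(1)
    comb <- f
    comb$vx <- a1 * f$vx + a2 * g$vx
    comb$vy <- a1 * f$vy + a2 * g$vy
    lhs <- interior_vals(divergence(comb))
    rhs <- a1 * interior_vals(divergence(f)) + a2 * interior_vals(divergence(g))
    expect_equal(lhs, rhs, tolerance = 1e-10)
    lhs <- interior_vals(curl_z(comb))
    rhs <- a1 * interior_vals(curl_z(f)) + a2 * interior_vals(curl_z(g))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("calculus rejects grids that are too small or irregular", {
  ax <- c(0, 1)
  tiny <- vector_field(ax, ax, matrix(0, 2, 2), matrix(0, 2, 2))
  expect_error(divergence(tiny), class = "rf_grid_error")
  expect_error(curl_z(tiny), class = "rf_grid_error")
  expect_error(vector_field(c(0, 1, 3), 0:2, matrix(0, 3, 3), matrix(0, 3, 3)),
               class = "rf_grid_error")
})

test_that("scattered interpolation is exact for linear fields and at samples", {
  set.seed(12)
  pts <- cbind(runif(400, -6, 6), runif(400, -6, 6))
  vel <- cbind(pts[, 1], pts[, 2])  # v = (x, y)
  f <- interpolate_scattered(pts, vel, list(extent = 5, spacing = 0.5))
  xx <- matrix(f$x, length(f$x), length(f$y))
  yy <- t(xx)
  expect_lt(max(abs(f$vx - xx)[f$mask]), 1e-9)
  expect_lt(max(abs(f$vy - yy)[f$mask]), 1e-9)
  # a node coinciding with a sample takes the sample value
  pts2 <- rbind(pts, c(0, 0))
  vel2 <- rbind(vel, c(42, -42))
  f2 <- interpolate_scattered(pts2, vel2, list(extent = 5, spacing = 0.5))
  o <- which(f2$x == 0)
  expect_equal(c(f2$vx[o, o], f2$vy[o, o]), c(42, -42))
})

test_that("three-point interpolation at the centroid is the mean of the vertices", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 3))
  vel <- rbind(c(1, 2), c(4, -1), c(-2, 5))
  ctr <- colMeans(pts)
  f <- interpolate_scattered(pts, vel, list(x = c(ctr[1] - 0.5, ctr[1], ctr[1] + 0.5),
                                            y = c(ctr[2] - 0.5, ctr[2], ctr[2] + 0.5)))
  expect_equal(c(f$vx[2, 2], f$vy[2, 2]), colMeans(vel), tolerance = 1e-10)
})

test_that("curl of an interpolated spiral scatter is 2 on interior unmasked nodes", {
  set.seed(13)
  pts <- cbind(runif(600, -6, 6), runif(600, -6, 6))
  vel <- cbind(pts[, 1] - pts[, 2], pts[, 2] + pts[, 1])
  f <- interpolate_scattered(pts, vel, list(extent = 5, spacing = 0.5))
  cz <- curl_z(f)
  iv <- interior_vals(cz)
  im <- interior_vals(list(value = cz$mask * 1, x = cz$x, y = cz$y)) > 0
  expect_lt(max(abs(iv[im] - 2)), 1e-8)
})

test_that("interpolation masks outside the convex hull and rejects degenerate scatters", {
  # samples confined to x >= 0: nodes at x < 0 must be masked
  set.seed(14)
  pts <- cbind(runif(200, 0, 6), runif(200, -6, 6))
  vel <- cbind(pts[, 1], pts[, 2])
  f <- interpolate_scattered(pts, vel, list(extent = 5, spacing = 1))
  expect_false(any(f$mask[f$x < -0.5, ]))
  expect_error(interpolate_scattered(pts[1:2, ], vel[1:2, ],
                                     list(extent = 2, spacing = 1)),
               class = "rf_degenerate_error")
  coll <- cbind(seq(0, 5, length.out = 10), seq(0, 5, length.out = 10) * 2)
  expect_error(interpolate_scattered(coll, coll, list(extent = 2, spacing = 1)),
               class = "rf_degenerate_error")
})

test_that("particles on the negated expansion field collapse to the origin", {
  neg <- make_canonical_field("expansion", 6)
  neg$vx <- -neg$vx; neg$vy <- -neg$vy
  seeds <- as.matrix(expand.grid(seq(-5, 5, 1), seq(-5, 5, 1)))
  sl <- advect_streamlines(neg, seeds)
  d <- sqrt(rowSums(sl$endpoints^2))
  expect_gte(mean(d < 1), 0.99)
  expect_error(advect_streamlines(neg, seeds, step = 0), class = "rf_step_error")
})

test_that("uniform translation carries particles straight out of the grid", {
  ax <- seq(-6, 6, 1)
  u <- vector_field(ax, ax, matrix(1, 13, 13), matrix(0, 13, 13))
  sl <- advect_streamlines(u, rbind(c(-6, 0.5), c(-6, -2)), record_paths = TRUE)
  expect_true(all(sl$status == "exit"))
  expect_equal(sl$endpoints[, 1], c(6, 6))  # right edge
  expect_equal(sl$endpoints[, 2], c(0.5, -2))  # straight line
})

test_that("rotation-field orbits stay in a narrow annulus", {
  rot <- make_canonical_field("rotation_ccw", 6, 0.5)
  sl <- advect_streamlines(rot, matrix(c(3, 0), 1), step = 0.1,
                           max_steps = 4000, record_paths = TRUE)
  r <- sqrt(rowSums(sl$paths[[1]]^2))
  expect_lt(max(abs(r - 3)), 0.02)
})

test_that("vector and scalar fields round-trip through delimited tables", {
  f <- make_canonical_field("spiral", 3)
  f$mask[1, 1] <- FALSE
  p1 <- tempfile(fileext = ".csv")
  write_vector_field(f, p1)
  g <- read_vector_field(p1)
  expect_equal(g$x, f$x)
  expect_equal(g$mask, f$mask)
  expect_equal(g$vx[g$mask], f$vx[f$mask])
  s <- divergence(f)
  p2 <- tempfile(fileext = ".csv")
  write_scalar_field(s, p2)
  s2 <- read_scalar_field(p2)
  expect_equal(s2$value[s2$mask], s$value[s$mask])
  unlink(c(p1, p2))
})
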