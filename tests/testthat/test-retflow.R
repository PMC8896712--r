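# Retinal flow frames and the flow features that encode heading: foveal
# curl, the divergence maximum, the foveal iso-contour and heading angles.

test_that("the retinal chart and its inverse are consistent", {
  expect_equal(unlist(chart(0.7, 0)), c(x = 0, y = 0))
  expect_equal(unlist(chart(pi / 2, 10)), c(x = 0, y = 10), tolerance = 1e-12)
  set.seed(31)
  th <- runif(50, -pi, pi); rho <- runif(50, 0, 60)
  ch <- chart(th, rho)
  back <- unchart(ch$x, ch$y)
  expect_equal(back$rho, rho, tolerance = 1e-12)
  expect_equal(cos(back$theta - th), rep(1, 50), tolerance = 1e-12)
  expect_error(chart(0, -1), class = "rf_chart_error")
})

test_that("point flow is zero for a stationary fixating eye", {
  pose <- orient_to_fixation(c(0, 0, 1.25), c(0, 2, 0))
  grid <- ground_grid(0.5, c(-2, 2), c(0.5, 5))
  pr <- project_grid(pose, grid)
  pf <- point_flow(pr, pr, fps = 30)
  expect_equal(max(abs(c(pf$vx, pf$vy))), 0)
  expect_error(point_flow(pr, pr, fps = 0), class = "rf_fps_error")
})

test_that("a straight approach produces radially outward flow", {
  sc <- straight_approach(duration = 0.1, fps = 30, start_distance = 3)
  fr <- sc$frames
  p1 <- orient_to_fixation(c(fr$cx[1], fr$cy[1], fr$cz[1]), c(fr$fx[1], fr$fy[1]))
  p2 <- orient_to_fixation(c(fr$cx[2], fr$cy[2], fr$cz[2]), c(fr$fx[2], fr$fy[2]))
  grid <- ground_grid(0.4, c(-2, 2), c(0.5, 5))
  pf <- point_flow(project_grid(p1, grid, 50), project_grid(p2, grid, 50),
                   fps = sc$fps)
  radial <- (pf$x * pf$vx + pf$y * pf$vy) / pmax(sqrt(pf$x^2 + pf$y^2), 1e-9)
  keep <- sqrt(pf$x^2 + pf$y^2) > 1
  expect_true(all(radial[keep] > 0))
})

test_that("flow frames are self-consistent and positive-divergent near the fovea", {
  sc <- straight_approach(duration = 0.1, fps = 30, start_distance = 3)
  run <- run_scenario(sc, keep_frames = TRUE)
  ff <- run$frames[[2]]
  sel <- sqrt(outer(ff$div_field$x^2, ff$div_field$y^2, "+")) <= 5
  expect_true(all(ff$div_field$value[sel & ff$div_field$mask] > 0))
  # definitional consistency: under the planar metric the stored fields are
  # exactly the vfield operators applied to the grid flow
  run_p <- run_scenario(sc, keep_frames = TRUE, metric = "planar")
  fp <- run_p$frames[[2]]
  dv <- divergence(fp$grid_flow)
  expect_equal(fp$div_field$value[fp$div_field$mask], dv$value[dv$mask])
  cz <- curl_z(fp$grid_flow)
  expect_equal(fp$curl_field$value[fp$curl_field$mask], cz$value[cz$mask])
  expect_error(flow_frame(matrix(0, 2, 2), matrix(0, 2, 2)),
               class = "rf_degenerate_error")
})

test_that("foveal curl reports the side of the fixation point", {
  # aligned fixation: no net rotation at the fovea
  sc0 <- straight_approach(fixation_offset_angle = 0, duration = 0.15, fps = 30)
  ft0 <- run_scenario(sc0)$features[-1, ]
  expect_lt(max(abs(ft0$foveal_curl)), 1e-8)
  # fixation to the left: counter-rotation with positive reported curl;
  # to the right: negative; mirrored magnitudes
  scL <- straight_approach(fixation_offset_angle = 5, duration = 0.15, fps = 30)
  scR <- straight_approach(fixation_offset_angle = -5, duration = 0.15, fps = 30)
  cL <- run_scenario(scL)$features$foveal_curl[-1]
  cR <- run_scenario(scR)$features$foveal_curl[-1]
  expect_true(all(cL > 0))
  expect_true(all(cR < 0))
  expect_equal(cL, -cR, tolerance = 1e-9)
})

test_that("perfect fixation nulls the flow at the fovea", {
  sc <- straight_approach(duration = 0.15, fps = 30)
  ft <- run_scenario(sc)$features[-1, ]
  expect_lt(max(ft$foveal_speed), 1e-6)
})

test_that("the divergence maximum migrates from the lower to the upper field", {
  # far from the fixation point (shallow gaze): peak in the lower field
  far <- straight_approach(duration = 0.1, fps = 30, start_distance = 5)
  ft_far <- run_scenario(far)$features[-1, ]
  expect_true(all(ft_far$maxdiv_y < 0))
  # nearer than one eye height (gaze steeper than 45 deg): upper field
  near <- straight_approach(duration = 0.1, fps = 30, start_distance = 0.9)
  ft_near <- run_scenario(near)$features[-1, ]
  expect_true(all(ft_near$maxdiv_y > 0))
})

test_that("the velocity ground line passes through the divergence maximum", {
  sc <- straight_approach(fixation_offset_angle = 4, duration = 0.1, fps = 30)
  ft <- run_scenario(sc)$features[-1, ]
  # ground-projected velocity line is x = 0; within one ground-grid spacing
  expect_lt(max(abs(ft$maxdiv_gx)), 0.25)
  expect_false(any(ft$maxdiv_boundary))
})

test_that("the foveal iso-contour closes, degenerates at 45 deg, and reopens", {
  sc <- straight_approach(duration = 1.3, fps = 30, start_distance = 2.5)
  ft <- run_scenario(sc)$features[-1, ]
  early <- ft[ft$declination_deg < 40, ]
  expect_true(all(early$iso_state == "closed"))
  expect_true(all(early$iso_area > 1))
  deg <- ft[which(ft$iso_area < 1)[1], ]
  expect_equal(deg$declination_deg, 45, tolerance = 1)
  late <- ft[ft$declination_deg > 50, ]
  expect_true(all(late$iso_area > 1))
  # the closed contour encloses the divergence maximum: check one frame
  run <- run_scenario(sc, keep_frames = TRUE)
  i <- which(run$features$declination_deg > 35)[1]
  iso <- foveal_isocontour(run$frames[[i]])
  md <- max_divergence(run$frames[[i]])
  expect_equal(iso$state, "closed")
  expect_true(retinalflow:::point_in_polygon(md$x, md$y,
                                             iso$curve[, 1], iso$curve[, 2]))
})

test_that("a divergence peak at the fovea itself is flagged degenerate", {
  # radial inflow with a quadratic falloff: div maximal at the origin
  set.seed(32)
  pts <- cbind(runif(800, -30, 30), runif(800, -30, 30))
  r2 <- rowSums(pts^2)
  vel <- -pts * (1 + r2 / 500)
  ff <- flow_frame(pts, vel, fov = 25, spacing = 1, fps = 30)
  iso <- foveal_isocontour(ff)
  expect_equal(iso$state, "degenerate")
  expect_equal(iso$area, 0)
})

test_that("heading angles are signed, mirrored, and guarded", {
  pose <- orient_to_fixation(c(0, 0, 1.25), c(0, 3, 0))
  expect_equal(heading_angles(pose, c(0, 1.25, 0))$velocity_fixation_angle, 0)
  poseL <- orient_to_fixation(c(0, 0, 1.25), c(-0.5, 3, 0))
  poseR <- orient_to_fixation(c(0, 0, 1.25), c(0.5, 3, 0))
  aL <- heading_angles(poseL, c(0, 1.25, 0))$velocity_fixation_angle
  aR <- heading_angles(poseR, c(0, 1.25, 0))$velocity_fixation_angle
  expect_equal(aL, -aR)
  expect_gt(aL, 0)  # fixation left of the path: the eye passes to its right
  expect_error(heading_angles(pose, c(0, 0, -1)), class = "rf_velocity_error")
})

test_that("scalar back-projection inverts the retinal projection", {
  sc <- straight_approach(duration = 0.1, fps = 30, start_distance = 3)
  run <- run_scenario(sc, keep_frames = TRUE)
  ff <- run$frames[[2]]
  pose <- retinalflow:::scenario_poses(sc)[[2]]
  bp <- backproject_scalar(ff$div_field, pose)
  expect_gt(nrow(bp), 1000)
  # the fovea maps to the fixation point
  ch <- retinalflow:::unproject_chart(pose, 0, 0)
  expect_equal(c(ch$gx, ch$gy), c(sc$frames$fx[2], sc$frames$fy[2]),
               tolerance = 1e-9)
  # back-projection then re-projection returns the original chart nodes
  sel <- which(ff$div_field$mask, arr.ind = TRUE)[1:50, ]
  cx <- ff$div_field$x[sel[, 1]]; cy <- ff$div_field$y[sel[, 2]]
  g <- retinalflow:::unproject_chart(pose, cx, cy)
  keep <- g$ok
  pr <- retinalflow:::project_points_raw(pose, cbind(g$gx[keep], g$gy[keep], 0))
  ch2 <- chart(pr$theta, pr$rho)
  expect_equal(ch2$x, cx[keep], tolerance = 1e-6)
  expect_equal(ch2$y, cy[keep], tolerance = 1e-6)
  # two routes to the divergence maximum agree (within the grid cell that
  # the argmax refinement moves inside)
  md <- max_divergence(ff, pose)
  top <- bp[which.max(bp$value), ]
  expect_lt(sqrt((md$ground[1] - top$gx)^2 + (md$ground[2] - top$gy)^2), 0.3)
})

test_that("slip adds a bounded, near-uniform velocity offset", {
  # downward slip, the dominant direction of natural fixation slip; a
  # lateral sweep additionally twists the (gravity-referenced) equator and
  # can locally exceed the foveal rate in the far periphery
  sc <- static_fixation_scenario(duration = 0.6, fps = 60, declination_deg = 45)
  p <- perturbation("slip", onset = 0.2, duration = 0.25,
                    direction = c(0, -1), magnitude = 1)
  r0 <- run_scenario(sc, keep_frames = TRUE)
  r1 <- run_scenario(apply_perturbation(sc, p), keep_frames = TRUE)
  w <- which(r1$features$t > 0.2 + 1e-9 & r1$features$t <= 0.45 + 1e-9)
  i <- w[length(w) %/% 2]
  slip_speed <- r1$features$foveal_speed[i]
  expect_equal(slip_speed, 4, tolerance = 0.02)
  g0 <- r0$frames[[i]]$grid_flow; g1 <- r1$frames[[i]]$grid_flow
  m <- g0$mask & g1$mask
  dmag <- sqrt((g1$vx - g0$vx)[m]^2 + (g1$vy - g0$vy)[m]^2)
  expect_lt(max(dmag), slip_speed * 1.02)
})

test_that("an injected saccade dominates the flow speed and curl", {
  sc <- straight_approach(speed = 1.25, duration = 0.45, fps = 60,
                          start_distance = 2)
  p <- perturbation("saccade", onset = 0.3, duration = 0.05,
                    direction = c(1, 1), rate = 195)
  r0 <- run_scenario(sc, keep_frames = TRUE)
  r1 <- run_scenario(apply_perturbation(sc, p), keep_frames = TRUE)
  w <- which(r1$features$t > 0.3 + 1e-9 & r1$features$t <= 0.35 + 1e-9)
  expect_equal(mean(r1$features$foveal_speed[w]), 195, tolerance = 0.04)
  i <- w[2]
  spd <- function(g) sqrt(g$vx[g$mask]^2 + g$vy[g$mask]^2)
  expect_gt(median(spd(r1$frames[[i]]$grid_flow)) /
              median(spd(r0$frames[[i]]$grid_flow)), 10)
  crl <- function(f) median(abs(f$curl_field$value[f$curl_field$mask]))
  expect_gt(crl(r1$frames[[i]]) / crl(r0$frames[[i]]), 10)
  # the injected rotation is divergence-free: div changes, but only modestly
  dvm <- function(f) median(abs(f$div_field$value[f$div_field$mask]))
  expect_gt(abs(dvm(r1$frames[[i]]) / dvm(r0$frames[[i]]) - 1), 0.02)
})
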