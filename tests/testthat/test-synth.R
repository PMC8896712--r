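# Synthetic trajectory generators and perturbations.

test_that("straight approaches place the fixation at the requested offset", {
  sc <- straight_approach(fixation_offset_angle = 0, duration = 0.5, fps = 30)
  expect_equal(sc$frames$fx[1], 0)  # on the ground track
  # mirrored offsets give mirrored scenarios
  a <- straight_approach(fixation_offset_angle = 7, duration = 0.3, fps = 30)
  b <- straight_approach(fixation_offset_angle = -7, duration = 0.3, fps = 30)
  expect_equal(a$frames$fx, -b$frames$fx)
  expect_equal(a$frames$fy, b$frames$fy)
  expect_equal(a$frames$cy, b$frames$cy)
})

test_that("gaze declination crosses 45 degrees when one eye height from fixation", {
  # closed form: atan(h / d(t)) = 45 deg when d = h, i.e. t = (5 - 1.25) / 1.25
  sc <- straight_approach(eye_height = 1.25, speed = 1.25, duration = 3.2,
                          fps = 60, start_distance = 5)
  poses <- retinalflow:::scenario_poses(sc)
  decl <- vapply(poses, gaze_declination, numeric(1))
  t45 <- sc$frames$t[which(decl >= 45 - 1e-9)[1]]
  expect_equal(t45, (5 - 1.25) / 1.25, tolerance = 1e-9)
})

test_that("sinusoid trajectories reduce to straight paths and hit peak velocity", {
  s0 <- sinusoid_trajectory("vertical", amplitude = 0, frequency = 2,
                            base_speed = 1.25, duration = 1, fps = 60)
  st <- straight_approach(speed = 1.25, duration = 1, fps = 60)
  expect_equal(s0$frames[, c("cx", "cy", "cz")], st$frames[, c("cx", "cy", "cz")])
  a <- 0.15; f <- 1.5
  sv <- sinusoid_trajectory("vertical", a, f, 1.25, duration = 2, fps = 240)
  vz <- diff(sv$frames$cz) * sv$fps
  expect_equal(max(abs(vz)), 2 * pi * f * a, tolerance = 1e-3)
  expect_error(sinusoid_trajectory("vertical", 2, 1, 1, eye_height = 1.25),
               class = "rf_scenario_error")
})

test_that("horizontal sinusoid flips the foveal curl at lateral-velocity zero crossings", {
  sh <- sinusoid_trajectory("horizontal", amplitude = 0.1, frequency = 1,
                            base_speed = 1.25, duration = 1, fps = 30,
                            fixation_ahead = 4)
  ft <- run_scenario(sh)$features[-1, ]
  vx <- diff(sh$frames$cx) * sh$fps
  # when moving rightward (+x) the fixation ahead lies to the left: positive curl
  agree <- sign(ft$foveal_curl) == sign(vx)
  strong <- abs(vx) > 0.2 * max(abs(vx))
  expect_true(all(agree[strong]))
})

test_that("corkscrew trajectories are circular in the frontal plane", {
  ck <- corkscrew_trajectory(radius = 0.1, angular_rate = 1, base_speed = 1.25,
                             duration = 1, fps = 60)
  r2 <- (ck$frames$cx + 0.1)^2 + (ck$frames$cz - 1.25)^2
  expect_equal(r2, rep(0.01, nrow(ck$frames)), tolerance = 1e-12)
  c0 <- corkscrew_trajectory(0, 1, 1.25, duration = 0.5, fps = 30)
  st <- straight_approach(speed = 1.25, duration = 0.5, fps = 30)
  expect_equal(c0$frames[, c("cx", "cy", "cz")], st$frames[, c("cx", "cy", "cz")])
})

test_that("corkscrew foveal curl oscillates at the revolution rate", {
  ck <- corkscrew_trajectory(radius = 0.08, angular_rate = 2, base_speed = 1.25,
                             duration = 1.5, fps = 30, fixation_ahead = 5)
  ft <- run_scenario(ck)$features[-1, ]
  x <- ft$foveal_curl - mean(ft$foveal_curl)
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = FALSE)
  fpk <- sp$freq[which.max(sp$spec)] * ck$fps
  expect_equal(fpk, 2, tolerance = 0.35)  # frequency resolution ~0.7 Hz
})

test_that("the gait generator hits its velocity and spectral targets", {
  for (ws in c(0.8, 1.4, 2.0)) {
    sc <- gait_head_trajectory(walk_speed = ws, duration = 5, fps = 100)
    vz <- diff(sc$frames$cz) * sc$fps
    expect_equal(max(abs(vz)) / ws, 0.5, tolerance = 0.02)
    sp <- stats::spec.pgram(vz, plot = FALSE, taper = 0)
    expect_equal(sp$freq[which.max(sp$spec)] * sc$fps, 2, tolerance = 0.11)
  }
  # integer number of cycles, zero jitter: no net vertical drift
  sc <- gait_head_trajectory(1.25, duration = 3, fps = 100)
  expect_equal(sc$frames$cz[301], sc$frames$cz[1], tolerance = 1e-12)
})

test_that("generators are deterministic given a seed", {
  a <- gait_head_trajectory(1.25, duration = 2, fps = 50, seed = 9,
                            phase_jitter = 0.2)
  b <- gait_head_trajectory(1.25, duration = 2, fps = 50, seed = 9,
                            phase_jitter = 0.2)
  expect_identical(a$frames, b$frames)
  c1 <- synth_calibration_session(c(3, 1, -2), noise_deg = 0.5, seed = 4)
  c2 <- synth_calibration_session(c(3, 1, -2), noise_deg = 0.5, seed = 4)
  expect_identical(c1$frames, c2$frames)
})

test_that("generators emit valid scenarios across random parameter draws", {
  set.seed(41)
  for (k in 1:300) {
    g <- sample(4, 1)
    sc <- switch(g,
      straight_approach(eye_height = runif(1, 0.9, 2), speed = runif(1, 0.5, 2),
                        fixation_offset_angle = runif(1, -15, 15),
                        duration = runif(1, 0.1, 0.6),
                        fps = sample(c(30, 60), 1),
                        start_distance = runif(1, 1, 8)),
      sinusoid_trajectory(sample(c("vertical", "horizontal"), 1),
                          amplitude = runif(1, 0, 0.3),
                          frequency = runif(1, 0.5, 3),
                          base_speed = runif(1, 0.5, 2),
                          duration = runif(1, 0.1, 0.6), fps = 30),
      corkscrew_trajectory(radius = runif(1, 0, 0.3),
                           angular_rate = runif(1, 0.5, 3),
                           base_speed = runif(1, 0.5, 2),
                           duration = runif(1, 0.1, 0.6), fps = 30),
      gait_head_trajectory(walk_speed = runif(1, 0.8, 2),
                           duration = runif(1, 0.5, 2), fps = 50,
                           seed = k, phase_jitter = runif(1, 0, 0.3))
    )
    expect_true(validate_scenario(sc))
  }
})

test_that("slip and saccade sweeps produce the stated foveal image motion", {
  sc <- static_fixation_scenario(duration = 0.6, fps = 60)
  slip <- perturbation("slip", onset = 0.2, duration = 0.25,
                       direction = c(1, -1), magnitude = 1)
  ft <- run_scenario(apply_perturbation(sc, slip))$features
  w <- ft$t > 0.2 + 1e-9 & ft$t <= 0.45 + 1e-9
  expect_equal(mean(ft$foveal_speed[w]), 4, tolerance = 1e-6)
  sac <- perturbation("saccade", onset = 0.2, duration = 0.05,
                      direction = c(1, 1), rate = 195)
  ft2 <- run_scenario(apply_perturbation(sc, sac))$features
  w2 <- ft2$t > 0.2 + 1e-9 & ft2$t <= 0.25 + 1e-9
  expect_equal(mean(ft2$foveal_speed[w2]), 195, tolerance = 1e-6)
})

test_that("perturbation bookkeeping: zero magnitude, overlap, window bounds", {
  sc <- straight_approach(duration = 0.5, fps = 30)
  z <- apply_perturbation(sc, perturbation("slip", onset = 0.1, duration = 0.1,
                                           direction = c(1, 0), magnitude = 0))
  expect_identical(z$frames, sc$frames)
  s1 <- apply_perturbation(sc, perturbation("slip", onset = 0.1, duration = 0.1,
                                            direction = c(1, 0), magnitude = 0.5))
  expect_error(
    apply_perturbation(s1, perturbation("slip", onset = 0.15, duration = 0.1,
                                        direction = c(0, 1), magnitude = 0.5)),
    class = "rf_overlap_error")
  # different kinds may overlap
  expect_s3_class(
    apply_perturbation(s1, perturbation("saccade", onset = 0.15, duration = 0.05,
                                        direction = c(1, 1), rate = 100))$frames,
    "data.frame")
  expect_error(
    apply_perturbation(sc, perturbation("slip", onset = 0.45, duration = 0.2,
                                        direction = c(1, 0), magnitude = 1)),
    class = "rf_scenario_error")
})

test_that("synthetic calibration sessions encode the misalignment exactly", {
  s0 <- synth_calibration_session(c(0, 0, 0))
  p0 <- gaze_ground_intersections(s0, c(0, 0, 0))
  expect_lt(max(abs(p0$x - s0$calib_point[1])), 1e-9)
  expect_lt(max(abs(p0$y - s0$calib_point[2])), 1e-9)
  s1 <- synth_calibration_session(c(5, -3, 2))
  expect_lt(calibration_error(gaze_ground_intersections(s1, c(5, -3, 2)),
                              s1$calib_point), 1e-9)
  expect_warning(
    synth_calibration_session(c(1, 0, 0),
                              sweep = data.frame(pitch = sin(1:100 / 10) * 20,
                                                 yaw = 0)),
    "single")
})
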