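# Synthetic eye trajectories, fixation schedules and perturbations. These
# generators stand in for recorded kinematics: they emit the same pose
# tables the rest of the pipeline consumes, with the statistical structure
# of walking data (forward progression, ~2 Hz vertical head oscillation
# whose peak velocity is about half the walking speed, piecewise-constant
# ground fixations, fixation slip and saccades).

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

new_scenario <- function(frames, fps, walk_speed, eye_height, generator,
                         params = list(), perturbations = list(), seed = NULL) {
  frames$fx0 <- frames$fx
  frames$fy0 <- frames$fy
  frames$perturbed <- FALSE
  sc <- structure(list(
    frames = frames, fps = fps, walk_speed = walk_speed,
    eye_height = eye_height, generator = generator, params = params,
    perturbations = perturbations, seed = seed
  ), class = "rf_scenario")
  validate_scenario(sc)
  sc
}

#' Validate a scenario object
#'
#' Checks the scenario invariants: frame times strictly increasing at
#' `1/fps` spacing, eye center above the ground plane at every frame, and
#' perturbation windows inside the scenario duration without same-kind
#' overlap.
#'
#' @param scenario an `rf_scenario`.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_scenario <- function(scenario) {
  fr <- scenario$frames
  dt <- diff(fr$t)
  if (any(dt <= 0)) rf_error("rf_scenario_error", "frame times must be strictly increasing")
  if (max(abs(dt - 1 / scenario$fps)) > 1e-6 / scenario$fps)
    rf_error("rf_scenario_error", "frame times must be spaced at 1/fps")
  if (any(fr$cz <= 0)) rf_error("rf_scenario_error", "eye center must stay above the ground")
  dur <- max(fr$t)
  for (kind in c("slip", "saccade")) {
    ps <- Filter(function(p) p$kind == kind, scenario$perturbations)
    if (length(ps) == 0) next
    win <- t(vapply(ps, function(p) c(p$onset, p$onset + p$duration), numeric(2)))
    if (any(win < -1e-9) || any(win > dur + 1e-9))
      rf_error("rf_scenario_error", "perturbation window outside scenario duration")
    o <- order(win[, 1])
    win <- win[o, , drop = FALSE]
    if (nrow(win) > 1 && any(win[-1, 1] < win[-nrow(win), 2] - 1e-9))
      rf_error("rf_overlap_error", sprintf("overlapping %s windows", kind))
  }
  invisible(TRUE)
}

#' @export
print.rf_scenario <- function(x, ...) {
  cat(sprintf("<rf_scenario:%s> %d frames at %g fps (%.2f s), %d perturbation(s)\n",
              x$generator, nrow(x$frames), x$fps, max(x$frames$t),
              length(x$perturbations)))
  invisible(x)
}

scenario_times <- function(duration, fps) {
  seq(0, duration, by = 1 / fps)
}

#' Constant-velocity straight approach to a fixated ground point
#'
#' The eye travels forward (+y) at constant speed and height while fixating
#' a ground point placed `start_distance` metres from the starting ground
#' position, at the signed angle `fixation_offset_angle` from the direction
#' of travel. Positive offsets put the fixation point to the left of the
#' path, so the eye passes to its right (positive
#' `velocity_fixation_angle`, counter-clockwise retinal flow, positive
#' foveal curl).
#'
#' @param eye_height eye height in metres (default 1.25).
#' @param speed walking speed in m/s (default 1.25).
#' @param fixation_offset_angle signed offset in degrees (default 0: the
#'   fixation point lies on the ground track).
#' @param duration scenario length in seconds.
#' @param fps frames per second.
#' @param start_distance ground distance from start to fixation point (m).
#' @return an `rf_scenario`.
#' @export
straight_approach <- function(eye_height = 1.25, speed = 1.25,
                              fixation_offset_angle = 0, duration = 3,
                              fps = 30, start_distance = 5) {
  if (speed <= 0) rf_error("rf_scenario_error", "speed must be positive")
  t <- scenario_times(duration, fps)
  a <- fixation_offset_angle * pi / 180
  frames <- data.frame(
    t = t, cx = 0, cy = speed * t, cz = eye_height,
    fx = -start_distance * sin(a), fy = start_distance * cos(a)
  )
  new_scenario(frames, fps, speed, eye_height, "straight_approach",
               params = list(speed = speed, eye_height = eye_height,
                             fixation_offset_angle = fixation_offset_angle,
                             start_distance = start_distance))
}

default_fixation_ahead <- function(base_speed, duration) {
  base_speed * duration + 2
}

#' Sinusoidally displaced forward trajectory
#'
#' Straight forward motion plus a sinusoidal displacement on the vertical
#' or horizontal (lateral) axis, fixating a single ground point ahead.
#'
#' @param axis `"vertical"` or `"horizontal"`.
#' @param amplitude displacement amplitude in metres (>= 0; must stay below
#'   `eye_height` on the vertical axis).
#' @param frequency oscillation frequency in Hz.
#' @param base_speed forward speed in m/s.
#' @param duration,fps scenario length (s) and frame rate.
#' @param eye_height mean eye height in metres.
#' @param fixation_ahead ground y of the fixated point; default just beyond
#'   the end of the path.
#' @return an `rf_scenario`.
#' @export
sinusoid_trajectory <- function(axis = c("vertical", "horizontal"), amplitude,
                                frequency, base_speed, duration = 4, fps = 30,
                                eye_height = 1.25, fixation_ahead = NULL) {
  axis <- match.arg(axis)
  if (amplitude < 0) rf_error("rf_scenario_error", "amplitude must be >= 0")
  if (axis == "vertical" && amplitude >= eye_height)
    rf_error("rf_scenario_error", "vertical amplitude must stay below eye height")
  if (is.null(fixation_ahead))
    fixation_ahead <- default_fixation_ahead(base_speed, duration)
  t <- scenario_times(duration, fps)
  osc <- amplitude * sin(2 * pi * frequency * t)
  frames <- data.frame(
    t = t,
    cx = if (axis == "horizontal") osc else 0,
    cy = base_speed * t,
    cz = eye_height + if (axis == "vertical") osc else 0,
    fx = 0, fy = fixation_ahead
  )
  new_scenario(frames, fps, base_speed, eye_height, "sinusoid_trajectory",
               params = list(axis = axis, amplitude = amplitude,
                             frequency = frequency, base_speed = base_speed,
                             fixation_ahead = fixation_ahead))
}

#' Corkscrew (circular frontal-plane) trajectory
#'
#' Forward motion combined with a circular displacement in the frontal
#' plane: vertical and horizontal sinusoids of equal amplitude in
#' quadrature.
#'
#' @param radius circle radius in metres (>= 0; below `eye_height`).
#' @param angular_rate revolutions per second (Hz).
#' @param base_speed forward speed in m/s.
#' @inheritParams sinusoid_trajectory
#' @return an `rf_scenario`.
#' @export
corkscrew_trajectory <- function(radius, angular_rate, base_speed,
                                 duration = 4, fps = 30, eye_height = 1.25,
                                 fixation_ahead = NULL) {
  if (radius < 0) rf_error("rf_scenario_error", "radius must be >= 0")
  if (radius >= eye_height)
    rf_error("rf_scenario_error", "radius must stay below eye height")
  if (is.null(fixation_ahead))
    fixation_ahead <- default_fixation_ahead(base_speed, duration)
  t <- scenario_times(duration, fps)
  ph <- 2 * pi * angular_rate * t
  frames <- data.frame(
    t = t,
    cx = radius * cos(ph) - radius,  # start on the circle at zero offset
    cy = base_speed * t,
    cz = eye_height + radius * sin(ph),
    fx = 0, fy = fixation_ahead
  )
  new_scenario(frames, fps, base_speed, eye_height, "corkscrew_trajectory",
               params = list(radius = radius, angular_rate = angular_rate,
                             base_speed = base_speed,
                             fixation_ahead = fixation_ahead))
}

# piecewise-constant schedule of ground fixation points ahead of the walker
make_fixation_schedule <- function(t, cy, gaze_distance, fix_duration) {
  onsets <- seq(0, max(t), by = fix_duration)
  seg <- findInterval(t, onsets)
  fy <- numeric(length(t))
  for (s in unique(seg)) {
    first <- which(seg == s)[1]
    fy[seg == s] <- cy[first] + gaze_distance
  }
  data.frame(fx = 0, fy = fy)
}

#' Gait-like head trajectory
#'
#' Forward progression at `walk_speed` with a vertical velocity oscillation
#' at the step frequency (default 2 Hz, the natural footstep rate) whose
#' peak magnitude is `vertical_peak_vel_fraction` of the walking speed
#' (default 0.5, matching the head oscillation of natural walking), plus a
#' smaller lateral sway at half the step frequency (alternating feet). Gaze
#' is re-fixated every `fix_duration` seconds on a ground point
#' `gaze_distance` metres ahead.
#'
#' @param walk_speed overall walking speed in m/s (> 0).
#' @param step_frequency footstep rate in Hz (default 2).
#' @param vertical_peak_vel_fraction peak vertical velocity as a fraction of
#'   `walk_speed` (default 0.5).
#' @param duration,fps scenario length (s) and frame rate.
#' @param seed integer seed for the optional phase jitter.
#' @param eye_height mean eye height in metres (default 1.25).
#' @param lateral_peak_vel_fraction peak lateral velocity fraction at
#'   `step_frequency / 2` (default 0.2).
#' @param phase_jitter standard deviation (radians) of smooth per-cycle
#'   phase noise; 0 (default) gives a strictly periodic trajectory.
#' @param gaze_distance,fix_duration fixation schedule parameters (m, s).
#' @return an `rf_scenario`.
#' @export
gait_head_trajectory <- function(walk_speed, step_frequency = 2,
                                 vertical_peak_vel_fraction = 0.5,
                                 duration = 4, fps = 100, seed = NULL,
                                 eye_height = 1.25,
                                 lateral_peak_vel_fraction = 0.2,
                                 phase_jitter = 0, gaze_distance = 3,
                                 fix_duration = 1) {
  if (walk_speed <= 0) rf_error("rf_scenario_error", "walk_speed must be positive")
  t <- scenario_times(duration, fps)
  f <- step_frequency
  ph_v <- 2 * pi * f * t
  ph_l <- pi * f * t
  if (phase_jitter > 0) {
    n_cyc <- ceiling(duration * f) + 1
    jit <- with_seed(seed, stats::rnorm(n_cyc, 0, phase_jitter))
    jt <- stats::approx(seq(0, duration, length.out = n_cyc), jit, xout = t)$y
    ph_v <- ph_v + jt
    ph_l <- ph_l + jt / 2
  }
  amp_v <- vertical_peak_vel_fraction * walk_speed / (2 * pi * f)
  amp_l <- lateral_peak_vel_fraction * walk_speed / (pi * f)
  fx_sched <- make_fixation_schedule(t, walk_speed * t, gaze_distance,
                                     fix_duration)
  frames <- data.frame(
    t = t,
    cx = amp_l * sin(ph_l),
    cy = walk_speed * t,
    cz = eye_height - amp_v * cos(ph_v),
    fx = fx_sched$fx, fy = fx_sched$fy
  )
  new_scenario(frames, fps, walk_speed, eye_height, "gait_head_trajectory",
               params = list(walk_speed = walk_speed,
                             step_frequency = step_frequency,
                             vertical_peak_vel_fraction = vertical_peak_vel_fraction,
                             lateral_peak_vel_fraction = lateral_peak_vel_fraction,
                             phase_jitter = phase_jitter,
                             gaze_distance = gaze_distance,
                             fix_duration = fix_duration),
               seed = seed)
}

#' Gaze perturbation descriptor
#'
#' @param kind `"slip"` (slow drift of the fixation point) or `"saccade"`
#'   (rapid gaze rotation overriding fixation).
#' @param onset,duration perturbation window in seconds.
#' @param direction length-2 retinal direction of the gaze sweep, in chart
#'   coordinates (x toward the left visual field, y upward, see [chart()]);
#'   e.g. `c(1, -1)` sweeps down and to the left. Need not be normalized.
#' @param rate rotation rate in deg/s (saccade).
#' @param magnitude total sweep in degrees (slip).
#' @return an object of class `rf_perturbation`.
#' @export
perturbation <- function(kind = c("slip", "saccade"), onset, duration,
                         direction, rate = NULL, magnitude = NULL) {
  kind <- match.arg(kind)
  if (duration <= 0) rf_error("rf_scenario_error", "perturbation duration must be positive")
  nd <- sqrt(sum(direction^2))
  if (nd < 1e-12) rf_error("rf_scenario_error", "perturbation direction must be non-zero")
  if (kind == "slip" && is.null(magnitude))
    rf_error("rf_scenario_error", "slip needs a total magnitude in degrees")
  if (kind == "saccade" && is.null(rate))
    rf_error("rf_scenario_error", "saccade needs a rate in deg/s")
  structure(list(kind = kind, onset = onset, duration = duration,
                 direction = direction / nd, rate = rate,
                 magnitude = magnitude),
            class = "rf_perturbation")
}

#' Inject a slip or saccade perturbation into a scenario
#'
#' During the perturbation window the gaze ray is swept away from the
#' scheduled fixation point in the stated retinal direction: uniformly over
#' the window to a total of `magnitude` degrees for slip (so a 1 degree
#' slip over 250 ms adds 4 deg/s of image motion at the fovea), or at
#' `rate` deg/s for a saccade (so the foveal image speed equals the saccade
#' speed). The per-frame fixation columns `fx`, `fy` are replaced by the
#' ground intersection of the swept gaze; the scheduled fixation is kept in
#' `fx0`, `fy0`.
#'
#' @param scenario an `rf_scenario`.
#' @param pert an [perturbation()].
#' @return the perturbed `rf_scenario`.
#' @export
apply_perturbation <- function(scenario, pert) {
  stopifnot(inherits(pert, "rf_perturbation"))
  trial <- scenario
  trial$perturbations <- c(scenario$perturbations, list(pert))
  validate_scenario(trial)  # window bounds + same-kind overlap
  fr <- scenario$frames
  idx <- which(fr$t > pert$onset - 1e-9 &
                 fr$t <= pert$onset + pert$duration + 1e-9)
  # frames whose flow pair overlaps the window (including the return to the
  # scheduled fixation one frame after it) are flagged as perturbed; a
  # zero-magnitude perturbation leaves the scenario unchanged
  total <- if (pert$kind == "slip") pert$magnitude else pert$rate * pert$duration
  flag <- if (total > 0)
    fr$t > pert$onset - 1e-9 &
      fr$t <= pert$onset + pert$duration + 1 / scenario$fps + 1e-9
  else rep(FALSE, nrow(fr))
  sweep_of <- function(tt) {
    dt <- pmin(pmax(tt - pert$onset, 0), pert$duration)
    if (pert$kind == "slip") pert$magnitude * dt / pert$duration
    else pert$rate * dt
  }
  for (i in idx) {
    s <- sweep_of(fr$t[i]) * pi / 180
    if (s <= 0) next
    pose <- orient_to_fixation(c(fr$cx[i], fr$cy[i], fr$cz[i]),
                               c(fr$fx0[i], fr$fy0[i]))
    d <- cos(s) * pose$forward +
      sin(s) * (pert$direction[1] * (-pose$right) + pert$direction[2] * pose$up)
    if (d[3] >= -1e-9)
      rf_error("rf_scenario_error",
               "perturbation sweeps the gaze to or above the horizon")
    t_hit <- -pose$center[3] / d[3]
    fr$fx[i] <- pose$center[1] + t_hit * d[1]
    fr$fy[i] <- pose$center[2] + t_hit * d[2]
  }
  fr$perturbed <- fr$perturbed | flag
  scenario$frames <- fr
  scenario$perturbations <- trial$perturbations
  scenario
}

#' Synthesize a VOR calibration session with a known sensor misalignment
#'
#' Emulates the calibration procedure in which a standing subject fixates a
#' ground marker `calib_distance` metres ahead while slowly sweeping the
#' head up/down, left/right and along the diagonals. Per-frame head
#' orientations follow the sweep schedule; the true eye-in-head gaze always
#' targets the calibration point, and the recorded (sensor-frame) gaze
#' vectors are corrupted by the inverse of `true_misalignment` plus
#' optional angular noise, so that recovering the misalignment is exactly
#' the calibration problem.
#'
#' @param true_misalignment Euler angles in degrees (intrinsic X-Y-Z, see
#'   [euler_to_matrix()]) of the sensor-to-head misalignment to simulate.
#' @param sweep optional data.frame with per-frame `pitch` and `yaw` head
#'   angles in degrees; the default schedule sweeps pitch, yaw and both
#'   diagonals at `amplitude` degrees over `n_frames` frames.
#' @param calib_distance ground distance to the calibration point (default
#'   1.4 m).
#' @param noise_deg per-frame angular noise s.d. in degrees (default 0).
#' @param seed integer seed for the noise.
#' @param n_frames,fps,eye_height,amplitude default-schedule parameters.
#' @return an object of class `calibration_session`: list with `frames`
#'   (`t`, head quaternion `qw,qx,qy,qz`, eye center `ex,ey,ez`, raw gaze
#'   `gx,gy,gz`), `calib_point`, `truncation_distance`. A single-axis sweep
#'   sets the attribute `degenerate_sweep` and warns (rotation about the
#'   gaze axis is unobservable).
#' @export
synth_calibration_session <- function(true_misalignment = c(0, 0, 0),
                                      sweep = NULL, calib_distance = 1.4,
                                      noise_deg = 0, seed = NULL,
                                      n_frames = 240, fps = 60,
                                      eye_height = 1.5, amplitude = 20) {
  if (is.null(sweep)) {
    n4 <- ceiling(n_frames / 4)
    u <- seq(0, 2 * pi, length.out = n4)
    s <- amplitude * sin(u)
    sweep <- data.frame(
      pitch = c(s, rep(0, n4), s / sqrt(2), s / sqrt(2)),
      yaw = c(rep(0, n4), s, s / sqrt(2), -s / sqrt(2))
    )[seq_len(n_frames), ]
  }
  degenerate <- stats::sd(sweep$pitch) < 1e-9 || stats::sd(sweep$yaw) < 1e-9
  if (degenerate)
    warning("sweep covers a single rotation axis; the misalignment component about the gaze axis is unobservable")
  n <- nrow(sweep)
  center <- c(0, 0, eye_height)
  calib_point <- c(0, calib_distance, 0)
  g_world <- calib_point - center
  g_world <- g_world / sqrt(sum(g_world^2))
  R_mis <- euler_to_matrix(true_misalignment)
  noise_angles <- if (noise_deg > 0)
    with_seed(seed, list(ang = stats::rnorm(n, 0, noise_deg * pi / 180),
                         dir = stats::runif(n, 0, 2 * pi)))
  else NULL
  frames <- data.frame(t = (seq_len(n) - 1) / fps,
                       qw = NA_real_, qx = NA_real_, qy = NA_real_, qz = NA_real_,
                       ex = center[1], ey = center[2], ez = center[3],
                       gx = NA_real_, gy = NA_real_, gz = NA_real_)
  for (i in seq_len(n)) {
    R_head <- euler_to_matrix(c(sweep$pitch[i], 0, sweep$yaw[i]))
    g_eih <- as.numeric(t(R_head) %*% g_world)
    g_raw <- as.numeric(t(R_mis) %*% g_eih)
    if (!is.null(noise_angles)) {
      # random rotation about an axis perpendicular to the gaze
      ref <- if (abs(g_raw[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- ref - sum(ref * g_raw) * g_raw
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(g_raw[2] * e1[3] - g_raw[3] * e1[2],
              g_raw[3] * e1[1] - g_raw[1] * e1[3],
              g_raw[1] * e1[2] - g_raw[2] * e1[1])
      ax <- cos(noise_angles$dir[i]) * e1 + sin(noise_angles$dir[i]) * e2
      g_raw <- as.numeric(rotation_about_axis(ax, noise_angles$ang[i]) %*% g_raw)
    }
    q <- matrix_to_quat(R_head)
    frames[i, c("qw", "qx", "qy", "qz")] <- q
    frames[i, c("gx", "gy", "gz")] <- g_raw
  }
  structure(list(frames = frames, calib_point = calib_point,
                 truncation_distance = 10),
            class = "calibration_session",
            true_misalignment = true_misalignment,
            degenerate_sweep = degenerate)
}

#' @export
print.calibration_session <- function(x, ...) {
  cat(sprintf("<calibration_session> %d frames, calibration point (%.2f, %.2f) m\n",
              nrow(x$frames), x$calib_point[1], x$calib_point[2]))
  invisible(x)
}

#' Export a scenario's pose table
#'
#' @param scenario an `rf_scenario`.
#' @return data.frame in the [write_pose_table()] layout.
#' @export
scenario_pose_table <- function(scenario) {
  fr <- scenario$frames
  data.frame(t = fr$t, cx = fr$cx, cy = fr$cy, cz = fr$cz,
             fx = fr$fx, fy = fr$fy)
}
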