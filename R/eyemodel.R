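# Geometry of the fixating spherical pinhole eye: minimal-torsion
# orientation toward a ground fixation point, field-of-view cone, and
# projection of ground points to retinal polar coordinates.
#
# World frame: x right, y forward, z up, ground plane at z = 0. The pose
# position is the optical station point (the pinhole pupil); the spherical
# retina of the stated radius sits behind it with the fovea at the opposite
# pole. Because every ray passes through the single pupil point, retinal
# polar coordinates reduce to the spherical direction of the incoming ray
# and are independent of the eye radius.

#' Orient a fixating eye toward a ground point with minimal torsion
#'
#' Builds the eye pose whose optic axis passes through `fixation`. The
#' zero-torsion reference is the horizontal (gravity-referenced) direction
#' at the gaze's own azimuth: the eye is yawed to the fixation azimuth and
#' then pitched down to the fixation along the geodesic, a single rotation
#' about the horizontal axis perpendicular to the gaze azimuth. This
#' leaves the eye's equator horizontal (no twist about the optic axis) and
#' makes retinal coordinates equivariant under rigid motions of the ground
#' plane. Straight-down gaze (fixation at the eye's vertical projection) is
#' the degenerate case: the azimuth is undefined and the equator direction
#' is carried over from `prev_pose` (an error if there is none).
#'
#' @param center eye position (pupil), length-3, `center[3] > 0` metres.
#' @param fixation fixated ground point, length 2 or 3 (z must be 0).
#' @param radius eye radius in mm (default 12; retinal coordinates do not
#'   depend on it because every ray passes through the single pupil point).
#' @param prev_pose previous frame's [eye_pose], used only for straight-down
#'   gaze.
#' @return an object of class `eye_pose`: list with `center`, `fixation`,
#'   `radius`, the gaze rotation `R` (columns = eye right/forward/up axes in
#'   world coordinates), and unit axes `right`, `forward` (optic axis), `up`.
#' @export
orient_to_fixation <- function(center, fixation, radius = 12, prev_pose = NULL) {
  center <- as.numeric(center)
  if (length(fixation) == 2) fixation <- c(fixation, 0)
  fixation <- as.numeric(fixation)
  if (center[3] <= 0) rf_error("rf_pose_error", "eye center must be above the ground plane")
  if (abs(fixation[3]) > 1e-9) rf_error("rf_pose_error", "fixation must lie on the ground plane")
  g <- fixation - center
  ng <- sqrt(sum(g^2))
  if (ng < 1e-12) rf_error("rf_pose_error", "fixation coincides with eye center")
  g <- g / ng
  hn <- sqrt(g[1]^2 + g[2]^2)
  if (hn < 1e-12) {
    # straight-down gaze: keep the previous frame's (horizontal) equator
    if (is.null(prev_pose))
      rf_error("rf_pose_error",
               "straight-down gaze and no previous pose to take the equator from")
    right <- c(prev_pose$right[1], prev_pose$right[2], 0)
    rn <- sqrt(sum(right^2))
    if (rn < 1e-12)
      rf_error("rf_pose_error", "previous pose has no horizontal equator direction")
    right <- right / rn
  } else {
    # horizontal right-hand direction perpendicular to the gaze azimuth
    right <- c(g[2], -g[1], 0) / hn
  }
  up <- c(right[2] * g[3] - right[3] * g[2],
          right[3] * g[1] - right[1] * g[3],
          right[1] * g[2] - right[2] * g[1])
  R <- cbind(right, g, up, deparse.level = 0)
  structure(list(
    center = center, fixation = fixation, radius = radius, R = R,
    right = right,
    forward = g,
    up = up
  ), class = "eye_pose")
}

#' @export
print.eye_pose <- function(x, ...) {
  cat(sprintf("<eye_pose> center (%.3g, %.3g, %.3g) m, fixation (%.3g, %.3g), declination %.2f deg\n",
              x$center[1], x$center[2], x$center[3], x$fixation[1], x$fixation[2],
              gaze_declination(x)))
  invisible(x)
}

#' Gaze declination below the horizontal
#'
#' @param pose an [eye_pose].
#' @return angle in degrees (positive = looking down).
#' @export
gaze_declination <- function(pose) {
  asin(max(-1, min(1, -pose$forward[3]))) * 180 / pi
}

#' Ground intersection of the field-of-view cone
#'
#' Samples the intersection of the cone with half-angle `fov_radius_deg`
#' about the optic axis with the ground plane. When the cone's upper edge
#' reaches or rises above the horizontal the intersection is unbounded; rays
#' at or above the horizon, and intersections farther than `clip` metres from
#' the eye's ground position, are clipped to `clip` and flagged.
#'
#' @param pose an [eye_pose].
#' @param fov_radius_deg cone half-angle in degrees (default 60).
#' @param n number of samples around the cone.
#' @param clip maximum ground distance in metres (default 50).
#' @return list with `points` (n x 2 ground coordinates), `bounded` (logical:
#'   all cone rays hit the ground within `clip`), and `clipped` (per-sample
#'   logical).
#' @export
fov_ground_boundary <- function(pose, fov_radius_deg = 60, n = 360, clip = 50) {
  gam <- fov_radius_deg * pi / 180
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  # cone directions: cos(gam) * forward + sin(gam) * (cos(phi) right + sin(phi) up)
  D <- cos(gam) * matrix(pose$forward, n, 3, byrow = TRUE) +
    sin(gam) * (outer(cos(phi), pose$right) + outer(sin(phi), pose$up))
  dz <- D[, 3]
  pts <- matrix(NA_real_, n, 2)
  clipped <- rep(FALSE, n)
  below <- dz < -1e-12
  t_hit <- ifelse(below, -pose$center[3] / dz, Inf)
  gx <- pose$center[1] + t_hit * D[, 1]
  gy <- pose$center[2] + t_hit * D[, 2]
  gdist <- sqrt((gx - pose$center[1])^2 + (gy - pose$center[2])^2)
  ok <- below & gdist <= clip
  pts[ok, ] <- cbind(gx[ok], gy[ok])
  # clip: horizontal direction of the ray, at distance `clip` on the ground
  far <- !ok
  if (any(far)) {
    hn <- sqrt(D[far, 1]^2 + D[far, 2]^2)
    hn[hn < 1e-12] <- 1
    pts[far, ] <- cbind(pose$center[1] + clip * D[far, 1] / hn,
                        pose$center[2] + clip * D[far, 2] / hn)
    clipped[far] <- TRUE
  }
  list(points = pts, bounded = !any(clipped), clipped = clipped)
}

# Vectorized projection of 3D points through the pinhole. Returns theta
# (radians, 0 = rightward on the eye's equator, pi/2 = upper visual field),
# rho (degrees from the fovea) and flags. Internal workhorse for
# project_point()/project_grid().
project_points_raw <- function(pose, P) {
  P <- matrix(as.numeric(P), ncol = 3)
  U <- P - matrix(pose$center, nrow(P), 3, byrow = TRUE)
  nu <- sqrt(rowSums(U^2))
  degen <- nu < 1e-12
  nu[degen] <- 1
  # theta = 0 points toward the LEFT visual field (anatomical retinal chart
  # orientation, see chart()); theta = pi/2 is the upper visual field
  a_l <- -(U %*% pose$right) / nu
  a_f <- (U %*% pose$forward) / nu
  a_u <- (U %*% pose$up) / nu
  rho <- atan2(sqrt(a_l^2 + a_u^2), a_f) * 180 / pi
  theta <- atan2(a_u, a_l)
  behind <- a_f <= 0
  data.frame(theta = as.numeric(theta), rho = as.numeric(rho),
             behind = as.numeric(behind) > 0, degenerate = degen)
}

#' Project a ground point to retinal polar coordinates
#'
#' Traces the ray from `p` through the pinhole pupil onto the spherical
#' retina and expresses the landing point in retinal polar coordinates:
#' `rho`, the great-circle distance from the fovea in degrees of visual
#' angle (equal to the angle between the incoming ray and the optic axis),
#' and `theta`, the angle from the eye's transverse-plane equator, with
#' `theta = pi/2` the upper visual field and `theta = 0` the left visual
#' field (the retinal-map orientation used throughout; see [chart()]). The
#' 180-degree display flip of the physical retinal image is already
#' applied, so the upper visual field is at the top.
#'
#' @param pose an [eye_pose].
#' @param p ground point, length 2 or 3 (z = 0).
#' @param fov field-of-view radius in degrees; points with `rho > fov` are
#'   out of view.
#' @return list with `theta` (radians), `rho` (degrees) and `in_view`
#'   (logical), or an error for the degenerate ray (`p` at the pupil).
#' @export
project_point <- function(pose, p, fov = 60) {
  if (length(p) == 2) p <- c(p, 0)
  res <- project_points_raw(pose, matrix(p, 1, 3))
  if (res$degenerate[1]) rf_error("rf_ray_error", "point coincides with the pupil")
  if (res$behind[1]) rf_error("rf_ray_error", "point lies behind the pupil plane")
  list(theta = res$theta[1], rho = res$rho[1], in_view = res$rho[1] <= fov)
}

#' Regular grid of points on the ground plane
#'
#' @param spacing node spacing in metres (default 0.25).
#' @param xlim,ylim ranges in metres.
#' @return data.frame with columns `id`, `x`, `y`, `z` (all z = 0).
#' @export
ground_grid <- function(spacing = 0.25, xlim = c(-5, 5), ylim = c(0, 10)) {
  if (spacing <= 0) rf_error("rf_grid_error", "spacing must be positive")
  gx <- seq(xlim[1], xlim[2], by = spacing)
  gy <- seq(ylim[1], ylim[2], by = spacing)
  df <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  data.frame(id = seq_len(nrow(df)), x = df$x, y = df$y, z = 0)
}

#' Project a ground grid through the eye
#'
#' Projects every grid point and returns the in-view subset with stable
#' point ids, so the same scene point can be matched across frames (and
#' recognised on re-entry after leaving the field of view).
#'
#' @param pose an [eye_pose].
#' @param grid a [ground_grid()] data.frame (columns `id`, `x`, `y`).
#' @param fov field-of-view radius in degrees.
#' @return data.frame with columns `id`, `theta` (radians), `rho` (degrees)
#'   for points with `rho <= fov` in front of the pupil plane.
#' @export
project_grid <- function(pose, grid, fov = 60) {
  P <- cbind(grid$x, grid$y, 0)
  res <- project_points_raw(pose, P)
  keep <- !res$behind & !res$degenerate & res$rho <= fov
  data.frame(id = grid$id[keep], theta = res$theta[keep], rho = res$rho[keep])
}

# Ground intersection of retinal chart locations: inverse of the projection.
# chart_x/chart_y in degrees (chart x toward the left visual field); returns
# ground x, y and ok flag (FALSE for rays at or above the horizon).
unproject_chart <- function(pose, chart_x, chart_y) {
  rho <- sqrt(chart_x^2 + chart_y^2) * pi / 180
  theta <- atan2(chart_y, chart_x)
  D <- cos(rho) %o% pose$forward +
    (sin(rho) * cos(theta)) %o% (-pose$right) +
    (sin(rho) * sin(theta)) %o% pose$up
  dz <- D[, 3]
  ok <- dz < -1e-12
  t_hit <- ifelse(ok, -pose$center[3] / dz, NA_real_)
  data.frame(gx = pose$center[1] + t_hit * D[, 1],
             gy = pose$center[2] + t_hit * D[, 2],
             ok = ok)
}

#' Read and write eye trajectory tables
#'
#' One row per frame with columns `t`, `cx`, `cy`, `cz` (eye position, m)
#' and `fx`, `fy` (ground fixation point, m).
#'
#' @param frames data.frame in the above layout.
#' @param path file path.
#' @return the reader returns the data.frame; the writer returns `path`
#'   invisibly.
#' @export
write_pose_table <- function(frames, path) {
  utils::write.csv(frames[, c("t", "cx", "cy", "cz", "fx", "fy")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_table
#' @export
read_pose_table <- function(path) {
  utils::read.csv(path)
}
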