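# Per-frame retinal flow and its features. Retinal positions live on the
# azimuthal-equidistant chart centered on the fovea: x = rho * cos(theta),
# y = rho * sin(theta), in degrees of visual angle, upper visual field at
# positive y and the LEFT visual field at positive x (the anatomical
# retinal-surface orientation; see chart()). Planar curl/divergence are
# computed on this chart; the metric distortion of the chart is below ~5%
# out to 60 degrees eccentricity and is documented as an approximation.

#' Azimuthal-equidistant retinal chart
#'
#' Maps retinal polar coordinates (theta, rho) to planar chart coordinates
#' `x = rho * cos(theta)`, `y = rho * sin(theta)` (degrees), and back. The
#' inverse is defined for `rho < 180`.
#'
#' The chart is drawn in the orientation retinal maps are conventionally
#' reported in: the upper visual field at the top (`theta = pi/2`) and the
#' *left* visual field at `theta = 0` (positive x). On this chart,
#' fixating a point to the left of the travel path produces positive curl
#' around the fovea, and fixation to the right produces negative curl. On a
#' chart with x toward the right visual field all curl values would change
#' sign; the sign convention is fixed here once so the curl field and every
#' derived feature agree.
#'
#' @param theta angle from the eye's equator, radians (vectorized).
#' @param rho great-circle eccentricity from the fovea, degrees.
#' @return `chart()`: data.frame with `x`, `y`; `unchart()`: data.frame with
#'   `theta`, `rho`.
#' @export
chart <- function(theta, rho) {
  if (any(rho < 0)) rf_error("rf_chart_error", "rho must be non-negative")
  data.frame(x = rho * cos(theta), y = rho * sin(theta))
}

#' @rdname chart
#' @param x,y chart coordinates in degrees.
#' @export
unchart <- function(x, y) {
  data.frame(theta = atan2(y, x), rho = sqrt(x^2 + y^2))
}

#' Frame-to-frame retinal point flow
#'
#' Chart displacement of each tracked point between consecutive projections.
#' Points absent from the previous frame (newly visible) carry undefined
#' flow on their first visible frame and are omitted.
#'
#' @param prev,curr data.frames with columns `id`, `theta`, `rho` as
#'   returned by [project_grid()].
#' @param fps frames per second (> 0).
#' @return data.frame with `id`, chart position `x`, `y` at the current
#'   frame (degrees), displacement `dx`, `dy` (deg/frame) and velocity
#'   `vx`, `vy` (deg/s).
#' @export
point_flow <- function(prev, curr, fps) {
  if (fps <= 0) rf_error("rf_fps_error", "fps must be positive")
  shared <- intersect(prev$id, curr$id)
  ip <- match(shared, prev$id)
  ic <- match(shared, curr$id)
  cp <- chart(prev$theta[ip], prev$rho[ip])
  cc <- chart(curr$theta[ic], curr$rho[ic])
  data.frame(id = shared,
             x = cc$x, y = cc$y,
             dx = cc$x - cp$x, dy = cc$y - cp$y,
             vx = (cc$x - cp$x) * fps, vy = (cc$y - cp$y) * fps)
}

#' Retinal flow frame: scattered flow interpolated to a regular grid
#'
#' Interpolates scattered retinal point velocities onto the square chart
#' grid spanning `[-fov, fov]` at `spacing` degrees, masks nodes beyond
#' `fov` eccentricity or outside the convex hull of the scatter, and
#' computes the divergence and curl scalar fields.
#'
#' @param points n x 2 matrix of chart positions (degrees).
#' @param velocities n x 2 matrix of chart velocities (deg/s).
#' @param fov field-of-view radius in degrees (default 60).
#' @param spacing retinal grid spacing in degrees (default 1).
#' @param fps frames per second the velocities were scaled with.
#' @param t frame time in seconds.
#' @param metric `"spherical"` (default) applies the first-order metric
#'   correction of the azimuthal-equidistant chart to the divergence and
#'   curl (the chart compresses azimuthal distances by `sin(rho)/rho`, so
#'   purely planar operators acquire an error that grows with
#'   eccentricity); `"planar"` uses the uncorrected planar operators. The
#'   correction vanishes at the fovea, so foveal features are identical
#'   under both; the location of the divergence maximum (tens of degrees
#'   eccentric) is where it matters.
#' @return an object of class `retinal_flow_frame`: list with `t`, `fps`,
#'   `spacing`, `fov`, `grid_flow` ([vector_field()], deg/s), `curl_field`
#'   and `div_field` ([scalar_field()], 1/s).
#' @export
flow_frame <- function(points, velocities, fov = 60, spacing = 1, fps = 30,
                       t = NA_real_, metric = c("spherical", "planar")) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  if (nrow(points) < 3)
    rf_error("rf_degenerate_error", "need at least 3 flow points")
  ax <- seq(-fov, fov, by = spacing)
  gf <- interpolate_scattered(points, as.matrix(velocities),
                              list(x = ax, y = ax))
  # restrict to the field of view
  rr <- sqrt(outer(ax^2, ax^2, "+"))
  gf$mask <- gf$mask & (rr <= fov + 1e-9)
  gf$vx[!gf$mask] <- NA_real_
  gf$vy[!gf$mask] <- NA_real_
  curl_field <- curl_z(gf)
  div_field <- divergence(gf)
  if (metric == "spherical") {
    # first-order spherical correction on the equidistant chart:
    # div_s = div_chart + u_rho (cot rho - 1/rho), and the analogous term
    # with the tangential component for the curl; both vanish at rho -> 0
    cx <- outer(gf$x, rep(1, length(gf$y)))
    cy <- outer(rep(1, length(gf$x)), gf$y)
    rn <- pmax(sqrt(cx^2 + cy^2), 1e-9)
    rad <- rn * pi / 180
    fac <- ifelse(rad < 1e-6, 0, 1 / tan(rad) - 1 / rad)  # 1/rad units
    u_rho <- (gf$vx * cx + gf$vy * cy) / rn * pi / 180    # rad/s
    u_phi <- (gf$vy * cx - gf$vx * cy) / rn * pi / 180
    div_field$value <- div_field$value + u_rho * fac
    curl_field$value <- curl_field$value + u_phi * fac
  }
  structure(list(
    t = t, fps = fps, spacing = spacing, fov = fov, metric = metric,
    grid_flow = gf,
    curl_field = curl_field,
    div_field = div_field
  ), class = "retinal_flow_frame")
}

#' @export
print.retinal_flow_frame <- function(x, ...) {
  cat(sprintf("<retinal_flow_frame> t=%.3fs, %d deg fov at %g deg spacing, %d valid nodes\n",
              x$t, x$fov, x$spacing, sum(x$grid_flow$mask)))
  invisible(x)
}

# index of the grid node at the fovea (chart origin)
fovea_node <- function(field) {
  c(which.min(abs(field$x)), which.min(abs(field$y)))
}

#' Mean curl around the fovea
#'
#' Average of the curl field over grid nodes within `window_deg` of the
#' fovea. During gaze-stabilized locomotion its sign reports whether the
#' walker's trajectory passes left (negative) or right (positive) of the
#' fixation point, and its magnitude grows with the angular offset.
#'
#' @param frame a [flow_frame()].
#' @param window_deg averaging radius in degrees (default 2).
#' @return mean curl in 1/s.
#' @export
foveal_curl <- function(frame, window_deg = 2) {
  cf <- frame$curl_field
  rr <- sqrt(outer(cf$x^2, cf$y^2, "+"))
  sel <- cf$mask & rr <= window_deg
  if (!any(sel)) rf_error("rf_window_error", "no valid curl nodes within the foveal window")
  mean(cf$value[sel])
}

#' Flow speed at the fovea
#'
#' Magnitude of the interpolated grid flow at the chart origin, in deg/s.
#' Zero (to numerical tolerance) during perfect fixation of a static point;
#' equal to the gaze sweep rate during slip or saccade perturbations.
#'
#' @param frame a [flow_frame()].
#' @return speed in deg/s.
#' @export
foveal_speed <- function(frame) {
  gf <- frame$grid_flow
  ij <- fovea_node(gf)
  if (!gf$mask[ij[1], ij[2]])
    rf_error("rf_window_error", "fovea node is masked")
  sqrt(gf$vx[ij[1], ij[2]]^2 + gf$vy[ij[1], ij[2]]^2)
}

#' Point of maximum retinal divergence
#'
#' Argmax of the divergence field over valid nodes (ties broken toward the
#' fovea), refined to sub-node accuracy by a quadratic fit over the 3 x 3
#' neighbourhood. With an [eye_pose] the retinal location is also traced
#' back to the ground plane; the ground projection of the eye's velocity
#' vector passes through this point.
#'
#' @param frame a [flow_frame()].
#' @param pose optional [eye_pose] for the ground back-projection.
#' @return list with chart location `x`, `y` (deg), polar `theta`, `rho`,
#'   `value` (1/s), `boundary` (TRUE when the argmax sits on the valid-region
#'   boundary, where the refinement is unreliable), and `ground` (length-2
#'   ground point or `NULL`).
#' @export
max_divergence <- function(frame, pose = NULL) {
  df <- frame$div_field
  if (!any(df$mask)) rf_error("rf_window_error", "divergence field has no valid nodes")
  v <- df$value
  v[!df$mask] <- -Inf
  top <- max(v)
  cand <- which(v >= top - 1e-12, arr.ind = TRUE)
  if (nrow(cand) > 1) {  # tie-break: nearest to the fovea
    d2 <- df$x[cand[, 1]]^2 + df$y[cand[, 2]]^2
    cand <- cand[which.min(d2), , drop = FALSE]
  }
  i <- cand[1, 1]; j <- cand[1, 2]
  nx <- length(df$x); ny <- length(df$y)
  on_edge <- i == 1 || j == 1 || i == nx || j == ny
  if (!on_edge) {
    nb <- df$mask[(i - 1):(i + 1), (j - 1):(j + 1)]
    on_edge <- !all(nb)
  }
  hx <- mean(diff(df$x)); hy <- mean(diff(df$y))
  x0 <- df$x[i]; y0 <- df$y[j]
  if (!on_edge) {
    # quadratic surface through the 3x3 neighbourhood (local coordinates)
    xs <- rep(c(-hx, 0, hx), times = 3)
    ys <- rep(c(-hy, 0, hy), each = 3)
    zs <- as.vector(df$value[(i - 1):(i + 1), (j - 1):(j + 1)])
    X <- cbind(1, xs, ys, xs^2, xs * ys, ys^2)
    b <- qr.solve(X, zs)
    H <- matrix(c(2 * b[4], b[5], b[5], 2 * b[6]), 2, 2)
    if (all(eigen(H, symmetric = TRUE, only.values = TRUE)$values < 0)) {
      off <- tryCatch(solve(H, -c(b[2], b[3])), error = function(e) c(0, 0))
      if (abs(off[1]) <= hx && abs(off[2]) <= hy) {
        x0 <- x0 + off[1]; y0 <- y0 + off[2]
      }
    }
  }
  pol <- unchart(x0, y0)
  ground <- NULL
  if (!is.null(pose)) {
    bp <- unproject_chart(pose, x0, y0)
    if (bp$ok[1]) ground <- c(bp$gx[1], bp$gy[1])
  }
  list(x = x0, y = y0, theta = pol$theta, rho = pol$rho,
       value = df$value[i, j], boundary = on_edge, ground = ground)
}

# shoelace area of a closed polygon
polygon_area <- function(px, py) {
  n <- length(px)
  abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
}

point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((py[i] > y) != (py[j] > y)) &&
        (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]))
      inside <- !inside
    j <- i
  }
  inside
}

#' Divergence iso-contour through the fovea
#'
#' Extracts the level set of the divergence field at the foveal divergence
#' value and returns the connected component enclosing or touching the
#' fovea. During a straight approach to a fixated ground point this contour
#' is a closed oval in the lower visual field that constricts to a point
#' when the walker is one eye height from the fixation point (45 degree
#' gaze declination) and then reopens into the upper field.
#'
#' @param frame a [flow_frame()].
#' @return list with `state` (`"closed"`, `"open"` or `"degenerate"`),
#'   `area` (deg^2; 0 when degenerate, NA when open), `level` (1/s) and
#'   `curve` (k x 2 matrix of chart coordinates, or `NULL`).
#' @export
foveal_isocontour <- function(frame) {
  df <- frame$div_field
  ij <- fovea_node(df)
  if (!df$mask[ij[1], ij[2]])
    rf_error("rf_window_error", "fovea node is masked")
  v0 <- df$value[ij[1], ij[2]]
  z <- df$value
  z[!df$mask] <- NA_real_
  rng <- range(z, na.rm = TRUE)
  # nudge the level off the exact node value so the marching-squares level
  # set is well defined; the offset shifts the contour by an infinitesimal
  # amount toward the peak side
  lev <- v0 - 1e-8 * max(diff(rng), abs(v0), 1e-12)
  segs <- grDevices::contourLines(df$x, df$y, z, levels = lev)
  sp <- frame$spacing
  if (length(segs) == 0) {
    return(list(state = "degenerate", area = 0, level = v0, curve = NULL))
  }
  # pick the component nearest the fovea, preferring ones that enclose it
  best <- NULL; best_score <- Inf
  for (s in segs) {
    d <- min(sqrt(s$x^2 + s$y^2))
    closed <- abs(s$x[1] - s$x[length(s$x)]) < 1e-9 &&
      abs(s$y[1] - s$y[length(s$y)]) < 1e-9
    contains <- closed && point_in_polygon(0, 0, s$x, s$y)
    score <- d - ifelse(contains, 1e6, 0)
    if (score < best_score) { best_score <- score; best <- s; best_closed <- closed }
  }
  d_best <- min(sqrt(best$x^2 + best$y^2))
  contains <- best_closed && point_in_polygon(0, 0, best$x, best$y)
  if (d_best > 1.5 * sp && !contains) {
    # the level set has receded from the fovea: the foveal value is the
    # local extremum and its contour has shrunk to a point
    return(list(state = "degenerate", area = 0, level = v0, curve = NULL))
  }
  curve <- cbind(best$x, best$y)
  if (!best_closed) {
    return(list(state = "open", area = NA_real_, level = v0, curve = curve))
  }
  area <- polygon_area(best$x, best$y)
  state <- if (area < sp^2) "degenerate" else "closed"
  list(state = state, area = area, level = v0, curve = curve)
}

signed_ground_angle <- function(origin, dir, target) {
  to <- target - origin
  cr <- dir[1] * to[2] - dir[2] * to[1]
  dt <- dir[1] * to[1] + dir[2] * to[2]
  atan2(cr, dt) * 180 / pi
}

#' Heading angles relative to the fixation point
#'
#' Signed angles at the eye's ground position: `velocity_fixation_angle` is
#' the angle between the ground-projected velocity direction and the
#' direction to the fixation point; `maxdiv_fixation_angle` is the same
#' construction with the direction to the ground back-projection of the
#' divergence maximum in place of the velocity direction. Positive values
#' mean the eye's path (or the maxdiv direction) passes to the right of the
#' fixation point; angles are in (-180, 180]. Because the ground projection
#' of the velocity vector passes through the point of maximum divergence,
#' the two angles agree, so the momentum direction can be read from the
#' retinal divergence pattern alone.
#'
#' @param pose an [eye_pose].
#' @param velocity 3D eye velocity in m/s (horizontal component must be
#'   non-zero).
#' @param maxdiv_ground optional length-2 ground point from
#'   [max_divergence()].
#' @return list with `velocity_fixation_angle` and `maxdiv_fixation_angle`
#'   (degrees; the latter NA when no ground point is supplied).
#' @export
heading_angles <- function(pose, velocity, maxdiv_ground = NULL) {
  vh <- velocity[1:2]
  if (sqrt(sum(vh^2)) < 1e-12)
    rf_error("rf_velocity_error", "horizontal velocity is zero")
  origin <- pose$center[1:2]
  vfa <- signed_ground_angle(origin, vh, pose$fixation[1:2])
  mfa <- NA_real_
  if (!is.null(maxdiv_ground))
    mfa <- signed_ground_angle(origin, maxdiv_ground[1:2] - origin,
                               pose$fixation[1:2])
  list(velocity_fixation_angle = wrap_angle(vfa),
       maxdiv_fixation_angle = wrap_angle(mfa))
}

#' Back-project a retinal scalar field onto the ground plane
#'
#' Maps every valid retinal grid node through the inverse projection to its
#' ground location, carrying the scalar value. Nodes whose rays do not hit
#' the ground (at or above the horizon) are dropped and counted.
#'
#' @param field a [scalar_field()] on the retinal chart.
#' @param pose the [eye_pose] the field was computed under.
#' @return data.frame with `gx`, `gy` (m), `value`, plus attribute
#'   `n_dropped`.
#' @export
backproject_scalar <- function(field, pose) {
  sel <- which(field$mask, arr.ind = TRUE)
  cx <- field$x[sel[, 1]]
  cy <- field$y[sel[, 2]]
  bp <- unproject_chart(pose, cx, cy)
  keep <- bp$ok
  out <- data.frame(gx = bp$gx[keep], gy = bp$gy[keep],
                    value = field$value[sel][keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}
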