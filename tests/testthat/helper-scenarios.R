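# Shared fixtures, all built in code.

# standing observer fixating a ground point at the given declination
static_fixation_scenario <- function(duration = 0.6, fps = 60,
                                     eye_height = 1.25,
                                     declination_deg = 45) {
  d <- eye_height / tan(declination_deg * pi / 180)
  fr <- data.frame(t = seq(0, duration, by = 1 / fps),
                   cx = 0, cy = 0, cz = eye_height, fx = 0, fy = d)
  scenario_from_frames(fr, fps = fps)
}

# constant-velocity, slightly descending walk: the focus of expansion lies
# strictly below the horizon, inside the ground-visible image region
descending_scenario <- function(duration = 0.2, fps = 30, speed = 1.25,
                                sink_rate = 0.25) {
  t <- seq(0, duration, by = 1 / fps)
  fr <- data.frame(t = t, cx = 0, cy = speed * t, cz = 1.6 - sink_rate * t,
                   fx = 0, fy = 6)
  scenario_from_frames(fr, fps = fps)
}

# synthetic radial expansion field v = p - c on a square grid
radial_field <- function(cx, cy, extent = 6, spacing = 0.3) {
  ax <- seq(-extent, extent, by = spacing)
  vx <- matrix(rep(ax - cx, times = length(ax)), length(ax))
  vy <- matrix(rep(ax - cy, each = length(ax)), length(ax))
  vector_field(ax, ax, vx, vy)
}

# random linear field v = A p + b on a shared grid
linear_field <- function(A, b, extent = 5, spacing = 0.5) {
  ax <- seq(-extent, extent, by = spacing)
  xx <- matrix(ax, length(ax), length(ax))
  yy <- t(xx)
  vector_field(ax, ax,
               A[1, 1] * xx + A[1, 2] * yy + b[1],
               A[2, 1] * xx + A[2, 2] * yy + b[2])
}

interior_vals <- function(sf) {
  n <- length(sf$x); m <- length(sf$y)
  sf$value[2:(n - 1), 2:(m - 1)]
}
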