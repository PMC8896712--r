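# Planar vector-field calculus: canonical fields, numerical divergence and
# curl, scattered-to-grid interpolation and streamline particle advection.
# These primitives are shared by the retinal analyses (grids in degrees of
# visual angle, velocities in deg/s) and the head-centered focus-of-expansion
# tracker (grids in camera units).

rf_error <- function(class, msg) {
  stop(structure(
    list(message = msg, call = sys.call(-1)),
    class = c(class, "rf_error", "error", "condition")
  ))
}

#' Planar vector field on a regular grid
#'
#' A velocity vector at each node of a regular rectangular grid. Matrices are
#' indexed `[i, j]` with `i` running over `x` and `j` over `y`, the same
#' layout [grDevices::contourLines()] expects. Masked nodes (`mask == FALSE`)
#' carry no velocity requirement and are skipped by the downstream operators.
#'
#' @param x,y strictly increasing, evenly spaced axis coordinates.
#' @param vx,vy velocity component matrices of dim `c(length(x), length(y))`.
#' @param mask optional logical matrix of the same dim; `NULL` means all
#'   nodes valid. Non-finite velocities at valid nodes are rejected.
#' @return an object of class `vector_field`.
#' @export
vector_field <- function(x, y, vx, vy, mask = NULL) {
  check_axis <- function(a, name) {
    if (length(a) < 2) rf_error("rf_grid_error", paste(name, "axis needs >= 2 nodes"))
    d <- diff(a)
    if (any(d <= 0)) rf_error("rf_grid_error", paste(name, "axis must be strictly increasing"))
    if (diff(range(d)) > 1e-8 * mean(d))
      rf_error("rf_grid_error", paste(name, "axis must be evenly spaced"))
  }
  check_axis(x, "x"); check_axis(y, "y")
  dm <- c(length(x), length(y))
  if (!identical(dim(vx), as.integer(dm)) || !identical(dim(vy), as.integer(dm)))
    rf_error("rf_grid_error", "velocity matrices must match grid dim")
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  if (!identical(dim(mask), as.integer(dm)))
    rf_error("rf_grid_error", "mask must match grid dim")
  if (any(!is.finite(vx[mask])) || any(!is.finite(vy[mask])))
    rf_error("rf_grid_error", "non-finite velocity at unmasked node")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 vx = vx, vy = vy, mask = mask),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> %d x %d grid, x in [%g, %g], y in [%g, %g], %d masked nodes\n",
              length(x$x), length(x$y), min(x$x), max(x$x), min(x$y), max(x$y),
              sum(!x$mask)))
  invisible(x)
}

#' Scalar field on a regular grid
#'
#' Companion container for divergence/curl values (units 1/time when the
#' source field is a velocity field).
#'
#' @param x,y axis coordinates as in [vector_field()].
#' @param value scalar matrix of dim `c(length(x), length(y))`.
#' @param mask optional logical validity matrix.
#' @return an object of class `scalar_field`.
#' @export
scalar_field <- function(x, y, value, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(value)
  structure(list(x = as.numeric(x), y = as.numeric(y), value = value, mask = mask),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  rng <- range(x$value[x$mask], na.rm = TRUE)
  cat(sprintf("<scalar_field> %d x %d grid, value in [%.4g, %.4g]\n",
              length(x$x), length(x$y), rng[1], rng[2]))
  invisible(x)
}

grid_spacing <- function(field) {
  c(mean(diff(field$x)), mean(diff(field$y)))
}

#' Canonical textbook flow fields
#'
#' Linear fields on the integer-like grid spanning `[-extent, extent]`:
#' expansion `v = (x, y)` (divergence 2, curl 0), counter-clockwise rotation
#' `v = (-y, x)` (curl +2), clockwise rotation `v = (y, -x)` (curl -2), and
#' the spiral sum `v = (x - y, y + x)` (divergence 2 and curl 2). Positive
#' curl denotes counter-clockwise rotation throughout the package.
#'
#' @param kind one of `"expansion"`, `"rotation_ccw"`, `"rotation_cw"`,
#'   `"spiral"`.
#' @param extent positive half-width of the grid.
#' @param spacing positive node spacing.
#' @return a [vector_field()].
#' @examples
#' f <- make_canonical_field("expansion", extent = 6)
#' range(divergence(f)$value)  # 2 everywhere
#' @export
make_canonical_field <- function(kind, extent = 6, spacing = 1) {
  if (extent < 1) rf_error("rf_grid_error", "extent must be >= 1")
  if (spacing <= 0) rf_error("rf_grid_error", "spacing must be positive")
  ax <- seq(-extent, extent, by = spacing)
  xx <- matrix(ax, length(ax), length(ax))
  yy <- t(xx)
  uv <- switch(kind,
    expansion    = list(xx, yy),
    rotation_ccw = list(-yy, xx),
    rotation_cw  = list(yy, -xx),
    spiral       = list(xx - yy, yy + xx),
    rf_error("rf_kind_error", sprintf("unknown canonical field kind '%s'", kind))
  )
  vector_field(ax, ax, uv[[1]], uv[[2]])
}

# Partial derivative of a value matrix along dimension 1 (x) or 2 (y).
# Central differences on the interior, one-sided at boundaries and next to
# masked nodes; both are exact for fields linear in position. Nodes with no
# valid neighbour along the axis become NA.
partial_deriv <- function(value, mask, axis_vals, dim) {
  if (dim == 2) {
    return(t(partial_deriv(t(value), t(mask), axis_vals, 1)))
  }
  h <- mean(diff(axis_vals))
  n <- nrow(value); m <- ncol(value)
  v <- value
  v[!mask] <- NA_real_
  vp <- rbind(v[-1, , drop = FALSE], matrix(NA_real_, 1, m))  # f[i+1]
  vm <- rbind(matrix(NA_real_, 1, m), v[-n, , drop = FALSE])  # f[i-1]
  central  <- (vp - vm) / (2 * h)
  forward  <- (vp - v) / h
  backward <- (v - vm) / h
  out <- central
  use_f <- !is.finite(out) & is.finite(forward)
  out[use_f] <- forward[use_f]
  use_b <- !is.finite(out) & is.finite(backward)
  out[use_b] <- backward[use_b]
  out[!mask] <- NA_real_
  out
}

check_calculus_grid <- function(field) {
  if (length(field$x) < 3 || length(field$y) < 3)
    rf_error("rf_grid_error", "divergence/curl need at least 3 nodes per axis")
}

#' Numerical divergence of a planar vector field
#'
#' `d(vx)/dx + d(vy)/dy` by central differences on interior nodes and
#' one-sided differences at boundaries (and next to masked nodes). Both
#' schemes are exact for fields linear in position, so the canonical
#' expansion field evaluates to 2 at every node including the edges.
#'
#' @param field a [vector_field()] with at least 3 nodes per axis.
#' @return a [scalar_field()]; units are 1/time when velocities are per time.
#' @export
divergence <- function(field) {
  check_calculus_grid(field)
  dvx_dx <- partial_deriv(field$vx, field$mask, field$x, 1)
  dvy_dy <- partial_deriv(field$vy, field$mask, field$y, 2)
  val <- dvx_dx + dvy_dy
  scalar_field(field$x, field$y, val, field$mask & is.finite(val))
}

#' Numerical z-curl of a planar vector field
#'
#' `d(vy)/dx - d(vx)/dy` by the same difference scheme as [divergence()].
#' Positive values denote counter-clockwise rotation.
#'
#' @inheritParams divergence
#' @return a [scalar_field()].
#' @export
curl_z <- function(field) {
  check_calculus_grid(field)
  dvy_dx <- partial_deriv(field$vy, field$mask, field$x, 1)
  dvx_dy <- partial_deriv(field$vx, field$mask, field$y, 2)
  val <- dvy_dx - dvx_dy
  scalar_field(field$x, field$y, val, field$mask & is.finite(val))
}

# TRUE for query points inside (or on) the convex hull of pts (n x 2).
in_convex_hull <- function(qx, qy, pts, tol = 1e-9) {
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  k <- length(h)
  if (k < 3) return(rep(FALSE, length(qx)))
  scale <- max(diff(range(hx)), diff(range(hy)))
  inside <- rep(TRUE, length(qx))
  # chull returns vertices clockwise; test each edge half-plane
  for (i in seq_len(k)) {
    j <- i %% k + 1
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    cr <- ex * (qy - hy[i]) - ey * (qx - hx[i])
    inside <- inside & (cr <= tol * scale)
  }
  inside
}

#' Interpolate scattered planar vectors onto a regular grid
#'
#' Locally weighted linear (moving least squares) interpolation: at each grid
#' node a plane is fitted through the samples within a search radius, with
#' smoothly decaying weights. The scheme is exact for fields linear in
#' position, and a node that coincides with a sample point takes that
#' sample's value exactly. Nodes outside the convex hull of the samples, or
#' with too few non-collinear neighbours, are masked invalid rather than
#' extrapolated.
#'
#' @param points n x 2 matrix of sample positions.
#' @param values n x m matrix of values at the samples (m = 2 for a velocity
#'   field).
#' @param grid either a list with numeric `x` and `y` axes, or a list with
#'   `extent` and `spacing` defining the square grid `[-extent, extent]`.
#' @param radius search radius; default 2.5 times the larger of the grid
#'   spacing and the estimated sample spacing. Expanded (up to 3 doublings)
#'   at nodes with too few neighbours.
#' @return a [vector_field()] when `m == 2`, otherwise a list with `values`
#'   (nodes x m) and `mask`.
#' @export
interpolate_scattered <- function(points, values, grid, radius = NULL) {
  points <- as.matrix(points)
  values <- as.matrix(values)
  if (nrow(points) < 3)
    rf_error("rf_degenerate_error", "need at least 3 sample points")
  # collinearity check on centered coordinates
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] < 1e-12 * max(sv[1], 1))
    rf_error("rf_degenerate_error", "sample points are collinear")
  if (!is.null(grid$extent)) {
    ax <- seq(-grid$extent, grid$extent, by = grid$spacing)
    grid <- list(x = ax, y = ax)
  }
  gx <- grid$x; gy <- grid$y
  hx <- mean(diff(gx)); hy <- mean(diff(gy))
  if (is.null(radius)) {
    area <- prod(apply(points, 2, function(a) max(diff(range(a)), 1e-12)))
    est <- sqrt(area / nrow(points))
    radius <- 2.5 * max(hx, hy, est)
  }
  res <- mls_interp_cpp(points[, 1], points[, 2], values, gx, gy, radius, 3L)
  nodes_x <- rep(gx, times = length(gy))
  nodes_y <- rep(gy, each = length(gx))
  hull_ok <- in_convex_hull(nodes_x, nodes_y, points)
  mask <- matrix(res$ok & hull_ok, length(gx), length(gy))
  vals <- res$values
  vals[!rep(mask, ncol(vals))] <- NA_real_
  if (ncol(values) == 2) {
    vector_field(gx, gy,
                 matrix(vals[, 1], length(gx), length(gy)),
                 matrix(vals[, 2], length(gx), length(gy)),
                 mask)
  } else {
    list(x = gx, y = gy,
         values = vals, mask = mask)
  }
}

#' Advect particles along the streamlines of a vector field
#'
#' Fixed-step midpoint (RK2) integration with bilinear velocity lookup. The
#' time step is `step` grid spacings divided by the field's maximum speed, so
#' no particle moves more than `step` spacings per iteration. A particle
#' terminates when it leaves the grid (or enters a masked cell; its endpoint
#' is clipped to the boundary of the last valid move), when it has converged
#' (per-step displacement below `tol` spacings), or after `max_steps`.
#'
#' @param field a [vector_field()].
#' @param seeds n x 2 matrix of start points.
#' @param step positive step length in units of grid spacings (default 0.25).
#' @param max_steps maximum number of integration steps (default 1000).
#' @param tol convergence displacement threshold in grid spacings.
#' @param record_paths if `TRUE`, keep the full path of every particle.
#' @return an object of class `streamline_set`: list with `seeds`,
#'   `endpoints` (n x 2), `steps`, `status` (factor: exit/converged/max_steps)
#'   and `paths` (list of matrices, or `NULL`).
#' @export
advect_streamlines <- function(field, seeds, step = 0.25, max_steps = 1000L,
                               tol = 1e-4, record_paths = FALSE) {
  if (step <= 0) rf_error("rf_step_error", "step must be positive")
  seeds <- as.matrix(seeds)
  sp <- max(grid_spacing(field))
  vmax <- max(sqrt(field$vx[field$mask]^2 + field$vy[field$mask]^2), na.rm = TRUE)
  if (!is.finite(vmax) || vmax <= 0) vmax <- 1
  h <- step * sp / vmax
  res <- advect_cpp(field$x, field$y, field$vx, field$vy, field$mask,
                    seeds[, 1], seeds[, 2], h, as.integer(max_steps),
                    tol * sp, isTRUE(record_paths))
  structure(list(
    seeds = seeds,
    endpoints = cbind(res$end_x, res$end_y),
    steps = res$steps,
    status = factor(c("exit", "converged", "max_steps")[res$status + 1L],
                    levels = c("exit", "converged", "max_steps")),
    paths = if (isTRUE(record_paths)) res$paths else NULL
  ), class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d particles: %s\n", nrow(x$seeds),
              paste(sprintf("%s=%d", levels(x$status), tabulate(x$status, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Read/write vector and scalar fields as delimited tables
#'
#' Vector fields are stored with columns `x, y, vx, vy, valid`; scalar fields
#' with `x, y, value, valid`; one row per grid node.
#'
#' @param field a [vector_field()] or [scalar_field()].
#' @param path file path.
#' @return `read_vector_field()` / `read_scalar_field()` return the
#'   reconstructed object; the writers return `path` invisibly.
#' @export
write_vector_field <- function(field, path) {
  df <- data.frame(
    x = rep(field$x, times = length(field$y)),
    y = rep(field$y, each = length(field$x)),
    vx = as.vector(field$vx), vy = as.vector(field$vy),
    valid = as.vector(field$mask)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vector_field
#' @export
read_vector_field <- function(path) {
  df <- utils::read.csv(path)
  x <- sort(unique(df$x)); y <- sort(unique(df$y))
  idx <- cbind(match(df$x, x), match(df$y, y))
  vx <- vy <- matrix(NA_real_, length(x), length(y))
  mask <- matrix(FALSE, length(x), length(y))
  vx[idx] <- df$vx; vy[idx] <- df$vy; mask[idx] <- df$valid
  vx[!mask] <- 0; vy[!mask] <- 0  # masked nodes carry no velocity requirement
  vector_field(x, y, vx, vy, mask)
}

#' @rdname write_vector_field
#' @export
write_scalar_field <- function(field, path) {
  df <- data.frame(
    x = rep(field$x, times = length(field$y)),
    y = rep(field$y, each = length(field$x)),
    value = as.vector(field$value),
    valid = as.vector(field$mask)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vector_field
#' @export
read_scalar_field <- function(path) {
  df <- utils::read.csv(path)
  x <- sort(unique(df$x)); y <- sort(unique(df$y))
  idx <- cbind(match(df$x, x), match(df$y, y))
  value <- matrix(NA_real_, length(x), length(y))
  mask <- matrix(FALSE, length(x), length(y))
  value[idx] <- df$value; mask[idx] <- df$valid
  scalar_field(x, y, value, mask)
}
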