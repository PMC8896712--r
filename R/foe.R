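# Head-centered focus-of-expansion detection. The FoE of a flow field is a
# repellor node; negating the field turns it into an attractor, so a grid
# of particles advected along the negated field piles up at the FoE. The
# FoE is declared present when at least a majority fraction of the
# particles end up in the same place.

#' Track the focus of expansion of a flow field by particle drift
#'
#' Negates the field (turning the FoE from a repellor into an attractor),
#' advects a uniform grid of particles along it with
#' [advect_streamlines()], and bins the particle endpoints. The winning
#' bin's endpoint cluster marks the FoE: the result is `present` when the
#' fraction of particles ending within one bin width of the winning bin's
#' centroid reaches `majority`, and its location is that cluster's centroid
#' (sub-bin accuracy). Seeds are placed only on valid cells, so masked
#' regions (e.g. above the horizon) do not dilute the vote.
#'
#' @param field a [vector_field()].
#' @param seed_density number of seed particles per axis (default 20).
#' @param bin_size endpoint bin width in field units (default 1/20 of the
#'   field width).
#' @param majority minimum endpoint fraction for a detection (default 0.5,
#'   i.e. the majority criterion).
#' @param step,max_steps advection parameters, see [advect_streamlines()].
#' @return an object of class `foe_result`: list with `present`, `location`
#'   (length-2, or `NULL` when absent), `fraction`, `n_particles`.
#' @export
track_foe <- function(field, seed_density = 20, bin_size = NULL,
                      majority = 0.5, step = 0.25, max_steps = 1000L) {
  if (!any(field$mask)) rf_error("rf_empty_error", "flow field has no valid nodes")
  width <- diff(range(field$x))
  height <- diff(range(field$y))
  if (is.null(bin_size)) bin_size <- width / 20
  neg <- field
  neg$vx <- -field$vx
  neg$vy <- -field$vy
  sx <- seq(min(field$x), max(field$x), length.out = seed_density + 2)[-c(1, seed_density + 2)]
  sy <- seq(min(field$y), max(field$y), length.out = seed_density + 2)[-c(1, seed_density + 2)]
  seeds <- as.matrix(expand.grid(x = sx, y = sy, KEEP.OUT.ATTRS = FALSE))
  # keep seeds whose bilinear cell is fully valid
  ix <- pmin(findInterval(seeds[, 1], field$x), length(field$x) - 1)
  iy <- pmin(findInterval(seeds[, 2], field$y), length(field$y) - 1)
  valid <- field$mask[cbind(ix, iy)] & field$mask[cbind(ix + 1, iy)] &
    field$mask[cbind(ix, iy + 1)] & field$mask[cbind(ix + 1, iy + 1)]
  seeds <- seeds[valid, , drop = FALSE]
  if (nrow(seeds) == 0) rf_error("rf_empty_error", "no seeds land on valid cells")
  sl <- advect_streamlines(neg, seeds, step = step, max_steps = max_steps)
  ep <- sl$endpoints
  n <- nrow(ep)
  bx <- floor((ep[, 1] - min(field$x)) / bin_size)
  by <- floor((ep[, 2] - min(field$y)) / bin_size)
  key <- paste(bx, by)
  counts <- table(key)
  win <- names(counts)[which.max(counts)]
  in_win <- key == win
  ctr <- c(mean(ep[in_win, 1]), mean(ep[in_win, 2]))
  near <- sqrt((ep[, 1] - ctr[1])^2 + (ep[, 2] - ctr[2])^2) <= bin_size
  fraction <- mean(near)
  loc <- c(mean(ep[near, 1]), mean(ep[near, 2]))
  present <- fraction >= majority
  structure(list(present = present,
                 location = if (present) loc else NULL,
                 fraction = fraction, n_particles = n),
            class = "foe_result")
}

#' @export
print.foe_result <- function(x, ...) {
  if (x$present)
    cat(sprintf("<foe_result> present at (%.3g, %.3g), fraction %.2f of %d particles\n",
                x$location[1], x$location[2], x$fraction, x$n_particles))
  else
    cat(sprintf("<foe_result> absent (best fraction %.2f of %d particles)\n",
                x$fraction, x$n_particles))
  invisible(x)
}

#' Frame-to-frame FoE velocity in degrees of visual angle per second
#'
#' Euclidean displacement of the FoE between two consecutive frames,
#' converted to visual degrees by the camera field of view over the field
#' width, and to a rate by the frame rate.
#'
#' @param loc_t,loc_t1 FoE locations (length-2) on consecutive frames; `NULL`
#'   or `NA` marks an absent detection.
#' @param fov_deg camera field of view in degrees spanned by `field_width`.
#' @param field_width field width in field units.
#' @param fps frames per second.
#' @return velocity in deg/s, or `NA` when either frame is absent.
#' @export
foe_velocity <- function(loc_t, loc_t1, fov_deg, field_width, fps) {
  if (is.null(loc_t) || is.null(loc_t1) || anyNA(loc_t) || anyNA(loc_t1))
    return(NA_real_)
  d <- sqrt(sum((loc_t1 - loc_t)^2))
  d * (fov_deg / field_width) * fps
}

camera_axes <- function(pitch_deg, yaw_deg) {
  p <- pitch_deg * pi / 180  # positive = pitched down
  yw <- yaw_deg * pi / 180   # positive = to the right of +y
  forward <- c(cos(p) * sin(yw), cos(p) * cos(yw), -sin(p))
  right <- c(cos(yw), -sin(yw), 0)
  up <- c(right[2] * forward[3] - right[3] * forward[2],
          right[3] * forward[1] - right[1] * forward[3],
          right[1] * forward[2] - right[2] * forward[1])
  list(forward = forward, right = right, up = up)
}

# perspective image coordinates (tangent units) of 3D points in a camera
camera_project <- function(center, axes, P) {
  U <- P - matrix(center, nrow(P), 3, byrow = TRUE)
  af <- as.numeric(U %*% axes$forward)
  ok <- af > 1e-9
  data.frame(u = as.numeric(U %*% axes$right) / af,
             v = as.numeric(U %*% axes$up) / af,
             ok = ok)
}

#' Head-centered flow field from the geometric model
#'
#' Generates the flow a head-fixed (non-fixating) pinhole camera would see
#' between two consecutive scenario frames, so the FoE tracker can be
#' exercised without any video. Ground points are sampled along the rays of
#' the camera grid at the current frame, re-projected at the previous
#' frame, and the per-point image displacements are interpolated onto the
#' regular camera grid. Image coordinates are tangent-plane units; the
#' camera axis follows a configurable head orientation (fixed, or per-frame
#' via a function).
#'
#' @param scenario an `rf_scenario`.
#' @param frame_index index (>= 2) of the current frame.
#' @param fov_deg camera half field of view in degrees (default 45).
#' @param n camera grid nodes per axis (default 41).
#' @param orientation length-2 `c(pitch, yaw)` in degrees (pitch positive
#'   down), or a function of the frame index returning such a vector.
#' @param clip maximum ground distance sampled, metres (default 50).
#' @return a [vector_field()] in tangent units per frame.
#' @export
head_frame_flow <- function(scenario, frame_index, fov_deg = 45, n = 41,
                            orientation = c(30, 0), clip = 50) {
  fr <- scenario$frames
  if (frame_index < 2 || frame_index > nrow(fr))
    rf_error("rf_scenario_error", "frame_index must address a frame pair")
  orient_of <- if (is.function(orientation)) orientation else function(i) orientation
  o1 <- orient_of(frame_index - 1L)
  o2 <- orient_of(frame_index)
  ax1 <- camera_axes(o1[1], o1[2])
  ax2 <- camera_axes(o2[1], o2[2])
  c1 <- c(fr$cx[frame_index - 1], fr$cy[frame_index - 1], fr$cz[frame_index - 1])
  c2 <- c(fr$cx[frame_index], fr$cy[frame_index], fr$cz[frame_index])
  half <- tan(fov_deg * pi / 180)
  axg <- seq(-half, half, length.out = n)
  sp <- axg[2] - axg[1]
  # sample rays on the half-offset lattice of the analysis grid
  s <- seq(-half - sp / 2, half + sp / 2, by = sp)
  su <- rep(s, times = length(s))
  sv <- rep(s, each = length(s))
  D <- outer(rep(1, length(su)), ax2$forward) + su %o% ax2$right + sv %o% ax2$up
  dz <- D[, 3]
  hit <- dz < -1e-9
  t_hit <- ifelse(hit, -c2[3] / dz, NA_real_)
  keep <- hit & t_hit * sqrt(D[, 1]^2 + D[, 2]^2) <= clip
  if (sum(keep) < 3) rf_error("rf_degenerate_error", "camera sees too little ground")
  P <- cbind(c2[1] + t_hit[keep] * D[keep, 1],
             c2[2] + t_hit[keep] * D[keep, 2], 0)
  prev <- camera_project(c1, ax1, P)
  ok <- prev$ok & abs(prev$u) <= half * 1.2 & abs(prev$v) <= half * 1.2
  if (sum(ok) < 3) rf_error("rf_degenerate_error", "too few points visible on both frames")
  pts <- cbind(su[keep][ok], sv[keep][ok])
  vel <- cbind(su[keep][ok] - prev$u[ok], sv[keep][ok] - prev$v[ok])
  interpolate_scattered(pts, vel, list(x = axg, y = axg))
}

#' Track the FoE across all frames of a scenario
#'
#' Convenience wrapper: runs [head_frame_flow()] + [track_foe()] on every
#' frame pair and converts the frame-to-frame FoE displacement to deg/s.
#'
#' @inheritParams head_frame_flow
#' @inheritParams track_foe
#' @return data.frame with `frame`, `t`, `present`, `x`, `y`, `fraction`,
#'   `velocity_deg_s` (NA on the first frame or around absent detections).
#' @export
track_foe_scenario <- function(scenario, fov_deg = 45, n = 41,
                               orientation = c(30, 0), seed_density = 20,
                               majority = 0.5) {
  fr <- scenario$frames
  nf <- nrow(fr)
  width <- 2 * tan(fov_deg * pi / 180)
  out <- data.frame(frame = 2:nf, t = fr$t[-1], present = FALSE,
                    x = NA_real_, y = NA_real_, fraction = NA_real_,
                    velocity_deg_s = NA_real_)
  prev_loc <- NULL
  for (k in seq_len(nrow(out))) {
    fld <- head_frame_flow(scenario, out$frame[k], fov_deg = fov_deg, n = n,
                           orientation = orientation)
    res <- track_foe(fld, seed_density = seed_density, majority = majority)
    out$present[k] <- res$present
    out$fraction[k] <- res$fraction
    if (res$present) {
      out$x[k] <- res$location[1]
      out$y[k] <- res$location[2]
      out$velocity_deg_s[k] <-
        foe_velocity(prev_loc, res$location, 2 * fov_deg, width, scenario$fps)
      prev_loc <- res$location
    } else {
      prev_loc <- NULL
    }
  }
  out
}
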