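# Orchestration: run a scenario end to end (trajectory -> eye poses ->
# retinal flow -> per-frame features), sweep fixation offsets, and write
# reproducible tabular outputs.

#' Build a scenario from an explicit frame table
#'
#' Escape hatch for trajectories not covered by the generators: any table
#' of eye positions and fixation points at a fixed frame rate.
#'
#' @param frames data.frame with columns `t`, `cx`, `cy`, `cz`, `fx`, `fy`.
#' @param fps frames per second.
#' @param walk_speed,eye_height optional metadata (defaults derived from
#'   the frames).
#' @return an `rf_scenario`.
#' @export
scenario_from_frames <- function(frames, fps, walk_speed = NA_real_,
                                 eye_height = NULL) {
  if (is.null(eye_height)) eye_height <- mean(frames$cz)
  new_scenario(frames[, c("t", "cx", "cy", "cz", "fx", "fy")], fps,
               walk_speed, eye_height, "custom")
}

scenario_poses <- function(scenario) {
  fr <- scenario$frames
  poses <- vector("list", nrow(fr))
  prev <- NULL
  for (i in seq_len(nrow(fr))) {
    prev <- orient_to_fixation(c(fr$cx[i], fr$cy[i], fr$cz[i]),
                               c(fr$fx[i], fr$fy[i]), prev_pose = prev)
    poses[[i]] <- prev
  }
  poses
}

# Scatter of retinal flow samples for a frame pair, using retinal-stratified
# sampling: scene points are taken where the rays of the half-offset chart
# lattice (plus the fixation anchor) meet the ground at the current frame,
# then re-projected under the previous pose. Points not visible on the
# previous frame (newly visible) are excluded; their flow is undefined.
frame_flow_scatter <- function(pose_prev, pose_cur, fov, spacing, fps,
                               ground_clip) {
  s <- seq(-fov - spacing / 2, fov + spacing / 2, by = spacing)
  su <- rep(s, times = length(s))
  sv <- rep(s, each = length(s))
  keep <- su^2 + sv^2 <= (fov + spacing)^2
  su <- c(0, su[keep])  # fixation anchor at the exact fovea
  sv <- c(0, sv[keep])
  bp <- unproject_chart(pose_cur, su, sv)
  gd <- sqrt((bp$gx - pose_cur$center[1])^2 + (bp$gy - pose_cur$center[2])^2)
  ok <- bp$ok & gd <= ground_clip
  P <- cbind(bp$gx[ok], bp$gy[ok], 0)
  prev <- project_points_raw(pose_prev, P)
  vis <- !prev$behind & prev$rho <= fov + 2 * spacing
  cur_x <- su[ok][vis]; cur_y <- sv[ok][vis]
  pc <- chart(prev$theta[vis], prev$rho[vis])
  list(points = cbind(cur_x, cur_y),
       velocities = cbind((cur_x - pc$x) * fps, (cur_y - pc$y) * fps))
}

# Scatter from a fixed ground grid with stable point ids (the bookkeeping
# variant): project the grid under both poses and difference shared ids.
grid_flow_scatter <- function(pose_prev, pose_cur, grid, fov, fps) {
  prev <- project_grid(pose_prev, grid, fov)
  cur <- project_grid(pose_cur, grid, fov)
  pf <- point_flow(prev, cur, fps)
  list(points = cbind(pf$x, pf$y), velocities = cbind(pf$vx, pf$vy))
}

empty_features_row <- function() {
  data.frame(frame = NA_integer_, t = NA_real_, declination_deg = NA_real_,
             foveal_curl = NA_real_, foveal_div = NA_real_,
             foveal_speed = NA_real_, maxdiv_x = NA_real_, maxdiv_y = NA_real_,
             maxdiv_theta = NA_real_, maxdiv_rho = NA_real_,
             maxdiv_gx = NA_real_, maxdiv_gy = NA_real_,
             maxdiv_boundary = NA, iso_state = NA_character_,
             iso_area = NA_real_, vel_fix_angle = NA_real_,
             maxdiv_fix_angle = NA_real_, perturbed = NA)
}

#' Run the retinal flow pipeline over a scenario
#'
#' For every frame: orient the eye at the fixation point, sample the ground
#' through the retina, compute the frame-to-frame retinal flow, interpolate
#' it onto the regular retinal grid, and extract the flow features (foveal
#' curl, foveal speed, point of maximum divergence with its ground
#' back-projection, foveal divergence iso-contour, heading angles). The
#' first frame's flow is defined to be zero; its feature row carries zero
#' flow quantities and undefined structural features.
#'
#' @param scenario an `rf_scenario`.
#' @param fov retinal field-of-view radius in degrees (default 60).
#' @param spacing retinal grid spacing in degrees (default 1).
#' @param window_deg foveal curl averaging radius (default 2).
#' @param sampling `"retinal"` (default): scene points sampled along the
#'   current frame's chart lattice for uniform retinal coverage;
#'   `"ground_grid"`: a fixed ground grid with stable point ids.
#' @param ground_spacing ground grid spacing in metres (ground_grid mode).
#' @param ground_clip maximum ground distance sampled, metres (default 20).
#' @param metric chart metric handling for divergence/curl, see
#'   [flow_frame()].
#' @param keep_frames if `TRUE`, return the per-frame [flow_frame()]
#'   objects (memory-heavy) alongside the feature table.
#' @param out_dir optional directory: writes `features.csv` and a
#'   `manifest.json` echoing the configuration and seed.
#' @return an object of class `rf_run`: list with `features` (one row per
#'   frame), `scenario`, `params`, and `frames` (list or `NULL`).
#' @export
run_scenario <- function(scenario, fov = 60, spacing = 1, window_deg = 2,
                         sampling = c("retinal", "ground_grid"),
                         ground_spacing = 0.25, ground_clip = 20,
                         metric = c("spherical", "planar"),
                         keep_frames = FALSE, out_dir = NULL) {
  sampling <- match.arg(sampling)
  metric <- match.arg(metric)
  fr <- scenario$frames
  nf <- nrow(fr)
  fps <- scenario$fps
  poses <- scenario_poses(scenario)
  grid <- NULL
  if (sampling == "ground_grid") {
    # one grid covering the union of per-frame FOV footprints (plus the
    # scheduled fixation points as extra tracked scene points)
    bx <- by <- numeric(0)
    for (p in poses) {
      b <- fov_ground_boundary(p, fov, n = 72, clip = ground_clip)
      bx <- range(bx, b$points[, 1])
      by <- range(by, b$points[, 2])
    }
    xr <- bx; yr <- by
    grid <- ground_grid(ground_spacing,
                        xlim = xr + c(-1, 1) * ground_spacing,
                        ylim = yr + c(-1, 1) * ground_spacing)
    anchors <- unique(fr[, c("fx", "fy")])
    grid <- rbind(grid,
                  data.frame(id = -seq_len(nrow(anchors)),
                             x = anchors$fx, y = anchors$fy, z = 0))
  }
  rows <- vector("list", nf)
  frames_out <- if (keep_frames) vector("list", nf) else NULL
  first <- empty_features_row()
  first$frame <- 1L; first$t <- fr$t[1]
  first$declination_deg <- gaze_declination(poses[[1]])
  first$foveal_curl <- 0; first$foveal_div <- 0; first$foveal_speed <- 0
  first$iso_state <- "undefined"; first$perturbed <- fr$perturbed[1]
  rows[[1]] <- first
  for (i in 2:nf) {
    sc <- if (sampling == "retinal")
      frame_flow_scatter(poses[[i - 1]], poses[[i]], fov, spacing, fps,
                         ground_clip)
    else
      grid_flow_scatter(poses[[i - 1]], poses[[i]], grid, fov, fps)
    ff <- flow_frame(sc$points, sc$velocities, fov = fov, spacing = spacing,
                     fps = fps, t = fr$t[i], metric = metric)
    if (keep_frames) frames_out[[i]] <- ff
    md <- max_divergence(ff, pose = poses[[i]])
    iso <- foveal_isocontour(ff)
    vel <- c(fr$cx[i] - fr$cx[i - 1], fr$cy[i] - fr$cy[i - 1],
             fr$cz[i] - fr$cz[i - 1]) * fps
    ha <- tryCatch(
      heading_angles(poses[[i]], vel, md$ground),
      rf_velocity_error = function(e)
        list(velocity_fixation_angle = NA_real_,
             maxdiv_fixation_angle = NA_real_))
    dfield <- ff$div_field
    fn <- fovea_node(dfield)
    row <- data.frame(
      frame = i, t = fr$t[i],
      declination_deg = gaze_declination(poses[[i]]),
      foveal_curl = foveal_curl(ff, window_deg),
      foveal_div = dfield$value[fn[1], fn[2]],
      foveal_speed = foveal_speed(ff),
      maxdiv_x = md$x, maxdiv_y = md$y,
      maxdiv_theta = md$theta, maxdiv_rho = md$rho,
      maxdiv_gx = if (is.null(md$ground)) NA_real_ else md$ground[1],
      maxdiv_gy = if (is.null(md$ground)) NA_real_ else md$ground[2],
      maxdiv_boundary = md$boundary,
      iso_state = iso$state, iso_area = iso$area,
      vel_fix_angle = ha$velocity_fixation_angle,
      maxdiv_fix_angle = ha$maxdiv_fixation_angle,
      perturbed = fr$perturbed[i])
    rows[[i]] <- row
  }
  features <- do.call(rbind, rows)
  params <- list(fov = fov, spacing = spacing, window_deg = window_deg,
                 sampling = sampling, ground_spacing = ground_spacing,
                 ground_clip = ground_clip, metric = metric)
  run <- structure(list(features = features, scenario = scenario,
                        params = params, frames = frames_out),
                   class = "rf_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.rf_run <- function(x, ...) {
  cat(sprintf("<rf_run> %s scenario, %d frames analysed\n",
              x$scenario$generator, nrow(x$features)))
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' Emits `features.csv` (the per-frame feature table) and `manifest.json`
#' (scenario generator, parameters, seed and analysis settings — everything
#' needed to reproduce the run byte-identically).
#'
#' @param run an `rf_run`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir` invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "retinalflow",
    version = as.character(utils::packageVersion("retinalflow")),
    generator = run$scenario$generator,
    generator_params = run$scenario$params,
    fps = run$scenario$fps,
    seed = run$scenario$seed,
    perturbations = lapply(run$scenario$perturbations, unclass),
    analysis = run$params
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Sweep lateral fixation offsets of a straight approach
#'
#' Runs [run_scenario()] on a [straight_approach()] per offset and stacks
#' the per-frame features: the relation between the velocity/fixation
#' angle, the foveal curl (sign and magnitude follow the offset side) and
#' the max-divergence/fixation angle (which tracks the velocity/fixation
#' angle).
#'
#' @param offsets signed fixation offsets in degrees (>= 2 values).
#' @param scenario_args list of arguments for [straight_approach()].
#' @param ... further arguments passed to [run_scenario()].
#' @return data.frame: `offset` plus the feature columns, frames 2+ only.
#' @export
sweep_offsets <- function(offsets, scenario_args = list(), ...) {
  if (length(offsets) < 2)
    rf_error("rf_scenario_error", "need at least 2 offsets")
  out <- lapply(offsets, function(o) {
    sc <- do.call(straight_approach,
                  c(list(fixation_offset_angle = o), scenario_args))
    ft <- run_scenario(sc, ...)$features
    ft <- ft[-1, ]  # first frame carries no flow
    cbind(offset = o, ft)
  })
  do.call(rbind, out)
}
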