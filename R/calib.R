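# VOR-based gaze alignment calibration. A head-mounted eye tracker reports
# gaze in its own sensor frame; the fixed sensor-to-head rotation is
# recovered by exploiting the vestibulo-ocular reflex: while the subject
# fixates a known ground marker and sweeps the head, the correct alignment
# rotation makes the head rotation cancel the compensatory eye rotation, so
# all gaze rays intersect the ground at the marker. The alignment is found
# by minimizing the mean gaze/ground intersection error over the Euler
# triple, starting from zero.

# Precompute the per-frame head rotation entries (n x 9, column-major) and
# raw gaze matrix (n x 3) of a session.
session_arrays <- function(session) {
  fr <- session$frames
  n <- nrow(fr)
  Rh <- matrix(NA_real_, n, 9)
  for (i in seq_len(n)) {
    Rh[i, ] <- as.numeric(quat_to_matrix(c(fr$qw[i], fr$qx[i], fr$qy[i], fr$qz[i])))
  }
  list(Rh = Rh,
       G = cbind(fr$gx, fr$gy, fr$gz),
       C = cbind(fr$ex, fr$ey, fr$ez))
}

intersections_from_arrays <- function(arr, euler, truncation) {
  A <- euler_to_matrix(euler)
  G1 <- arr$G %*% t(A)  # aligned gaze, still in head frame
  Rh <- arr$Rh
  dx <- Rh[, 1] * G1[, 1] + Rh[, 4] * G1[, 2] + Rh[, 7] * G1[, 3]
  dy <- Rh[, 2] * G1[, 1] + Rh[, 5] * G1[, 2] + Rh[, 8] * G1[, 3]
  dz <- Rh[, 3] * G1[, 1] + Rh[, 6] * G1[, 2] + Rh[, 9] * G1[, 3]
  hit <- dz < -1e-12
  t_hit <- ifelse(hit, -arr$C[, 3] / dz, truncation)
  data.frame(x = arr$C[, 1] + t_hit * dx,
             y = arr$C[, 2] + t_hit * dy,
             z = arr$C[, 3] + t_hit * dz,
             truncated = !hit)
}

#' Gaze/ground intersections under a candidate alignment rotation
#'
#' Rotates every raw gaze vector by the Euler-angle alignment rotation,
#' then by the frame's head orientation, and casts the resulting world ray
#' from the eye center to the ground plane. Rays that do not intersect the
#' ground are truncated at the session's truncation distance (default
#' 10 m) and flagged.
#'
#' @param session a `calibration_session` (see
#'   [synth_calibration_session()]).
#' @param euler length-3 alignment Euler angles in degrees (intrinsic
#'   X-Y-Z).
#' @return data.frame with `x`, `y`, `z` (m) and `truncated` per frame.
#' @export
gaze_ground_intersections <- function(session, euler = c(0, 0, 0)) {
  intersections_from_arrays(session_arrays(session), euler,
                            session$truncation_distance)
}

#' Mean gaze/ground intersection error
#'
#' Arithmetic mean Euclidean distance between the intersection points and
#' the calibration point; the objective the alignment fit minimizes.
#'
#' @param points data.frame with `x`, `y`, `z` columns (from
#'   [gaze_ground_intersections()]).
#' @param calib_point length-3 calibration point (or length-2, ground).
#' @return mean distance in metres.
#' @export
calibration_error <- function(points, calib_point) {
  if (nrow(points) == 0) rf_error("rf_empty_error", "no intersection points")
  if (length(calib_point) == 2) calib_point <- c(calib_point, 0)
  mean(sqrt((points$x - calib_point[1])^2 +
              (points$y - calib_point[2])^2 +
              (points$z - calib_point[3])^2))
}

#' Recover the sensor-to-head alignment rotation of a session
#'
#' Unconstrained local minimization of [calibration_error()] over the
#' Euler-angle triple, starting from `c(0, 0, 0)`: Nelder-Mead followed by
#' a BFGS polish. With sweeps about at least two head axes and no noise the
#' minimizer is the true misalignment.
#'
#' @param session a `calibration_session`.
#' @param start starting Euler triple in degrees (default zero, per the
#'   calibration procedure).
#' @return an object of class `alignment_result`: list with `euler`
#'   (degrees, each in (-180, 180]), `residual_error` (m),
#'   `intersections` (per-frame ground points at the optimum) and
#'   `convergence` (0 = converged).
#' @export
fit_alignment <- function(session, start = c(0, 0, 0)) {
  arr <- session_arrays(session)
  cp <- session$calib_point
  obj <- function(e) {
    calibration_error(intersections_from_arrays(arr, e, session$truncation_distance), cp)
  }
  nm <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  bf <- tryCatch(
    stats::optim(nm$par, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) nm)
  best <- if (bf$value <= nm$value) bf else nm
  if (nm$convergence != 0 && bf$convergence != 0) {
    cond <- structure(
      list(message = sprintf(
        "alignment optimization did not converge (final iterate %.3f, %.3f, %.3f deg, error %.4f m)",
        best$par[1], best$par[2], best$par[3], best$value),
        call = sys.call(-1), final_iterate = best$par),
      class = c("rf_optim_error", "rf_error", "error", "condition"))
    stop(cond)
  }
  structure(list(
    euler = wrap_angle(best$par),
    residual_error = best$value,
    intersections = intersections_from_arrays(arr, best$par,
                                              session$truncation_distance),
    convergence = best$convergence
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> euler (%.3f, %.3f, %.3f) deg, residual %.4g m\n",
              x$euler[1], x$euler[2], x$euler[3], x$residual_error))
  invisible(x)
}

#' Scatter of gaze/ground intersections around their centroid
#'
#' Root-mean-square distance of the per-frame intersections from their own
#' centroid: the verification statistic of a calibration. A correct
#' alignment yields a tight cluster around the calibration point; a wrong
#' one smears the intersections along the head sweep.
#'
#' @inheritParams gaze_ground_intersections
#' @return RMS scatter radius in metres.
#' @export
vor_consistency_check <- function(session, euler = c(0, 0, 0)) {
  p <- gaze_ground_intersections(session, euler)
  cx <- mean(p$x); cy <- mean(p$y); cz <- mean(p$z)
  sqrt(mean((p$x - cx)^2 + (p$y - cy)^2 + (p$z - cz)^2))
}

#' Read and write calibration session tables
#'
#' One row per frame: `t`, head quaternion `qw, qx, qy, qz`, eye center
#' `ex, ey, ez` (m), raw sensor-frame gaze direction `gx, gy, gz`, plus the
#' constant columns `cpx, cpy` (calibration point) and `trunc`
#' (truncation distance).
#'
#' @param session a `calibration_session`.
#' @param path file path.
#' @return the reader returns a `calibration_session`; the writer returns
#'   `path` invisibly.
#' @export
write_calibration_session <- function(session, path) {
  df <- session$frames
  df$cpx <- session$calib_point[1]
  df$cpy <- session$calib_point[2]
  df$trunc <- session$truncation_distance
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_session
#' @export
read_calibration_session <- function(path) {
  df <- utils::read.csv(path)
  structure(list(
    frames = df[, c("t", "qw", "qx", "qy", "qz", "ex", "ey", "ez",
                    "gx", "gy", "gz")],
    calib_point = c(df$cpx[1], df$cpy[1], 0),
    truncation_distance = df$trunc[1]
  ), class = "calibration_session")
}
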