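# 3D rotation helpers shared by the eye model, the synthetic generators and
# the VOR calibration. All rotations are 3x3 orthonormal matrices acting on
# column vectors; the world frame is x-right, y-forward, z-up with the ground
# plane at z = 0.

#' Rotation about an arbitrary axis
#'
#' Rodrigues' formula. The axis need not be normalized.
#'
#' @param axis length-3 axis (not all zero).
#' @param angle rotation angle in radians (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) stop("rotation axis must be non-zero")
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Minimal (geodesic) rotation taking one direction to another
#'
#' The unique rotation about the axis perpendicular to both vectors that
#' carries `from` to `to`; it introduces no twist about either vector.
#' Returns the identity for parallel inputs and signals an error for
#' anti-parallel inputs, where the geodesic is not unique.
#'
#' @param from,to length-3 direction vectors (need not be unit).
#' @return 3x3 rotation matrix `R` with `R %*% from` parallel to `to`.
#' @export
rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t <- to / sqrt(sum(to^2))
  c_ <- sum(f * t)
  ax <- c(f[2] * t[3] - f[3] * t[2],
          f[3] * t[1] - f[1] * t[3],
          f[1] * t[2] - f[2] * t[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-15) {
    if (c_ > 0) return(diag(3))
    stop("rotation_between: anti-parallel directions have no unique geodesic")
  }
  rotation_about_axis(ax, atan2(s, c_))
}

#' Euler angles to rotation matrix (intrinsic X-Y-Z)
#'
#' The convention used throughout the calibration module: rotate about the
#' body x axis by `euler[1]`, then the new y axis by `euler[2]`, then the new
#' z axis by `euler[3]`. As matrices on world-frame column vectors this is
#' `Rx %*% Ry %*% Rz`.
#'
#' @param euler length-3 angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(euler) {
  stopifnot(length(euler) == 3)
  r <- euler * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

#' Rotation matrix to Euler angles (intrinsic X-Y-Z)
#'
#' Inverse of [euler_to_matrix()]. Angles are returned in degrees in
#' (-180, 180]; at the gimbal singularity (|pitch| = 90 deg) the x angle is
#' set to zero.
#'
#' @param R 3x3 rotation matrix.
#' @return length-3 angles in degrees.
#' @export
matrix_to_euler <- function(R) {
  # R = Rx Ry Rz; R[1,3] = sy, R[1,2] = -cy*sz, R[1,1] = cy*cz,
  # R[2,3] = -sx*cy, R[3,3] = cx*cy.
  sy <- max(-1, min(1, R[1, 3]))
  y <- asin(sy)
  if (abs(sy) < 1 - 1e-12) {
    x <- atan2(-R[2, 3], R[3, 3])
    z <- atan2(-R[1, 2], R[1, 1])
  } else {
    x <- 0
    z <- atan2(R[2, 1], R[2, 2]) * sign(sy)
  }
  c(x, y, z) * 180 / pi
}

#' Quaternion (w, x, y, z) to rotation matrix
#'
#' @param q length-4 unit quaternion, scalar part first.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Rotation matrix to quaternion (w, x, y, z)
#'
#' @param R 3x3 rotation matrix.
#' @return length-4 unit quaternion with non-negative scalar part.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(max(R[i, i] - R[j, j] - R[k, k] + 1, 0)) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# wrap angles (deg) into (-180, 180]
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}
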