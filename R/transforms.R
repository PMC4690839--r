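# Rigid-transform and rotation helpers. All homogeneous transforms are 4x4
# matrices; points are length-3 vectors or n x 3 matrices, in metres.

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, angle in radians.
#' The model convention is X anterior, Y up, Z lateral (right side).
#'
#' @param a rotation angle (rad)
#' @return 3x3 rotation matrix
#' @export
rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis (Rodrigues formula)
#'
#' @param axis length-3 axis vector (normalized internally)
#' @param angle rotation angle (rad)
#' @return 3x3 rotation matrix
#' @export
axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Build a homogeneous rigid transform
#'
#' @param R 3x3 rotation matrix (default identity)
#' @param p length-3 translation (default zero), metres
#' @return 4x4 homogeneous matrix
#' @export
make_transform <- function(R = diag(3), p = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- p
  T
}

#' Invert a rigid transform
#' @param T 4x4 homogeneous matrix
#' @return 4x4 inverse
#' @export
tf_inv <- function(T) {
  R <- T[1:3, 1:3]
  out <- diag(4)
  out[1:3, 1:3] <- t(R)
  out[1:3, 4] <- -t(R) %*% T[1:3, 4]
  out
}

#' Apply a rigid transform to points
#'
#' @param T 4x4 homogeneous matrix
#' @param pts length-3 vector or n x 3 matrix
#' @return transformed points, same shape as input
#' @export
tf_apply <- function(T, pts) {
  if (is.null(dim(pts))) {
    as.numeric(T[1:3, 1:3] %*% pts + T[1:3, 4])
  } else {
    sweep(pts %*% t(T[1:3, 1:3]), 2, T[1:3, 4], "+")
  }
}

# rotation part / origin part accessors
tf_rot <- function(T) T[1:3, 1:3]
tf_origin <- function(T) T[1:3, 4]

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps * 10) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle of a rotation matrix
#' @param R 3x3 rotation matrix
#' @return rotation angle in radians, in [0, pi]
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
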