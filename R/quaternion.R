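# Quaternion convention: Hamilton, scalar-first (w, x, y, z), unit norm,
# active rotation from the sensor frame to the global frame. A vector v in
# sensor coordinates maps to q (x) v (x) q* in global coordinates.

#' Rotation matrices from unit quaternions
#'
#' @param q numeric matrix, n x 4, columns (w, x, y, z)
#' @return 3 x 3 x n array of rotation matrices (sensor -> global)
#' @keywords internal
#' @noRd
quat_to_matrix <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  R <- array(0, c(3, 3, nrow(q)))
  R[1, 1, ] <- 1 - 2 * (y^2 + z^2)
  R[1, 2, ] <- 2 * (x * y - w * z)
  R[1, 3, ] <- 2 * (x * z + w * y)
  R[2, 1, ] <- 2 * (x * y + w * z)
  R[2, 2, ] <- 1 - 2 * (x^2 + z^2)
  R[2, 3, ] <- 2 * (y * z - w * x)
  R[3, 1, ] <- 2 * (x * z - w * y)
  R[3, 2, ] <- 2 * (y * z + w * x)
  R[3, 3, ] <- 1 - 2 * (x^2 + y^2)
  R
}

# Rotate row vectors v (n x 3) sample-wise by quaternions q (n x 4),
# sensor -> global. Vectorized over samples.
quat_rotate <- function(q, v) {
  R <- quat_to_matrix(q)
  out <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    out[, j] <- R[j, 1, ] * v[, 1] + R[j, 2, ] * v[, 2] + R[j, 3, ] * v[, 3]
  }
  out
}

# Quaternion for a rotation of `angle` radians about unit axis (3-vector).
axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# Hamilton product of two scalar-first quaternions (vectors or n x 4).
quat_multiply <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1) b <- b[rep(1, n), , drop = FALSE]
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}
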