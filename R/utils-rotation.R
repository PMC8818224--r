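# 3-D rotation helpers shared by the simulator (mounting offsets) and the
# calibration module. Axis order everywhere is (heave, surge, sway).

#' Rotation matrix from an axis and an angle
#'
#' Builds the 3x3 rotation matrix for a right-handed rotation of `angle`
#' degrees about `axis` (Rodrigues' formula). Axis components are in device
#' coordinates, ordered (heave, surge, sway).
#'
#' @param axis Numeric length-3 vector; need not be normalised.
#' @param angle Rotation angle in degrees.
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @export
#' @examples
#' rotation_about(c(0, 0, 1), 90)
rotation_about <- function(axis, angle) {
  stopifnot(length(axis) == 3, is.numeric(angle), length(angle) == 1)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) abort("rotation axis must be non-zero")
  u <- axis / nrm
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Minimal rotation carrying unit vector `from` onto unit vector `to`.
rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t <- to / sqrt(sum(to^2))
  d <- sum(f * t)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    # antiparallel: rotate 180 degrees about any axis orthogonal to `from`
    ref <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- pracma_cross(f, ref)
    return(rotation_about(ax, 180))
  }
  ax <- pracma_cross(f, t)
  rotation_about(ax, acos(pmin(pmax(d, -1), 1)) * 180 / pi)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle in degrees between two 3-vectors.
angle_between <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) abort("cannot measure the angle of a zero vector")
  acos(pmin(pmax(sum(a * b) / (na * nb), -1), 1)) * 180 / pi
}

#' Random mounting rotation
#'
#' Draws a rotation about a uniformly random axis, with the rotation angle
#' uniform on `[0, max_angle]` degrees. Used to simulate a non-centred device
#' on the collar.
#'
#' @param max_angle Largest rotation angle that can be drawn, degrees.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A 3x3 rotation matrix.
#' @export
random_mounting_offset <- function(max_angle = 40, seed = 1L) {
  withr::with_seed(seed, {
    ax <- rnorm(3)
    ang <- runif(1, 0, max_angle)
    rotation_about(ax, ang)
  })
}

check_rotation <- function(R, arg = "rotation") {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3))) {
    abort(sprintf("%s must be a 3x3 matrix", arg))
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    abort(sprintf("%s must be orthonormal with determinant +1", arg))
  }
  invisible(R)
}
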