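# Rail-reference mounting calibration.
#
# Before deployment the collar hangs on a rail with the device at the bottom,
# so the mean acceleration over that window is pure gravity in a known
# direction. A device mounted off-centre reads gravity rotated away from
# that direction; the calibration estimates the minimal (axis-angle)
# rotation taking the window mean back onto the expected gravity direction
# and applies it to every sample. Rotation only: both loggers report in
# calibrated g, so no per-axis gain or offset is fitted.

#' Calibration reference window
#'
#' @param window Length-2 numeric `(start_s, end_s)` of the rail-reference
#'   window within the trace; at least 4 s long.
#' @param expected_gravity Unit vector (heave, surge, sway) that gravity
#'   should take after correction; defaults to +heave (device hanging
#'   upright).
#' @return A `calibration_reference` object.
#' @export
calibration_reference <- function(window = c(0, 10),
                                  expected_gravity = c(1, 0, 0)) {
  stopifnot(length(window) == 2, length(expected_gravity) == 3)
  if (diff(window) < 4) abort("reference window must be at least 4 s long")
  nrm <- sqrt(sum(expected_gravity^2))
  if (abs(nrm - 1) > 1e-6) expected_gravity <- expected_gravity / nrm
  structure(list(window = as.numeric(window),
                 expected_gravity = expected_gravity),
            class = "calibration_reference")
}

new_mounting_correction <- function(rotation, residual_angle) {
  check_rotation(rotation)
  structure(list(rotation = rotation, residual_angle = residual_angle),
            class = "mounting_correction")
}

#' @export
print.mounting_correction <- function(x, ...) {
  ang <- angle_between(x$rotation %*% c(1, 0, 0), c(1, 0, 0))
  cat(sprintf("<mounting_correction> rotation of %.2f deg (heave image), residual %.3f deg\n",
              ang, x$residual_angle))
  invisible(x)
}

#' Estimate the mounting correction from a rail-reference window
#'
#' Averages the acceleration vector over the reference window and returns
#' the minimal rotation mapping that mean onto the expected gravity
#' direction, together with the residual angle between the corrected mean
#' and the expected direction (0 up to floating error by construction of the
#' minimal rotation; reported so stored calibrations are auditable).
#'
#' @param trace A trace tibble covering the reference window.
#' @param reference A [calibration_reference()].
#' @return A `mounting_correction` (fields `rotation`, `residual_angle`).
#' @export
#' @examples
#' pl <- session_plan(tibble::tibble(behaviour = "stand", duration = 30),
#'                    mounting_offset = rotation_about(c(0, 0, 1), 20), seed = 2)
#' ses <- compose_session(pl)
#' estimate_correction(ses$trace, calibration_reference(c(0, 10)))
estimate_correction <- function(trace, reference = calibration_reference()) {
  check_trace(trace)
  stopifnot(inherits(reference, "calibration_reference"))
  w <- reference$window
  if (w[1] < min(trace$time_s) - 1e-9 || w[2] > max(trace$time_s) + 1 / trace_rate(trace) + 1e-9) {
    abort("reference window must lie inside the trace")
  }
  in_w <- trace$time_s >= w[1] & trace$time_s < w[2]
  if (sum(in_w) < 2 * trace_rate(trace)) {
    abort("reference window contains fewer than 2 s of samples")
  }
  m <- c(mean(trace$heave_g[in_w]), mean(trace$surge_g[in_w]),
         mean(trace$sway_g[in_w]))
  if (sqrt(sum(m^2)) < 0.5) abort("reference window not static")
  R <- rotation_between(m, reference$expected_gravity)
  corrected <- as.numeric(R %*% m)
  new_mounting_correction(R, angle_between(corrected, reference$expected_gravity))
}

#' Apply a mounting correction to a trace
#'
#' Rotates every sample vector by the correction's rotation matrix. Vector
#' magnitudes and the time grid are untouched.
#'
#' @param trace A trace tibble.
#' @param correction A `mounting_correction`.
#' @return The corrected trace tibble.
#' @export
apply_correction <- function(trace, correction) {
  check_trace(trace)
  stopifnot(inherits(correction, "mounting_correction"))
  m <- as.matrix(trace[, c("heave_g", "surge_g", "sway_g")]) %*%
    t(correction$rotation)
  out <- trace
  out$heave_g <- m[, 1]; out$surge_g <- m[, 2]; out$sway_g <- m[, 3]
  out
}
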