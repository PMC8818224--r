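# Per-sample predictor channels.
#
# Fourteen channels per logging event: the raw tri-axial signal; the static
# (gravity/posture) component of each axis, a 2-second centred rolling mean;
# the dynamic component |raw - static| of each axis; VeDBA and VeSBA (the
# Euclidean norms of the dynamic and static vectors); Anim.stat (postural
# deviation angle from the calibrated resting orientation); and pitch and
# roll from the static vector.

#' Rolling static (gravity) component of one axis
#'
#' Centred moving average over a `window`-second window. The window length in
#' samples is `round(window * rate)`; at the edges the mean is taken over the
#' samples that exist (shrinking window). For even window lengths the window
#' extends one sample further forward than backward.
#'
#' @param signal Numeric vector, one axis in g.
#' @param rate Sampling rate, samples/s.
#' @param window Window length in seconds (default 2).
#' @return Numeric vector the same length as `signal`.
#' @export
#' @examples
#' rolling_static(rep(0.5, 100), rate = 30)[1]  # 0.5: mean of a constant
rolling_static <- function(signal, rate, window = 2) {
  if (length(signal) == 0) abort("`signal` is empty")
  w <- round(window * rate)
  if (w < 2) abort("`window` times `rate` must cover at least 2 samples")
  if (length(signal) < w) abort("signal shorter than one rolling window")
  as.numeric(zoo::rollapply(zoo::zoo(signal), width = w, FUN = mean,
                            align = "center", partial = TRUE))
}

#' Dynamic component of one axis
#'
#' The movement-driven residual `|raw - static|`, elementwise and
#' non-negative; sign information is deliberately discarded.
#'
#' @param raw,static Equal-length numeric vectors in g.
#' @return Non-negative numeric vector.
#' @export
dynamic_component <- function(raw, static) {
  if (length(raw) != length(static)) abort("`raw` and `static` lengths differ")
  abs(raw - static)
}

#' Vectorial dynamic body acceleration
#'
#' Per-sample Euclidean norm of the three dynamic components; the standard
#' movement-intensity proxy.
#'
#' @param dyn_h,dyn_s,dyn_w Equal-length dynamic components in g.
#' @return Non-negative numeric vector.
#' @export
#' @examples
#' vedba(0.3, 0.4, 0)  # 0.5
vedba <- function(dyn_h, dyn_s, dyn_w) {
  n <- length(dyn_h)
  if (length(dyn_s) != n || length(dyn_w) != n) abort("input lengths differ")
  sqrt(dyn_h^2 + dyn_s^2 + dyn_w^2)
}

#' Vectorial static body acceleration
#'
#' Per-sample Euclidean norm of the three static components; close to 1 g
#' whenever the animal is stationary and the trace is calibrated.
#'
#' @param stat_h,stat_s,stat_w Equal-length static components in g.
#' @return Non-negative numeric vector.
#' @export
vesba <- function(stat_h, stat_s, stat_w) {
  n <- length(stat_h)
  if (length(stat_s) != n || length(stat_w) != n) abort("input lengths differ")
  sqrt(stat_h^2 + stat_s^2 + stat_w^2)
}

#' Pitch and roll from the static vector
#'
#' Postural angles in degrees: `pitch = asin(static_surge / VeSBA)` (head-up
#' versus head-down tilt; +90 when gravity registers entirely in surge, i.e.
#' head pointing at the ground) and `roll = asin(static_sway / VeSBA)`
#' (lateral tilt). An upright stance (gravity in +heave) gives 0 for both.
#'
#' @param stat_h,stat_s,stat_w Equal-length static components in g.
#' @return A tibble with columns `pitch` and `roll`, degrees in
#'   `[-90, 90]`.
#' @export
#' @examples
#' pitch_roll(0, 1, 0)  # pitch 90: head-down posture
pitch_roll <- function(stat_h, stat_s, stat_w) {
  v <- vesba(stat_h, stat_s, stat_w)
  if (any(v == 0)) abort("pitch/roll undefined where the static vector is zero")
  clamp <- function(x) pmin(pmax(x, -1), 1)
  tibble(pitch = asin(clamp(stat_s / v)) * 180 / pi,
         roll = asin(clamp(stat_w / v)) * 180 / pi)
}

#' Animal static acceleration (postural deviation angle)
#'
#' Per-sample angle, in degrees, between the static acceleration vector and
#' the calibrated resting reference orientation (by default +heave, the
#' upright stance after calibration). 0 when the posture matches the
#' reference, 90 when orthogonal to it.
#'
#' @param stat_h,stat_s,stat_w Equal-length static components in g.
#' @param reference Length-3 reference orientation; normalised internally.
#' @return Numeric vector of angles in `[0, 180]` degrees.
#' @export
anim_stat <- function(stat_h, stat_s, stat_w, reference = c(1, 0, 0)) {
  v <- vesba(stat_h, stat_s, stat_w)
  if (any(v == 0)) abort("Anim.stat undefined where the static vector is zero")
  r <- reference / sqrt(sum(reference^2))
  dotp <- (stat_h * r[1] + stat_s * r[2] + stat_w * r[3]) / v
  acos(pmin(pmax(dotp, -1), 1)) * 180 / pi
}

#' Derive the 14 predictor channels from a calibrated trace
#'
#' Produces the full per-sample feature frame: `heave`, `surge`, `sway`
#' (raw), `static_heave`, `static_surge`, `static_sway`, `dynamic_heave`,
#' `dynamic_surge`, `dynamic_sway`, `vedba`, `vesba`, `anim_stat`, `pitch`,
#' `roll`, preceded by `time_s`. The trace should already be
#' mounting-corrected (see [apply_correction()]); `reference` is the resting
#' orientation used for `anim_stat` and defaults to the calibration target
#' +heave.
#'
#' @param trace A calibrated trace tibble.
#' @param window Rolling-mean window in seconds for the static component.
#' @param reference Resting reference orientation for `anim_stat`.
#' @return A tibble with `time_s` plus the 14 predictor columns.
#' @export
#' @examples
#' seg <- simulate_segment("stand", 10, noise_sd = 0, seed = 1)
#' head(derive_features(seg))
derive_features <- function(trace, window = 2, reference = c(1, 0, 0)) {
  check_trace(trace)
  rate <- trace_rate(trace)
  if (nrow(trace) < round(window * rate)) {
    abort("trace shorter than one rolling window")
  }
  sh <- rolling_static(trace$heave_g, rate, window)
  ss <- rolling_static(trace$surge_g, rate, window)
  sw <- rolling_static(trace$sway_g, rate, window)
  dh <- dynamic_component(trace$heave_g, sh)
  ds <- dynamic_component(trace$surge_g, ss)
  dw <- dynamic_component(trace$sway_g, sw)
  pr <- pitch_roll(sh, ss, sw)
  tibble(
    time_s = trace$time_s,
    heave = trace$heave_g, surge = trace$surge_g, sway = trace$sway_g,
    static_heave = sh, static_surge = ss, static_sway = sw,
    dynamic_heave = dh, dynamic_surge = ds, dynamic_sway = dw,
    vedba = vedba(dh, ds, dw),
    vesba = vesba(sh, ss, sw),
    anim_stat = anim_stat(sh, ss, sw, reference),
    pitch = pr$pitch, roll = pr$roll
  )
}

# The 14 predictor column names, in canonical order.
rf_predictors <- function() {
  c("heave", "surge", "sway", "static_heave", "static_surge", "static_sway",
    "dynamic_heave", "dynamic_surge", "dynamic_sway", "vedba", "vesba",
    "anim_stat", "pitch", "roll")
}
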