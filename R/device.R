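#' Data-logger device profile
#'
#' A device profile describes the operational envelope of an accelerometer
#' data logger: its sampling rate, the symmetric acceleration range it can
#' record before saturating, and its amplitude resolution (g per count;
#' 0 means the output is treated as continuous). Axis order is fixed as
#' (heave, surge, sway) throughout the package.
#'
#' @param name Short device label, e.g. `"CEFAS"`.
#' @param sampling_rate Recording frequency in samples per second; > 0.
#' @param max_accel Symmetric clip bound in g. Must exceed 1 g so that the
#'   gravity vector itself is always measurable.
#' @param resolution Amplitude resolution in g per count; `0` for continuous
#'   output.
#' @return A `device_profile` object (a named list).
#' @export
#' @examples
#' device_profile("toy", sampling_rate = 10, max_accel = 4)
device_profile <- function(name, sampling_rate, max_accel, resolution = 0) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be > 0")
  }
  if (!is.numeric(max_accel) || max_accel <= 1) {
    abort("`max_accel` must exceed 1 g (the device must be able to record gravity)")
  }
  if (!is.numeric(resolution) || resolution < 0) {
    abort("`resolution` must be >= 0")
  }
  structure(
    list(name = name, sampling_rate = as.numeric(sampling_rate),
         max_accel = as.numeric(max_accel), resolution = as.numeric(resolution),
         axis_order = c("heave", "surge", "sway")),
    class = "device_profile"
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("<device_profile> %s: %g Hz, +/-%g g, resolution %s\n",
              x$name, x$sampling_rate, x$max_accel,
              if (x$resolution > 0) paste0(x$resolution, " g") else "continuous"))
  invisible(x)
}

#' Built-in collar logger profiles
#'
#' The two collar-mounted loggers the package models: a CEFAS G6 class device
#' (30 Hz, +/-2.3 g, continuous output) and a GCDC X8M-3 class device (50 Hz,
#' +/-8.6 g, 0.001 g resolution).
#'
#' @return A named list with elements `cefas` and `gcdc`, each a
#'   [device_profile()].
#' @export
#' @examples
#' cheetah_devices()$cefas
cheetah_devices <- function() {
  list(
    cefas = device_profile("CEFAS", sampling_rate = 30, max_accel = 2.3,
                           resolution = 0),
    gcdc = device_profile("GCDC", sampling_rate = 50, max_accel = 8.6,
                          resolution = 0.001)
  )
}

#' Record an ideal trace through a device profile
#'
#' Takes an ideal (continuous, high-rate) trace and produces what the given
#' logger would have recorded: the signal is resampled onto the device's
#' uniform time grid by linear interpolation, clipped to `+/-max_accel` on
#' each axis, and, when the profile has a positive resolution, rounded to the
#' nearest multiple of that resolution. Upsampling is refused: the ideal
#' trace must be sampled at least as fast as the device records.
#'
#' The operation is idempotent: recording an already-recorded trace through
#' the same profile returns it unchanged.
#'
#' @param trace A trace tibble with columns `time_s`, `heave_g`, `surge_g`,
#'   `sway_g` on a uniform time grid.
#' @param device A [device_profile()].
#' @return A trace tibble at the device's sampling rate, with the device
#'   profile attached as attribute `"device"`.
#' @export
#' @examples
#' tr <- tibble::tibble(time_s = seq(0, 1, by = 0.01),
#'                      heave_g = 5, surge_g = 0, sway_g = 0)
#' max(apply_device(tr, cheetah_devices()$cefas)$heave_g)  # 2.3
apply_device <- function(trace, device) {
  check_trace(trace)
  stopifnot(inherits(device, "device_profile"))
  src_rate <- trace_rate(trace)
  if (src_rate < device$sampling_rate - 1e-9) {
    abort(sprintf(
      "ideal trace is sampled at %.3g Hz but the device records at %g Hz; upsampling is not supported",
      src_rate, device$sampling_rate))
  }
  t0 <- trace$time_s[1]
  t1 <- trace$time_s[nrow(trace)]
  new_t <- t0 + seq(0, floor((t1 - t0) * device$sampling_rate)) / device$sampling_rate
  resampled <- purrr::map(
    c(heave_g = "heave_g", surge_g = "surge_g", sway_g = "sway_g"),
    function(col) approx(trace$time_s, trace[[col]], xout = new_t)$y
  )
  out <- tibble(time_s = new_t, !!!resampled)
  quantise <- function(x) {
    x <- pmin(pmax(x, -device$max_accel), device$max_accel)
    if (device$resolution > 0) x <- round(x / device$resolution) * device$resolution
    x
  }
  out <- mutate(out, across(c("heave_g", "surge_g", "sway_g"), quantise))
  attr(out, "device") <- device
  class(out) <- c("accel_trace", class(tibble()))
  out
}

# --- internal trace helpers -------------------------------------------------

check_trace <- function(trace) {
  need <- c("time_s", "heave_g", "surge_g", "sway_g")
  if (!is.data.frame(trace) || !all(need %in% names(trace))) {
    abort(paste0("a trace needs columns ", paste(need, collapse = ", ")))
  }
  if (nrow(trace) < 2) abort("a trace needs at least two samples")
  invisible(trace)
}

trace_rate <- function(trace) {
  dt <- diff(trace$time_s)
  if (any(dt <= 0)) abort("trace time grid must be strictly increasing")
  1 / stats::median(dt)
}

new_accel_trace <- function(time_s, heave, surge, sway, device = NULL) {
  out <- tibble(time_s = time_s, heave_g = heave, surge_g = surge, sway_g = sway)
  if (!is.null(device)) attr(out, "device") <- device
  class(out) <- c("accel_trace", class(tibble()))
  out
}

# Fraction of samples saturated at the clip bound on any axis.
clipped_fraction <- function(trace, device = attr(trace, "device")) {
  stopifnot(!is.null(device))
  m <- as.matrix(trace[, c("heave_g", "surge_g", "sway_g")])
  mean(apply(abs(m) >= device$max_accel - 1e-12, 1, any))
}
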