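# Plain-text interchange formats: trace CSV (time_s,heave_g,surge_g,sway_g),
# label interval CSV (start_s,end_s,behaviour; half-open intervals), session
# plan YAML, and the 10-number calibration CSV.

#' Read and write trace CSV files
#'
#' Traces are exchanged as UTF-8 CSV with header
#' `time_s,heave_g,surge_g,sway_g` and `.` as the decimal separator, one file
#' per device.
#'
#' @param trace A trace tibble.
#' @param path File path.
#' @return `read_trace_csv()` returns a trace tibble; `write_trace_csv()`
#'   returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  check_trace(trace)
  readr::write_csv(trace[, c("time_s", "heave_g", "surge_g", "sway_g")], path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  check_trace(raw)
  new_accel_trace(raw$time_s, raw$heave_g, raw$surge_g, raw$sway_g)
}

#' Read and write behaviour label intervals
#'
#' Label tracks are exchanged as interval CSVs with header
#' `start_s,end_s,behaviour`; intervals are half-open `[start, end)`.
#'
#' @param intervals Tibble with columns `start_s`, `end_s`, `behaviour`.
#' @param path File path.
#' @return `read_labels_csv()` returns the interval tibble;
#'   `write_labels_csv()` returns `path` invisibly.
#' @export
write_labels_csv <- function(intervals, path) {
  stopifnot(all(c("start_s", "end_s", "behaviour") %in% names(intervals)))
  readr::write_csv(intervals[, c("start_s", "end_s", "behaviour")], path)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    start_s = readr::col_double(), end_s = readr::col_double(),
    behaviour = readr::col_character()))
}

#' Read and write session plans
#'
#' Session plans round-trip through a plain YAML file; the seed is part of
#' the file, so a stored plan regenerates its session exactly.
#'
#' @param plan A [session_plan()].
#' @param path File path.
#' @return `read_session_plan()` returns a [session_plan()];
#'   `write_session_plan()` returns `path` invisibly.
#' @export
write_session_plan <- function(plan, path) {
  stopifnot(inherits(plan, "session_plan"))
  yaml::write_yaml(list(
    rail_window = plan$rail_window,
    noise_sd = plan$noise_sd,
    seed = plan$seed,
    mounting_offset = if (is.null(plan$mounting_offset)) NULL else
      as.numeric(plan$mounting_offset),
    segments = purrr::map2(plan$segments$behaviour, plan$segments$duration,
                           function(b, d) list(behaviour = b, duration = d))
  ), path, precision = 17)  # full double precision so plans regenerate exactly
  invisible(path)
}

#' @rdname write_session_plan
#' @export
read_session_plan <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) abort("session plan file must contain a seed")
  session_plan(
    segments = tibble(
      behaviour = purrr::map_chr(raw$segments, "behaviour"),
      duration = purrr::map_dbl(raw$segments, "duration")
    ),
    rail_window = raw$rail_window %||% 10,
    mounting_offset = if (is.null(raw$mounting_offset)) NULL else
      matrix(unlist(raw$mounting_offset), 3, 3),
    noise_sd = raw$noise_sd %||% 0.05,
    seed = raw$seed
  )
}

#' Read and write mounting corrections
#'
#' A correction is persisted as a single CSV row: the nine rotation-matrix
#' entries in column-major order plus the residual angle, so calibrations are
#' auditable and reusable across a session.
#'
#' @param correction A `mounting_correction` from [estimate_correction()].
#' @param path File path.
#' @return `read_correction()` returns a `mounting_correction`;
#'   `write_correction()` returns `path` invisibly.
#' @export
write_correction <- function(correction, path) {
  stopifnot(inherits(correction, "mounting_correction"))
  row <- as.data.frame(as.list(c(
    stats::setNames(as.numeric(correction$rotation), paste0("r", 1:9)),
    residual_angle = correction$residual_angle)))
  readr::write_csv(row, path)
  invisible(path)
}

#' @rdname write_correction
#' @export
read_correction <- function(path) {
  row <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  R <- matrix(as.numeric(row[1, paste0("r", 1:9)]), 3, 3)
  new_mounting_correction(R, row$residual_angle[1])
}
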