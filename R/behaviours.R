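#' Behaviour signal specification
#'
#' A behaviour spec describes how one ethogram behaviour appears in collar
#' accelerometry: the posture (the direction gravity takes in device axes),
#' the intensity of body movement, and, for locomotory gaits, the stride rate
#' and the footfall pattern over one stride cycle.
#'
#' @param name Behaviour label.
#' @param static_orientation Length-3 numeric: the gravity direction in
#'   (heave, surge, sway) device axes; normalised internally.
#' @param dynamic_amplitude RMS amplitude (g) of the dynamic heave component.
#'   0 for a perfectly still posture.
#' @param stride_rate Strides per second; 0 for non-gait behaviours. A zero
#'   stride rate requires an empty footfall pattern and vice versa.
#' @param footfall_pattern A data frame with columns `limb` (one of `"FL"`,
#'   `"FR"`, `"BL"`, `"BR"`), `onset` (contact onset as a phase in [0, 1)),
#'   `duration` (contact duration as a fraction of the stride cycle), and
#'   `weight` (relative impulse amplitude). `NULL` for non-gait behaviours.
#' @param body_bounce Amplitude of the stride-frequency centre-of-mass
#'   oscillation, relative to the footfall impulse scale. This term places
#'   the dominant spectral line at the stride rate; the footfall impulses add
#'   the beat-frequency harmonics that distinguish the gaits.
#' @param duration_range Plausible bout duration range in seconds (metadata
#'   used when building session plans).
#' @return A `behaviour_spec` object.
#' @export
#' @examples
#' behaviour_spec("stand", c(1, 0, 0), dynamic_amplitude = 0.04)
behaviour_spec <- function(name, static_orientation, dynamic_amplitude,
                           stride_rate = 0, footfall_pattern = NULL,
                           body_bounce = 0.8, duration_range = c(2, 120)) {
  stopifnot(is.character(name), length(static_orientation) == 3)
  nrm <- sqrt(sum(static_orientation^2))
  if (nrm < 1e-9) abort("`static_orientation` must be a non-zero vector")
  if (dynamic_amplitude < 0) abort("`dynamic_amplitude` must be >= 0")
  has_pattern <- !is.null(footfall_pattern) && nrow(footfall_pattern) > 0
  if ((stride_rate == 0) == has_pattern) {
    abort("`stride_rate` must be 0 exactly when `footfall_pattern` is empty")
  }
  if (has_pattern) {
    need <- c("limb", "onset", "duration", "weight")
    stopifnot(all(need %in% names(footfall_pattern)))
    stopifnot(all(footfall_pattern$onset >= 0 & footfall_pattern$onset < 1),
              all(footfall_pattern$duration > 0 & footfall_pattern$duration <= 1),
              all(footfall_pattern$limb %in% c("FL", "FR", "BL", "BR")))
    footfall_pattern <- as_tibble(footfall_pattern)
  }
  structure(
    list(name = name,
         static_orientation = static_orientation / nrm,
         dynamic_amplitude = as.numeric(dynamic_amplitude),
         stride_rate = as.numeric(stride_rate),
         footfall_pattern = footfall_pattern,
         body_bounce = as.numeric(body_bounce),
         duration_range = duration_range),
    class = "behaviour_spec"
  )
}

#' @export
print.behaviour_spec <- function(x, ...) {
  cat(sprintf("<behaviour_spec> %s: amp %.2g g, stride %.2g /s\n",
              x$name, x$dynamic_amplitude, x$stride_rate))
  invisible(x)
}

footfalls <- function(...) {
  rows <- list(...)
  tibble(
    limb = purrr::map_chr(rows, 1),
    onset = purrr::map_dbl(rows, 2),
    duration = purrr::map_dbl(rows, 3),
    weight = purrr::map_dbl(rows, 4)
  )
}

#' Default behaviour specs for the cheetah ethogram
#'
#' Signal specs for the 17 fine-resolution behaviours: the four sedentary
#' postures (crouch, lie, sit, stand), head movement, the six stalk variants,
#' the four locomotory gaits (walk, trot, canter, gallop), pounce, and the
#' rag-bag "other" category. Postures drive the static (gravity) direction:
#' upright behaviours put gravity in heave, head-down stalking rotates it
#' towards surge, and lying rolls it towards sway. Gaits are built from
#' footfall-locked impulse trains over one stride cycle — walk a four-beat
#' sequence, trot a two-beat diagonal pattern, canter a three-beat 1-2-1
#' pattern, gallop a four-beat pattern with suspension — plus a stride-rate
#' body oscillation. Dynamic amplitudes are ordered
#' lie < stand < walk < trot < canter < gallop so that intermediate gaits are
#' genuinely confusable. Stride rates and amplitudes are package assumptions,
#' not measured values.
#'
#' @return A named list of [behaviour_spec()] objects.
#' @export
#' @examples
#' names(cheetah_behaviours())
cheetah_behaviours <- function() {
  walk_ff <- footfalls(list("BL", 0.00, 0.60, 1.00), list("FL", 0.25, 0.60, 0.50),
                       list("BR", 0.50, 0.60, 0.60), list("FR", 0.75, 0.60, 0.90))
  trot_ff <- footfalls(list("BL", 0.00, 0.35, 1.00), list("FR", 0.00, 0.35, 0.90),
                       list("BR", 0.50, 0.35, 0.55), list("FL", 0.50, 0.35, 0.50))
  canter_ff <- footfalls(list("BR", 0.00, 0.30, 1.00), list("BL", 0.30, 0.30, 0.80),
                         list("FR", 0.30, 0.30, 0.75), list("FL", 0.60, 0.30, 0.95))
  gallop_ff <- footfalls(list("BL", 0.00, 0.20, 1.00), list("BR", 0.12, 0.20, 0.80),
                         list("FL", 0.38, 0.20, 0.85), list("FR", 0.50, 0.20, 0.95))
  pounce_ff <- footfalls(list("BL", 0.00, 0.25, 1.00), list("BR", 0.02, 0.25, 0.95))

  specs <- list(
    behaviour_spec("crouch", c(0.97, 0.24, 0), 0.03),
    behaviour_spec("lie", c(0.25, 0.05, 0.97), 0.02),
    behaviour_spec("sit", c(0.93, 0.37, 0), 0.03),
    behaviour_spec("stand", c(1, 0, 0), 0.04),
    behaviour_spec("head movement", c(0.92, 0.39, 0), 0.12),
    behaviour_spec("crouching stalk", c(0.88, 0.48, 0), 0.04),
    behaviour_spec("lying stalk", c(0.30, 0.25, 0.92), 0.03),
    behaviour_spec("sitting stalk", c(0.84, 0.55, 0), 0.04),
    behaviour_spec("standing stalk", c(0.89, 0.45, 0.05), 0.05),
    behaviour_spec("walking stalk", c(0.87, 0.49, 0), 0.20,
                   stride_rate = 0.9, footfall_pattern = walk_ff, body_bounce = 0.6),
    behaviour_spec("trotting stalk", c(0.87, 0.48, 0.07), 0.55,
                   stride_rate = 1.6, footfall_pattern = trot_ff, body_bounce = 0.5),
    behaviour_spec("walk", c(0.99, 0.14, 0), 0.25,
                   stride_rate = 1.0, footfall_pattern = walk_ff, body_bounce = 0.6),
    behaviour_spec("trot", c(0.98, 0.18, 0), 0.70,
                   stride_rate = 1.8, footfall_pattern = trot_ff, body_bounce = 0.5),
    behaviour_spec("canter", c(0.98, 0.21, 0), 1.20,
                   stride_rate = 2.2, footfall_pattern = canter_ff, body_bounce = 0.9),
    behaviour_spec("gallop", c(0.96, 0.27, 0), 2.20,
                   stride_rate = 2.8, footfall_pattern = gallop_ff, body_bounce = 1.3),
    behaviour_spec("pounce", c(0.80, 0.60, 0), 1.80,
                   stride_rate = 0.8, footfall_pattern = pounce_ff, body_bounce = 1.5),
    behaviour_spec("other", c(0.90, 0.30, 0.31), 0.35)
  )
  stats::setNames(specs, purrr::map_chr(specs, "name"))
}
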