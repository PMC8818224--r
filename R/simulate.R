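# Ground-truthed collar-accelerometer signal simulator.
#
# Signal model per behaviour: 1 g of gravity projected onto the posture's
# static orientation, plus a dynamic component, plus i.i.d. Gaussian sensor
# noise per axis. For gaits the dynamic component is a footfall-locked train
# of raised-cosine impulses (heave, with smaller surge/sway components whose
# signs alternate with limb side and fore/hind position) plus a sinusoidal
# body oscillation at the stride rate; for non-gait movers it is smoothed
# broadband noise. The dynamic heave component is rescaled to the spec's RMS
# amplitude after synthesis.

# Relative size of the surge / sway impulse components and of the smoothed
# wobble on the off axes for non-gait movers.
.surge_frac <- 0.45
.sway_frac <- 0.30

#' Simulate one behaviour segment
#'
#' Generates an ideal (unclipped, continuous-amplitude) tri-axial trace for a
#' single behaviour bout. `spec` may be a [behaviour_spec()] or a behaviour
#' name, looked up in `specs`.
#'
#' @param spec A [behaviour_spec()] or a behaviour name.
#' @param duration Bout length in seconds; > 0.
#' @param rate Sampling rate of the ideal trace in samples/s (default 100,
#'   comfortably above both logger rates).
#' @param noise_sd Standard deviation of the additive Gaussian sensor noise,
#'   in g, per axis.
#' @param seed Optional integer seed; when given the segment is reproducible.
#' @param specs Named list of behaviour specs used to resolve a character
#'   `spec`.
#' @return A trace tibble (`time_s`, `heave_g`, `surge_g`, `sway_g`).
#' @export
#' @examples
#' seg <- simulate_segment("stand", duration = 5, noise_sd = 0, seed = 1)
#' colMeans(seg[, -1])  # close to (1, 0, 0): gravity in heave
simulate_segment <- function(spec, duration, rate = 100, noise_sd = 0.05,
                             seed = NULL, specs = cheetah_behaviours()) {
  if (is.character(spec)) {
    if (!spec %in% names(specs)) {
      abort(sprintf("unknown behaviour '%s'", spec))
    }
    spec <- specs[[spec]]
  }
  stopifnot(inherits(spec, "behaviour_spec"))
  if (duration <= 0) abort("`duration` must be > 0")
  if (rate <= 0) abort("`rate` must be > 0")

  gen <- function() {
    n <- max(2L, round(duration * rate))
    t <- (seq_len(n) - 1) / rate
    dyn <- dynamic_signal(spec, t, rate)
    g <- spec$static_orientation
    tibble(
      time_s = t,
      heave_g = g[1] + dyn$h + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0,
      surge_g = g[2] + dyn$s + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0,
      sway_g = g[3] + dyn$w + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    )
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  class(out) <- c("accel_trace", class(tibble()))
  out
}

# Dynamic (movement) component on the three axes, heave RMS == dynamic_amplitude.
dynamic_signal <- function(spec, t, rate) {
  n <- length(t)
  if (spec$dynamic_amplitude == 0) {
    return(list(h = numeric(n), s = numeric(n), w = numeric(n)))
  }
  if (spec$stride_rate > 0) {
    phase <- (t * spec$stride_rate) %% 1
    h <- s <- w <- numeric(n)
    for (i in seq_len(nrow(spec$footfall_pattern))) {
      ff <- spec$footfall_pattern[i, ]
      delta <- (phase - ff$onset) %% 1
      on <- delta < ff$duration
      pulse <- numeric(n)
      pulse[on] <- ff$weight * 0.5 * (1 - cos(2 * pi * delta[on] / ff$duration))
      h <- h + pulse
      s <- s + .surge_frac * pulse * (if (substr(ff$limb, 1, 1) == "F") 1 else -1)
      w <- w + .sway_frac * pulse * (if (substr(ff$limb, 2, 2) == "L") 1 else -1)
    }
    # centre-of-mass oscillation at the stride rate (trunk flexion for the
    # gallop, vertical bounce generally); dominates the periodogram fundamental
    h <- h + spec$body_bounce * sin(2 * pi * spec$stride_rate * t)
    s <- s + 0.5 * spec$body_bounce * cos(2 * pi * spec$stride_rate * t)
    h <- h - mean(h); s <- s - mean(s); w <- w - mean(w)
  } else {
    # non-gait mover: band-limited wobble (smoothed white noise)
    smooth_w <- max(3L, round(rate / 4))
    h <- smooth_noise(n, smooth_w)
    s <- .surge_frac / 0.45 * 0.6 * smooth_noise(n, smooth_w)
    w <- 0.6 * smooth_noise(n, smooth_w)
  }
  sc <- spec$dynamic_amplitude / max(sqrt(mean(h^2)), 1e-12)
  list(h = sc * h, s = sc * s, w = sc * w)
}

smooth_noise <- function(n, width) {
  x <- rnorm(n + width)
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))[
    seq(floor(width / 2) + 1, length.out = n)]
}

#' Session plan
#'
#' An ordered plan of behaviour bouts preceded by a rail-reference window
#' (the collar hanging on a rail before deployment: gravity along +heave,
#' no body movement), together with the simulated mounting offset, the sensor
#' noise level, and the seed that makes the whole session reproducible.
#'
#' @param segments Data frame with columns `behaviour` and `duration` (s).
#' @param rail_window Length of the leading rail-reference window, seconds;
#'   at least 4 s so that it spans two rolling-average windows.
#' @param mounting_offset A 3x3 rotation matrix simulating a non-centred
#'   device, or `NULL` for a perfectly centred mount.
#' @param noise_sd Per-axis Gaussian sensor noise sd in g.
#' @param seed Integer seed (mandatory).
#' @return A `session_plan` object.
#' @export
#' @examples
#' session_plan(tibble::tibble(behaviour = "lie", duration = 60), seed = 1)
session_plan <- function(segments, rail_window = 10, mounting_offset = NULL,
                         noise_sd = 0.05, seed) {
  stopifnot(is.data.frame(segments),
            all(c("behaviour", "duration") %in% names(segments)))
  if (nrow(segments) == 0) abort("a session plan needs at least one segment")
  if (any(segments$duration <= 0)) abort("segment durations must be > 0")
  if (rail_window < 4) abort("`rail_window` must be at least 4 s")
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory")
  if (!is.null(mounting_offset)) check_rotation(mounting_offset, "mounting_offset")
  structure(
    list(segments = as_tibble(segments), rail_window = rail_window,
         mounting_offset = mounting_offset, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "session_plan"
  )
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %d segments, %.0f s + %.0f s rail, seed %d\n",
              nrow(x$segments), sum(x$segments$duration), x$rail_window, x$seed))
  invisible(x)
}

#' Compose a full simulated session
#'
#' Concatenates the rail-reference window and the planned behaviour bouts
#' into one ideal trace, applies the plan's mounting-offset rotation to every
#' sample, and returns the trace with its per-sample label track and the
#' label intervals. The rail window is labelled `"unassignable"`; it carries
#' a known static direction (+heave) and no body movement, which is what the
#' calibration module exploits. Identical plans and seeds give identical
#' output.
#'
#' @param plan A [session_plan()].
#' @param specs Named list of [behaviour_spec()]s covering every planned
#'   behaviour.
#' @param rate Ideal sampling rate, samples/s.
#' @return A list with `trace` (trace tibble), `labels` (per-sample tibble
#'   `time_s`, `behaviour`), and `intervals` (tibble `start_s`, `end_s`,
#'   `behaviour`, half-open `[start, end)`).
#' @export
#' @examples
#' pl <- session_plan(tibble::tibble(behaviour = "lie", duration = 60), seed = 1)
#' ses <- compose_session(pl)
#' nrow(ses$trace)  # (10 + 60) s at 100 Hz
compose_session <- function(plan, specs = cheetah_behaviours(), rate = 100) {
  stopifnot(inherits(plan, "session_plan"))
  missing_specs <- setdiff(unique(plan$segments$behaviour), names(specs))
  if (length(missing_specs) > 0) {
    abort(paste0("no behaviour spec for: ", paste(missing_specs, collapse = ", ")))
  }
  rail_spec <- behaviour_spec("rail", c(1, 0, 0), dynamic_amplitude = 0)
  pieces <- vector("list", nrow(plan$segments) + 1)
  pieces[[1]] <- simulate_segment(rail_spec, plan$rail_window, rate,
                                  noise_sd = plan$noise_sd, seed = plan$seed)
  for (i in seq_len(nrow(plan$segments))) {
    pieces[[i + 1]] <- simulate_segment(
      plan$segments$behaviour[i], plan$segments$duration[i], rate,
      noise_sd = plan$noise_sd, seed = plan$seed + i, specs = specs)
  }
  durations <- c(plan$rail_window, plan$segments$duration)
  starts <- cumsum(c(0, head(durations, -1)))
  trace <- purrr::map2(pieces, starts,
                       function(p, s) mutate(p, time_s = .data$time_s + s)) |>
    purrr::list_rbind()
  if (!is.null(plan$mounting_offset)) {
    m <- as.matrix(trace[, c("heave_g", "surge_g", "sway_g")]) %*%
      t(plan$mounting_offset)
    trace$heave_g <- m[, 1]; trace$surge_g <- m[, 2]; trace$sway_g <- m[, 3]
  }
  class(trace) <- c("accel_trace", class(tibble()))
  labels_vec <- rep(c("unassignable", plan$segments$behaviour),
                    times = purrr::map_int(pieces, nrow))
  labels <- tibble(time_s = trace$time_s, behaviour = labels_vec)
  attr(labels, "level") <- "fine"
  intervals <- tibble(
    start_s = starts[-1],
    end_s = starts[-1] + plan$segments$duration,
    behaviour = plan$segments$behaviour
  )
  list(trace = trace, labels = labels, intervals = intervals)
}

#' Default exercise-bout session plans
#'
#' Ready-made plans emulating a lure-chase exercise session: the `"full"`
#' plan is a 12-minute bout of four active chases (stalks, walks, trots,
#' canters, gallops, the occasional pounce) punctuated by three lower
#' intensity rest periods, touching all 17 fine behaviours with a realistic
#' imbalance (lying most common, pounce and sitting stalk rare). The
#' `"small"` plan is a 2-minute cut covering 11 behaviours, sized for tests
#' and quick examples.
#'
#' @param size `"full"` (720 s of behaviour) or `"small"` (120 s).
#' @param seed Integer seed for the session.
#' @param mounting_offset Optional 3x3 rotation; defaults to a reproducible
#'   ~25 degree offset drawn from the seed.
#' @param noise_sd Sensor noise sd in g.
#' @return A [session_plan()].
#' @export
cheetah_session_plan <- function(size = c("full", "small"), seed = 1L,
                                 mounting_offset = random_mounting_offset(25, seed = seed + 97L),
                                 noise_sd = 0.05) {
  size <- match.arg(size)
  seg <- function(behaviour, duration) tibble(behaviour = behaviour, duration = duration)
  segments <- if (size == "small") {
    bind_rows(
      seg("lie", 20), seg("stand", 12), seg("head movement", 8),
      seg("lying stalk", 10), seg("walking stalk", 8), seg("walk", 14),
      seg("trotting stalk", 6), seg("trot", 10), seg("canter", 10),
      seg("gallop", 12), seg("other", 10)
    )
  } else {
    bind_rows(
      # rest 1
      seg("lie", 60), seg("sit", 18), seg("head movement", 8), seg("stand", 14),
      # chase 1
      seg("crouching stalk", 6), seg("lying stalk", 40), seg("standing stalk", 10),
      seg("walking stalk", 14), seg("walk", 20), seg("trot", 8),
      seg("canter", 12), seg("gallop", 16), seg("pounce", 1.5), seg("other", 12.5),
      # rest 2
      seg("lie", 70), seg("crouch", 6), seg("sit", 10),
      seg("head movement", 10), seg("stand", 16),
      # chase 2
      seg("lying stalk", 35), seg("sitting stalk", 2), seg("trotting stalk", 8),
      seg("walking stalk", 10), seg("walk", 16), seg("trot", 6),
      seg("canter", 10), seg("gallop", 14), seg("other", 15),
      # rest 3
      seg("lie", 65), seg("stand", 20), seg("sit", 8), seg("head movement", 6),
      # chase 4 (short)
      seg("standing stalk", 6), seg("lying stalk", 30), seg("walking stalk", 6),
      seg("trotting stalk", 6), seg("walk", 14), seg("trot", 4),
      seg("canter", 8), seg("gallop", 12), seg("pounce", 1),
      seg("other", 18), seg("crouching stalk", 2), seg("lying stalk", 15),
      seg("walk", 10), seg("canter", 4), seg("gallop", 8), seg("other", 9)
    )
  }
  session_plan(segments, rail_window = 10, mounting_offset = mounting_offset,
               noise_sd = noise_sd, seed = seed)
}
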