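# Behaviour vocabulary, label-track operations, and the fine -> medium ->
# coarse collapsing hierarchy.
#
# The fine resolution has 17 classes: the four sedentary postures, head
# movement, six stalk variants, the four gaits, pounce, and "other". At
# medium resolution the sedentary postures collapse to "sedentary", walking
# and trotting stalks to "moving stalk", and pounce joins "other" (it cannot
# be categorised reliably at that level). At coarse resolution locomotory
# behaviours (the gaits, the moving stalks, and pounce) are "active",
# non-locomotory behaviours other than head movement are "inactive", and
# head movement and "other" survive as their own classes.

.unassignable <- "unassignable"

#' Behaviour hierarchy
#'
#' Builds and validates a fine/medium/coarse collapsing hierarchy from a
#' three-column data frame. Both maps must be total over the fine
#' vocabulary, and the rag-bag class `"other"` must map to itself at every
#' level.
#'
#' @param df Data frame with columns `fine`, `medium`, `coarse`, one row per
#'   fine behaviour.
#' @return A `behaviour_hierarchy` tibble.
#' @export
behaviour_hierarchy <- function(df) {
  need <- c("fine", "medium", "coarse")
  if (!all(need %in% names(df))) {
    abort("a hierarchy needs columns fine, medium, coarse")
  }
  df <- as_tibble(df)[, need]
  if (anyDuplicated(df$fine)) abort("duplicated fine labels in hierarchy")
  if (anyNA(df)) abort("hierarchy maps must be total (no missing images)")
  oth <- df[df$fine == "other", ]
  if (nrow(oth) == 1 && !(oth$medium == "other" && oth$coarse == "other")) {
    abort("'other' must map to 'other' at every level")
  }
  class(df) <- c("behaviour_hierarchy", class(df))
  df
}

#' The cheetah ethogram hierarchy
#'
#' The packaged 17-class fine vocabulary with its medium (12-class) and
#' coarse (4-class) collapsing maps, read from
#' `extdata/cheetah_ethogram.csv`; users can supply any other ethogram in
#' the same three-column format via [behaviour_hierarchy()].
#'
#' @return A `behaviour_hierarchy` tibble.
#' @export
#' @examples
#' cheetah_hierarchy()
cheetah_hierarchy <- function() {
  path <- system.file("extdata", "cheetah_ethogram.csv", package = "accelcat")
  behaviour_hierarchy(readr::read_csv(path, col_types = "ccc", progress = FALSE))
}

#' Align interval labels with a trace
#'
#' Gives every sample the behaviour of the interval containing its
#' timestamp. Intervals are half-open `[start_s, end_s)`, so a sample on a
#' boundary belongs to the later interval; samples not covered by any
#' interval become `"unassignable"`.
#'
#' @param trace A trace tibble.
#' @param intervals Tibble with columns `start_s`, `end_s`, `behaviour`;
#'   must be non-overlapping.
#' @return A label track: tibble with `time_s` and `behaviour`, tagged with
#'   attribute `level = "fine"`.
#' @export
align_labels <- function(trace, intervals) {
  check_trace(trace)
  stopifnot(all(c("start_s", "end_s", "behaviour") %in% names(intervals)))
  iv <- arrange(as_tibble(intervals), .data$start_s)
  if (nrow(iv) > 1) {
    bad <- which(iv$start_s[-1] < iv$end_s[-nrow(iv)] - 1e-12)
    if (length(bad) > 0) {
      abort(sprintf("overlapping label intervals: [%g, %g) and [%g, %g)",
                    iv$start_s[bad[1]], iv$end_s[bad[1]],
                    iv$start_s[bad[1] + 1], iv$end_s[bad[1] + 1]))
    }
  }
  idx <- findInterval(trace$time_s + 1e-12, iv$start_s)
  lab <- rep(.unassignable, nrow(trace))
  hit <- idx > 0
  hit[hit] <- trace$time_s[hit] < iv$end_s[idx[hit]] - 1e-12
  lab[hit] <- iv$behaviour[idx[hit]]
  out <- tibble(time_s = trace$time_s, behaviour = lab)
  attr(out, "level") <- "fine"
  out
}

#' Remove unassignable rows
#'
#' Drops every row whose `behaviour` is `"unassignable"` (intervals where
#' the animal could not be seen clearly) and reports how many were removed.
#'
#' @param data Any data frame with a `behaviour` column.
#' @return The filtered data frame, with the removed-row count in attribute
#'   `"removed"`.
#' @export
drop_unassignable <- function(data) {
  stopifnot("behaviour" %in% names(data))
  keep <- data$behaviour != .unassignable
  out <- data[keep, , drop = FALSE]
  removed <- sum(!keep)
  if (removed > 0) {
    message(sprintf("removed %d unassignable logging events", removed))
  }
  if (nrow(out) == 0) warn("all rows were unassignable; dataset is empty")
  attr(out, "removed") <- removed
  out
}

#' Collapse behaviour labels to a coarser resolution
#'
#' Replaces each fine label by its image under the hierarchy's medium or
#' coarse map. Labels already at the target level pass through unchanged,
#' so collapsing is idempotent by level; `"unassignable"` also passes
#' through. Any other unknown label is an error.
#'
#' @param labels A character vector of labels, or a data frame with a
#'   `behaviour` column (returned in kind).
#' @param to Target level, `"medium"` or `"coarse"` (or `"fine"`, the
#'   identity).
#' @param hierarchy A [behaviour_hierarchy()].
#' @return Collapsed labels, same shape and length as the input.
#' @export
#' @examples
#' collapse_labels(c("lie", "walk", "pounce"), "coarse")
collapse_labels <- function(labels, to = c("medium", "coarse", "fine"),
                            hierarchy = cheetah_hierarchy()) {
  to <- match.arg(to)
  if (is.data.frame(labels)) {
    out <- labels
    out$behaviour <- collapse_labels(labels$behaviour, to, hierarchy)
    attr(out, "level") <- to
    return(out)
  }
  if (to == "fine") return(labels)
  map <- stats::setNames(hierarchy[[to]], hierarchy$fine)
  # identity on the target vocabulary makes collapsing idempotent by level
  for (lv in unique(hierarchy[[to]])) map[lv] <- lv
  map[.unassignable] <- .unassignable
  unknown <- setdiff(unique(labels), names(map))
  if (length(unknown) > 0) {
    abort(paste0("labels absent from the hierarchy: ",
                 paste(unknown, collapse = ", ")))
  }
  unname(map[labels])
}

#' Count events per behaviour label
#'
#' Exact multiset counts of a label track; counts always sum to the track
#' length.
#'
#' @param labels Character vector or data frame with a `behaviour` column.
#' @return Tibble with columns `behaviour` and `n`, sorted by label.
#' @export
count_by_label <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$behaviour
  tibble(behaviour = labels) |> count(.data$behaviour) |> arrange(.data$behaviour)
}

#' Attach a label track to a feature frame
#'
#' Joins per-sample features and labels positionally (both are on the same
#' time grid) into one labelled dataset ready for [split_dataset()].
#'
#' @param features A feature frame from [derive_features()].
#' @param labels A label track from [align_labels()].
#' @param device Optional device name recorded in attribute `"device_name"`.
#' @return The feature tibble with a `behaviour` column appended.
#' @export
label_features <- function(features, labels, device = NULL) {
  if (is.data.frame(labels)) {
    if (nrow(labels) != nrow(features)) {
      abort("feature frame and label track lengths differ")
    }
    labels <- labels$behaviour
  }
  if (length(labels) != nrow(features)) {
    abort("feature frame and label track lengths differ")
  }
  out <- mutate(features, behaviour = labels)
  if (!is.null(device)) attr(out, "device_name") <- device
  out
}

#' Published cheetah event counts and accuracy tables
#'
#' Reference tables from a captive-cheetah lure-chase deployment of the two
#' modelled logger types (CEFAS and GCDC): `cheetah_event_counts()` gives
#' the number of logging events per fine behaviour and device, and
#' `cheetah_reported_accuracy()` the per-behaviour validation
#' categorisation accuracy (%) per device at each model resolution. They
#' ship with the package so that the hierarchy aggregates and the
#' device-comparison arithmetic can be recomputed without the original
#' recordings.
#'
#' @return `cheetah_event_counts()`: tibble `behaviour`, `cefas`, `gcdc`
#'   (event counts). `cheetah_reported_accuracy()`: tibble `model`
#'   (fine/medium/coarse), `behaviour`, `cefas`, `gcdc` (accuracy %).
#' @export
cheetah_event_counts <- function() {
  path <- system.file("extdata", "reported_event_counts.csv", package = "accelcat")
  readr::read_csv(path, col_types = "cii", progress = FALSE)
}

#' @rdname cheetah_event_counts
#' @export
cheetah_reported_accuracy <- function() {
  path <- system.file("extdata", "reported_accuracy.csv", package = "accelcat")
  readr::read_csv(path, col_types = "ccdd", progress = FALSE)
}
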