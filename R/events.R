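# Events, epochs, and slicing.
#
# Epoch semantics: event i opens the half-open window [t_i, t_{i+1}); the
# final event is a pure terminator.  With only start/end events the whole
# recording is one epoch.  Half-open windows tile the span exactly, so
# per-epoch counts of interval events (assigned by midpoint) are conserved.

#' Replace the events stream of a recording
#'
#' Overwrites the recording's events with a user-supplied list, e.g. triggers
#' exported from a stimulus-delivery program or another device; no merging
#' with the original events occurs.  All other streams are untouched.
#'
#' @param rec a [gaze_recording].
#' @param events data.frame `name`, `ts` (ns, recording clock).
#' @return the recording with `events` replaced.
#' @export
replace_events <- function(rec, events) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (is.null(events$name) || is.null(events$ts) || nrow(events) == 0L) {
    gp_stop("events", "replacement events need non-empty 'name' and 'ts'")
  }
  sp <- recording_span(rec)
  if (all(events$ts < sp[1] | events$ts > sp[2])) {
    gp_stop("events", sprintf(
      "all %d replacement events fall outside the recording span [%.0f, %.0f] ns",
      nrow(events), sp[1], sp[2]))
  }
  events <- events[order_by_ts(events$ts), c("name", "ts"), drop = FALSE]
  rownames(events) <- NULL
  rec$events <- events
  gp_log("events", sprintf("events replaced: %d rows", nrow(events)))
  rec
}

#' Build epochs from an event sequence
#'
#' Every event except the last opens an epoch named after it and closed by
#' the next event's timestamp: n events give n - 1 contiguous, pairwise
#' disjoint half-open epochs that tile `[t_1, t_n)`.  A recording holding
#' only start and end events therefore yields a single epoch covering the
#' whole recording.
#'
#' @param events data.frame `name`, `ts`, at least 2 rows.
#' @return data.frame `name`, `start_ts`, `end_ts`, `duration_ms`.
#' @export
build_epochs <- function(events) {
  if (is.null(events) || nrow(events) < 2L) {
    gp_stop("epochs", "need at least 2 events (start and end) to build epochs")
  }
  events <- events[order_by_ts(events$ts), , drop = FALSE]
  n <- nrow(events)
  ep <- data.frame(
    name = events$name[-n],
    start_ts = events$ts[-n],
    end_ts = events$ts[-1L],
    stringsAsFactors = FALSE
  )
  ep <- ep[ep$end_ts > ep$start_ts, , drop = FALSE]  # drop zero-width ties
  ep$duration_ms <- ns_to_ms(ep$end_ts - ep$start_ts)
  rownames(ep) <- NULL
  ep
}

in_epoch_point <- function(ts, epoch) ts >= epoch$start_ts & ts < epoch$end_ts

in_epoch_interval <- function(start_ts, end_ts, epoch) {
  mid <- (start_ts + end_ts) / 2
  mid >= epoch$start_ts & mid < epoch$end_ts
}

#' Restrict a recording to one epoch
#'
#' Point samples (gaze, pupil, surface, events) are kept when
#' `start_ts <= t < end_ts`.  Interval events (fixations, blinks, saccades)
#' are assigned by their midpoint and never split, so for any partition of
#' the timeline into epochs each interval is counted in exactly one epoch.
#'
#' @param rec a [gaze_recording].
#' @param epoch one-row data.frame (or list) with `start_ts`, `end_ts`.
#' @return a `gaze_recording` restricted to the epoch.
#' @export
slice_recording <- function(rec, epoch) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (epoch$end_ts <= epoch$start_ts) {
    gp_log("epochs", "empty epoch slice requested")
  }
  keep_pt <- function(df) df[in_epoch_point(df$ts, epoch), , drop = FALSE]
  keep_iv <- function(df) {
    df[in_epoch_interval(df$start_ts, df$end_ts, epoch), , drop = FALSE]
  }
  out <- rec
  out$gaze <- keep_pt(rec$gaze)
  out$pupil <- keep_pt(rec$pupil)
  out$surface_gaze <- keep_pt(rec$surface_gaze)
  out$surface_fixations <- keep_pt(rec$surface_fixations)
  out$events <- keep_pt(rec$events)
  out$fixations <- keep_iv(rec$fixations)
  out$blinks <- keep_iv(rec$blinks)
  out$saccades <- keep_iv(rec$saccades)
  for (s in c("gaze", "pupil", "surface_gaze", "surface_fixations", "events",
              "fixations", "blinks", "saccades")) {
    rownames(out[[s]]) <- NULL
  }
  out
}
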