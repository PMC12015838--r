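# The in-memory recording model: a bundle of parallel time-stamped streams
# sharing one session clock.

#' Construct a gaze recording
#'
#' Bundles the parallel streams of one eye-tracking session.  All streams are
#' sorted by timestamp on construction (stable with respect to file order).
#' Timestamps are nanoseconds on the shared session clock; durations are
#' milliseconds; pupil diameters are millimetres.
#'
#' @param gaze data.frame with columns `ts`, `x`, `y`, `worn`,
#'   `fixation_id`, `blink_id` (scene-camera pixels).
#' @param fixations data.frame `id`, `start_ts`, `end_ts`, `duration_ms`,
#'   `x`, `y` (centroid).
#' @param blinks data.frame `id`, `start_ts`, `end_ts`, `duration_ms`.
#' @param saccades data.frame `id`, `start_ts`, `end_ts`, `duration_ms`,
#'   `amplitude_px`, `mean_velocity`, `peak_velocity` (px/s).
#' @param pupil data.frame `ts`, `diameter_left`, `diameter_right`,
#'   `diameter` (mm; `diameter` is resolved from left/right when absent).
#' @param events data.frame `name`, `ts`.
#' @param surface_gaze,surface_fixations enrichment streams: `ts`,
#'   `on_surface`, `sx`, `sy` (surface-normalised coordinates in `[0, 1]`).
#' @param participant participant code (kept verbatim in reports).
#' @return an object of class `gaze_recording`.
#' @export
gaze_recording <- function(gaze, fixations, blinks, saccades, pupil, events,
                           surface_gaze, surface_fixations,
                           participant = "anonymous") {
  rec <- list(
    gaze = gaze[order_by_ts(gaze$ts), , drop = FALSE],
    fixations = fixations[order_by_ts(fixations$start_ts), , drop = FALSE],
    blinks = blinks[order_by_ts(blinks$start_ts), , drop = FALSE],
    saccades = saccades[order_by_ts(saccades$start_ts), , drop = FALSE],
    pupil = pupil[order_by_ts(pupil$ts), , drop = FALSE],
    events = events[order_by_ts(events$ts), , drop = FALSE],
    surface_gaze = surface_gaze[order_by_ts(surface_gaze$ts), , drop = FALSE],
    surface_fixations =
      surface_fixations[order_by_ts(surface_fixations$ts), , drop = FALSE],
    participant = participant
  )
  for (s in names(rec)[1:8]) rownames(rec[[s]]) <- NULL
  structure(rec, class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  sp <- recording_span(x)
  cat(sprintf("<gaze_recording> participant '%s'\n", x$participant))
  cat(sprintf("  span: %.3f s (%.0f ns to %.0f ns)\n",
              (sp[2] - sp[1]) / NS_PER_S, sp[1], sp[2]))
  cat(sprintf(
    "  gaze %d | fixations %d | blinks %d | saccades %d | pupil %d\n",
    nrow(x$gaze), nrow(x$fixations), nrow(x$blinks), nrow(x$saccades),
    nrow(x$pupil)))
  cat(sprintf("  events %d | surface gaze %d | surface fixations %d\n",
              nrow(x$events), nrow(x$surface_gaze),
              nrow(x$surface_fixations)))
  invisible(x)
}

#' Time span of a recording
#'
#' @param rec a `gaze_recording`.
#' @return numeric `c(start_ts, end_ts)` in nanoseconds covering every
#'   stream (point timestamps and interval endpoints).
#' @export
recording_span <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  ts <- c(rec$gaze$ts, rec$pupil$ts, rec$events$ts, rec$surface_gaze$ts,
          rec$fixations$start_ts, rec$fixations$end_ts,
          rec$blinks$start_ts, rec$blinks$end_ts,
          rec$saccades$start_ts, rec$saccades$end_ts)
  ts <- ts[is.finite(ts)]
  if (!length(ts)) return(c(0, 0))
  c(min(ts), max(ts))
}

issue <- function(kind, stream, message, ids = integer()) {
  data.frame(kind = kind, stream = stream, message = message,
             ids = I(list(ids)), stringsAsFactors = FALSE)
}

#' Validate a recording's internal consistency
#'
#' Pure report: scans the streams for structural problems and returns them as
#' machine-readable issues without modifying anything.  Checks: monotone
#' timestamps per stream, interval sanity (`end_ts > start_ts`), duration
#' consistency with the timestamp pair (within 1 ms), pairwise blink
#' overlap, and gaze `fixation_id`/`blink_id` references that are absent
#' from the corresponding interval table.
#'
#' @param rec a `gaze_recording`.
#' @return data.frame of issues (`kind`, `stream`, `message`, `ids`); zero
#'   rows means clean.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  issues <- list()
  add <- function(x) issues[[length(issues) + 1L]] <<- x

  for (s in c("gaze", "pupil", "surface_gaze")) {
    ts <- rec[[s]]$ts
    if (length(ts) > 1L && any(diff(ts) <= 0)) {
      add(issue("non_monotonic", s,
                sprintf("%d non-increasing timestamp step(s) in %s",
                        sum(diff(ts) <= 0), s)))
    }
  }
  for (s in c("fixations", "blinks", "saccades")) {
    tab <- rec[[s]]
    bad <- which(tab$end_ts <= tab$start_ts)
    if (length(bad)) {
      add(issue("empty_interval", s,
                sprintf("%d interval(s) with end <= start in %s",
                        length(bad), s), tab$id[bad]))
    }
    dur <- ns_to_ms(tab$end_ts - tab$start_ts)
    off <- which(abs(dur - tab$duration_ms) > 1)
    if (length(off)) {
      add(issue("duration_mismatch", s,
                sprintf("%d %s duration(s) disagree with timestamps by >1 ms",
                        length(off), s), tab$id[off]))
    }
  }
  # pairwise blink overlap (blinks are sorted by start)
  b <- rec$blinks
  if (nrow(b) > 1L) {
    for (i in seq_len(nrow(b) - 1L)) {
      if (b$end_ts[i] > b$start_ts[i + 1L]) {
        add(issue("overlap", "blinks",
                  sprintf("blinks %d and %d overlap", b$id[i], b$id[i + 1L]),
                  c(b$id[i], b$id[i + 1L])))
      }
    }
  }
  # dangling references from gaze
  for (ref in c(fixation_id = "fixations", blink_id = "blinks")) {
    col <- names(which(ref == c(fixation_id = "fixations",
                                blink_id = "blinks")))
    ids <- unique(rec$gaze[[col]])
    ids <- ids[!is.na(ids)]
    missing <- setdiff(ids, rec[[ref]]$id)
    if (length(missing)) {
      add(issue("dangling_reference", "gaze",
                sprintf("gaze references %s value(s) absent from %s: %s",
                        col, ref, paste(missing, collapse = ", ")),
                missing))
    }
  }
  both <- which(!is.na(rec$gaze$fixation_id) & !is.na(rec$gaze$blink_id))
  if (length(both)) {
    add(issue("conflicting_labels", "gaze",
              sprintf("%d gaze sample(s) carry both fixation and blink ids",
                      length(both))))
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(kind = character(), stream = character(),
               message = character(), ids = I(list()),
               stringsAsFactors = FALSE)
}
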