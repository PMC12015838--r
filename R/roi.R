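# Region-of-interest (ROI) annotation.
#
# ROI membership is consumed from the enrichment stream (the vendor's
# surface mapping), never recomputed geometrically.  Gaze and pupil samples
# take the flag of the temporally nearest surface sample within a matching
# tolerance; saccades take a majority vote over their window; blinks — whose
# gaze is absent while the lid is closed — fall back to the surface status
# just before onset, then just after offset.  Unknowns default to off-ROI
# (0/false), never missing, so downstream sums stay well defined.

# index of the temporally nearest element of sorted ref_ts for each query
nearest_index <- function(query_ts, ref_ts) {
  n <- length(ref_ts)
  lo <- findInterval(query_ts, ref_ts)            # last ref <= query (0 if none)
  hi <- pmin(lo + 1L, n)
  lo <- pmax(lo, 1L)
  pick_hi <- abs(ref_ts[hi] - query_ts) < abs(ref_ts[lo] - query_ts)
  ifelse(pick_hi, hi, lo)
}

#' Annotate gaze samples with ROI membership
#'
#' Assigns each gaze frame the binary value 1 (gaze on the ROI) or 0 taken
#' from the temporally nearest enrichment sample.  Frames farther than
#' `tolerance_ms` from any surface sample default to 0 and are counted in
#' one gap warning.
#'
#' @param gaze gaze data.frame (`ts`, ...).
#' @param surface_gaze enrichment data.frame (`ts`, `on_surface`).
#' @param tolerance_ms matching tolerance; the default 25 ms spans several
#'   nominal 200 Hz sample periods, absorbing jitter without bridging gaps.
#' @return integer vector (0/1), one per gaze row.
#' @export
annotate_gaze_on_roi <- function(gaze, surface_gaze, tolerance_ms = 25) {
  if (nrow(surface_gaze) == 0L) {
    gp_stop("roi", "empty enrichment stream: this version requires enrichment")
  }
  if (nrow(gaze) == 0L) return(integer())
  idx <- nearest_index(gaze$ts, surface_gaze$ts)
  gap <- abs(surface_gaze$ts[idx] - gaze$ts) > tolerance_ms * NS_PER_MS
  flag <- as.integer(surface_gaze$on_surface[idx] %in% TRUE)
  flag[gap] <- 0L
  if (any(gap)) {
    gp_warn("roi", sprintf(
      "%d gaze frame(s) beyond the %g ms enrichment matching tolerance; set to 0",
      sum(gap), tolerance_ms))
  }
  flag
}

#' Annotate pupil samples with ROI membership
#'
#' Nearest-sample rule as for gaze; the flag is stored as logical
#' TRUE/FALSE on the pupil stream.
#'
#' @inheritParams annotate_gaze_on_roi
#' @param pupil pupil data.frame (`ts`, ...).
#' @return logical vector, one per pupil row.
#' @export
annotate_pupil_on_roi <- function(pupil, surface_gaze, tolerance_ms = 25) {
  if (nrow(pupil) == 0L) return(logical())
  annotate_gaze_on_roi(pupil, surface_gaze, tolerance_ms) == 1L
}

#' Annotate interval events (blinks or saccades) with ROI membership
#'
#' Saccades have valid gaze throughout, so `on_roi` is the majority vote of
#' the surface samples overlapping `[start_ts, end_ts)`, ties resolved by the
#' status at onset.  Blinks have no usable gaze mid-interval, so `on_roi` is
#' the status of the last surface sample at or before onset (lookback up to
#' `lookaround_ms`), else the first sample at or after offset (lookahead up
#' to `lookaround_ms`), else FALSE with a warning.
#'
#' @param intervals data.frame `id`, `start_ts`, `end_ts` (sorted,
#'   non-overlapping).
#' @param surface_gaze enrichment data.frame (`ts`, `on_surface`).
#' @param policy `"majority"` (saccades) or `"blink"` (lookback/lookahead).
#' @param lookaround_ms blink lookback/lookahead horizon (default 200 ms).
#' @return the intervals with a logical `on_roi` column added; counts,
#'   timestamps and durations are untouched.
#' @export
annotate_intervals_on_roi <- function(intervals, surface_gaze,
                                      policy = c("majority", "blink"),
                                      lookaround_ms = 200) {
  policy <- match.arg(policy)
  if (nrow(surface_gaze) == 0L) {
    gp_stop("roi", "empty enrichment stream: this version requires enrichment")
  }
  n <- nrow(intervals)
  if (n == 0L) {
    intervals$on_roi <- logical()
    return(intervals)
  }
  sts <- surface_gaze$ts
  son <- surface_gaze$on_surface %in% TRUE
  look_ns <- lookaround_ms * NS_PER_MS
  flag <- logical(n)
  defaulted <- 0L
  for (i in seq_len(n)) {
    a <- intervals$start_ts[i]
    b <- intervals$end_ts[i]
    if (policy == "majority") {
      inside <- which(sts >= a & sts < b)
      if (length(inside)) {
        votes <- sum(son[inside])
        if (votes * 2 != length(inside)) {
          flag[i] <- votes * 2 > length(inside)
          next
        }
      }
      # tie or no overlapping samples: status at onset (nearest sample)
      flag[i] <- son[nearest_index(a, sts)]
    } else {
      before <- which(sts <= a & sts >= a - look_ns)
      after <- which(sts >= b & sts <= b + look_ns)
      if (length(before)) {
        flag[i] <- son[max(before)]
      } else if (length(after)) {
        flag[i] <- son[min(after)]
      } else {
        flag[i] <- FALSE
        defaulted <- defaulted + 1L
      }
    }
  }
  if (defaulted > 0L) {
    gp_warn("roi", sprintf(
      "%d blink(s) isolated by more than %g ms from any surface sample; on_roi defaulted to FALSE",
      defaulted, lookaround_ms))
  }
  intervals$on_roi <- flag
  intervals
}

#' Annotate every stream of a recording with ROI membership
#'
#' Convenience wrapper applying [annotate_gaze_on_roi()] (gaze, as `on_roi`
#' 0/1), [annotate_pupil_on_roi()] (pupil, TRUE/FALSE) and
#' [annotate_intervals_on_roi()] (blinks with the blink policy, saccades
#' with the majority policy).  Only flags are added; no stream's counts,
#' timestamps or durations change.
#'
#' @param rec a [gaze_recording].
#' @param tolerance_ms nearest-sample matching tolerance for point streams.
#' @param lookaround_ms blink lookback/lookahead horizon.
#' @return the annotated recording.
#' @export
annotate_recording <- function(rec, tolerance_ms = 25, lookaround_ms = 200) {
  stopifnot(inherits(rec, "gaze_recording"))
  rec$gaze$on_roi <- annotate_gaze_on_roi(rec$gaze, rec$surface_gaze,
                                          tolerance_ms)
  rec$pupil$on_roi <- annotate_pupil_on_roi(rec$pupil, rec$surface_gaze,
                                            tolerance_ms)
  rec$blinks <- annotate_intervals_on_roi(rec$blinks, rec$surface_gaze,
                                          policy = "blink",
                                          lookaround_ms = lookaround_ms)
  rec$saccades <- annotate_intervals_on_roi(rec$saccades, rec$surface_gaze,
                                            policy = "majority")
  gp_log("roi", "ROI annotation added to gaze, pupil, blinks, saccades")
  rec
}

#' Fraction of flagged samples
#'
#' Mean of a binary ROI-membership sequence: the fraction of time (in
#' samples) spent on the ROI.
#'
#' @param flags logical or 0/1 vector, non-empty.
#' @return fraction in `[0, 1]`.
#' @export
roi_occupancy_fraction <- function(flags) {
  if (length(flags) == 0L) gp_stop("roi", "empty flag sequence")
  mean(as.numeric(flags))
}
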