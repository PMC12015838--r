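# Inter-fixation gaze movements.
#
# Detection of fixations/saccades is the device's job; here we segment the
# already-labelled gaze stream.  A movement k is the ordered run of gaze
# samples strictly between the last sample of fixation k and the first
# sample of fixation k+1 (by fixation-table order).  Samples inside blinks
# are excluded (lid-closed gaze is noise); samples before the first or after
# the last fixation belong to no movement.

#' Index inter-fixation movements on the gaze stream
#'
#' Adds a `movement_id` column: samples without a fixation id that lie
#' strictly between the last sample of fixation k and the first sample of
#' fixation k+1 receive movement id k.  Samples carrying a blink id, and
#' samples before the first or after the last fixation, receive no id.
#'
#' @param gaze gaze data.frame with `ts` and `fixation_id` (and optionally
#'   `blink_id`) columns, sorted by `ts`.
#' @return the gaze data.frame with an integer `movement_id` column.
#' @export
index_movements <- function(gaze) {
  gaze$movement_id <- rep(NA_integer_, nrow(gaze))
  fid <- gaze$fixation_id
  present <- sort(unique(fid[!is.na(fid)]))
  if (length(present) == 0L) {
    gp_warn("movements", "no fixation ids on the gaze stream; nothing indexed")
    return(gaze)
  }
  if (length(present) == 1L) return(gaze)
  in_blink <- if (is.null(gaze$blink_id)) rep(FALSE, nrow(gaze)) else
    !is.na(gaze$blink_id)
  for (k in seq_len(length(present) - 1L)) {
    a <- present[k]
    b <- present[k + 1L]
    last_a <- max(which(fid %in% a))
    first_b <- min(which(fid %in% b))
    if (first_b - last_a > 1L) {
      run <- (last_a + 1L):(first_b - 1L)
      run <- run[is.na(fid[run]) & !in_blink[run]]
      gaze$movement_id[run] <- a
    }
  }
  gaze
}

#' Extract movements with path metrics
#'
#' One movement per distinct `movement_id`, with duration (ms), path length
#' (sum of consecutive Euclidean steps, px) and displacement (first-to-last
#' Euclidean distance, px).  A single-sample movement has zero path length
#' and displacement and is kept.  When surface-normalised coordinates are
#' supplied the same metrics are also computed in relative units.
#'
#' @param gaze gaze data.frame after [index_movements()].
#' @param surface_gaze optional enrichment stream; when given, each movement
#'   sample is matched to its nearest surface sample and relative-coordinate
#'   metrics (`path_length_rel`, `displacement_rel`) are added.
#' @return data.frame `id`, `n_samples`, `start_ts`, `end_ts`,
#'   `duration_ms`, `path_length`, `displacement` (+ `_rel` variants).
#' @export
extract_movements <- function(gaze, surface_gaze = NULL) {
  if (is.null(gaze$movement_id)) {
    gp_stop("movements", "gaze stream is not movement-indexed; run index_movements()")
  }
  ids <- sort(unique(gaze$movement_id[!is.na(gaze$movement_id)]))
  out <- data.frame(
    id = ids, n_samples = rep(NA_integer_, length(ids)),
    start_ts = rep(NA_real_, length(ids)), end_ts = rep(NA_real_, length(ids)),
    duration_ms = rep(NA_real_, length(ids)),
    path_length = rep(NA_real_, length(ids)),
    displacement = rep(NA_real_, length(ids)),
    path_length_rel = rep(NA_real_, length(ids)),
    displacement_rel = rep(NA_real_, length(ids))
  )
  if (length(ids) == 0L) return(out)
  has_rel <- !is.null(surface_gaze) && nrow(surface_gaze) > 0L
  for (i in seq_along(ids)) {
    run <- gaze[which(gaze$movement_id %in% ids[i]), , drop = FALSE]
    out$n_samples[i] <- nrow(run)
    out$start_ts[i] <- run$ts[1]
    out$end_ts[i] <- run$ts[nrow(run)]
    out$duration_ms[i] <- ns_to_ms(out$end_ts[i] - out$start_ts[i])
    out$path_length[i] <- path_length(run$x, run$y)
    out$displacement[i] <- euclidean_distance(
      c(run$x[1], run$y[1]), c(run$x[nrow(run)], run$y[nrow(run)]))
    if (has_rel) {
      j <- nearest_index(run$ts, surface_gaze$ts)
      sx <- surface_gaze$sx[j]
      sy <- surface_gaze$sy[j]
      ok <- !is.na(sx) & !is.na(sy)
      if (sum(ok) >= 1L) {
        out$path_length_rel[i] <- path_length(sx[ok], sy[ok])
        out$displacement_rel[i] <- euclidean_distance(
          c(sx[ok][1], sy[ok][1]), c(sx[ok][sum(ok)], sy[ok][sum(ok)]))
      }
    }
  }
  out
}

path_length <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Group gaze samples by fixation or by movement
#'
#' @param gaze gaze data.frame ([index_movements()] must have run for
#'   `by = "movement"`).
#' @param by `"fixation"` or `"movement"`.
#' @return named list mapping id to the ordered sample rows of that group;
#'   every sample appears in at most one group.
#' @export
collect_gaze_groups <- function(gaze, by = c("fixation", "movement")) {
  by <- match.arg(by)
  col <- if (by == "fixation") "fixation_id" else "movement_id"
  if (is.null(gaze[[col]])) {
    if (by == "movement") {
      gp_stop("movements", "gaze stream is not movement-indexed")
    }
    return(list())
  }
  ids <- gaze[[col]]
  keep <- !is.na(ids)
  if (!any(keep)) return(list())
  split(gaze[keep, , drop = FALSE], ids[keep])
}
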