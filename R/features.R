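# Per-epoch feature battery.
#
# Five categories — blink, fixations, gaze, saccade, pupillometry — each
# reduced to a tidy set of indices with units.  Empty categories yield
# explicit NA markers rather than zeros (counts excepted: an epoch really
# can have 0 blinks), so "no saccades" is distinguishable from "saccades of
# zero amplitude".

feat <- function(index, value, unit) {
  data.frame(index = index,
             value = if (is.null(value) || length(value) == 0L) NA_real_
                     else as.numeric(value),
             unit = unit, stringsAsFactors = FALSE)
}

stat_rows <- function(prefix, values, unit, which = c("total", "average",
                                                      "max", "min")) {
  if (length(values) == 0L) {
    # totals are additive across epochs, so an empty category contributes 0;
    # averages and extrema of nothing stay empty-marked
    return(do.call(rbind, lapply(which, function(w)
      feat(paste0(prefix, "_", w),
           if (w == "total") 0 else NA_real_, unit))))
  }
  s <- descriptive_stats(values)
  map <- c(total = "total", average = "mean", max = "maximum",
           min = "minimum")
  do.call(rbind, lapply(which, function(w)
    feat(paste0(prefix, "_", w), s[[map[[w]]]], unit)))
}

#' Blink indices of one epoch slice
#'
#' Count, total duration, average duration, and "surface duration" — the
#' total duration of blinks flagged on the ROI.  All durations in ms; an
#' epoch with no blinks reports zeros.
#'
#' @param slice an annotated [gaze_recording] (typically an epoch slice).
#' @return data.frame `index`, `value`, `unit`.
#' @export
blink_features <- function(slice) {
  b <- slice$blinks
  on <- if (is.null(b$on_roi)) rep(FALSE, nrow(b)) else b$on_roi %in% TRUE
  rbind(
    feat("count", nrow(b), "count"),
    feat("duration_total", sum(b$duration_ms), "ms"),
    feat("duration_average",
         if (nrow(b)) mean(b$duration_ms) else 0, "ms"),
    feat("duration_surface", sum(b$duration_ms[on]), "ms")
  )
}

#' Fixation indices of one epoch slice
#'
#' Count; duration total/average/max/min; the position of the
#' longest-duration fixation and the (unweighted) mean position; and the
#' consecutive-centroid distance list in absolute (scene px) and relative
#' (surface-normalised) coordinates with total and average.  With fewer
#' than two fixations the distance indices are empty-marked.
#'
#' @param slice a [gaze_recording] slice; relative distances use the
#'   `surface_fixations` enrichment stream (nearest sample to each fixation
#'   midpoint).
#' @return data.frame `index`, `value`, `unit`.
#' @export
fixation_features <- function(slice) {
  f <- slice$fixations
  n <- nrow(f)
  out <- rbind(
    feat("count", n, "count"),
    stat_rows("duration", f$duration_ms, "ms")
  )
  if (n > 0L) {
    longest <- which.max(f$duration_ms)
    out <- rbind(out,
      feat("position_max_duration_x", f$x[longest], "px"),
      feat("position_max_duration_y", f$y[longest], "px"),
      feat("position_average_x", mean(f$x), "px"),
      feat("position_average_y", mean(f$y), "px"))
  } else {
    out <- rbind(out,
      feat("position_max_duration_x", NA_real_, "px"),
      feat("position_max_duration_y", NA_real_, "px"),
      feat("position_average_x", NA_real_, "px"),
      feat("position_average_y", NA_real_, "px"))
  }
  dist_abs <- if (n >= 2L) sqrt(diff(f$x)^2 + diff(f$y)^2) else numeric()
  out <- rbind(out,
    stat_rows("distance_absolute", dist_abs, "px", c("total", "average")))
  dist_rel <- numeric()
  sf <- slice$surface_fixations
  if (n >= 2L && !is.null(sf) && nrow(sf) > 0L &&
      any(!is.na(sf$sx))) {
    mid <- (f$start_ts + f$end_ts) / 2
    j <- nearest_index(mid, sf$ts)
    sx <- sf$sx[j]
    sy <- sf$sy[j]
    if (all(!is.na(sx) & !is.na(sy))) {
      dist_rel <- sqrt(diff(sx)^2 + diff(sy)^2)
    }
  }
  rbind(out,
    stat_rows("distance_relative", dist_rel, "norm", c("total", "average")))
}

#' Gaze indices of one epoch slice
#'
#' Total sample count; mean samples per fixation and per movement; movement
#' duration total/average; and movement distance (path length) statistics
#' in absolute and relative coordinates.  Epochs without movements
#' empty-mark the movement indices.
#'
#' @param slice a [gaze_recording] slice whose gaze stream has been through
#'   [index_movements()].
#' @return data.frame `index`, `value`, `unit`.
#' @export
gaze_features <- function(slice) {
  g <- slice$gaze
  fix_groups <- collect_gaze_groups(g, by = "fixation")
  has_mov <- !is.null(g$movement_id)
  mov_groups <- if (has_mov) collect_gaze_groups(g, by = "movement") else list()
  movements <- if (has_mov) {
    extract_movements(g, slice$surface_gaze)
  } else {
    extract_movements(index_movements(g), slice$surface_gaze)
  }
  out <- rbind(
    feat("count_total", nrow(g), "count"),
    feat("count_per_fixation",
         if (length(fix_groups)) mean(vapply(fix_groups, nrow, 0L)) else NA_real_,
         "count"),
    feat("count_per_movement",
         if (nrow(movements)) mean(movements$n_samples) else NA_real_,
         "count"),
    stat_rows("movement_duration", movements$duration_ms, "ms",
              c("total", "average")),
    stat_rows("movement_distance_absolute", movements$path_length, "px"),
    stat_rows("movement_distance_relative",
              movements$path_length_rel[!is.na(movements$path_length_rel)],
              "norm")
  )
  out
}

#' Saccade indices of one epoch slice
#'
#' Count; duration total/average/max/min (ms); amplitude average/max/min
#' (px); mean-velocity average/max/min (px/s); and the overall peak
#' velocity, the maximum of per-saccade peaks.
#'
#' @param slice a [gaze_recording] slice.
#' @return data.frame `index`, `value`, `unit`.
#' @export
saccade_features <- function(slice) {
  s <- slice$saccades
  rbind(
    feat("count", nrow(s), "count"),
    stat_rows("duration", s$duration_ms, "ms"),
    stat_rows("amplitude", s$amplitude_px, "px",
              c("average", "max", "min")),
    stat_rows("mean_velocity", s$mean_velocity, "px/s",
              c("average", "max", "min")),
    feat("peak_velocity",
         if (nrow(s)) max(s$peak_velocity) else NA_real_, "px/s")
  )
}

#' Pupillometry indices of one epoch slice
#'
#' First and last diameter, max/min, and average (mm); optionally
#' restricted to the samples flagged on the ROI.
#'
#' @param slice a [gaze_recording] slice with resolved pupil diameters.
#' @param roi_only restrict to on-ROI samples (requires annotation).
#' @return data.frame `index`, `value`, `unit`.
#' @export
pupil_features <- function(slice, roi_only = FALSE) {
  p <- slice$pupil
  d <- p$diameter
  if (roi_only) {
    if (is.null(p$on_roi)) gp_stop("features", "pupil stream not ROI-annotated")
    d <- d[p$on_roi %in% TRUE]
  }
  d <- d[!is.na(d)]
  if (length(d) == 0L) {
    return(rbind(
      feat("diameter_first", NA_real_, "mm"),
      feat("diameter_last", NA_real_, "mm"),
      stat_rows("diameter", numeric(), "mm", c("max", "min", "average")),
      feat("count", 0L, "count")))
  }
  rbind(
    feat("diameter_first", d[1], "mm"),
    feat("diameter_last", d[length(d)], "mm"),
    stat_rows("diameter", d, "mm", c("max", "min", "average")),
    feat("count", length(d), "count")
  )
}

feature_categories <- function() {
  c("blink", "fixations", "gaze", "saccade", "pupillometry")
}

#' Extract the full per-epoch feature report
#'
#' Slices the recording by each epoch and runs all five category extractors,
#' filling the complete epoch-by-category grid; a category that is empty in
#' an epoch contributes NA-marked indices, never aborts the grid.  Each row
#' also carries the epoch's name, bounds and duration.
#'
#' @param rec an annotated, movement-indexed [gaze_recording].
#' @param epochs data.frame from [build_epochs()].
#' @param participant participant code stored on the report (defaults to the
#'   recording's).
#' @param pupil_roi_only restrict pupillometry indices to on-ROI samples.
#' @return a `feature_report`: tidy data.frame with columns `participant`,
#'   `epoch`, `epoch_name`, `epoch_start_ts`, `epoch_end_ts`,
#'   `epoch_duration_ms`, `category`, `index`, `value`, `unit`.
#' @export
extract_report <- function(rec, epochs, participant = rec$participant,
                           pupil_roi_only = FALSE) {
  stopifnot(inherits(rec, "gaze_recording"), nrow(epochs) >= 1L)
  if (is.null(rec$gaze$movement_id)) rec$gaze <- index_movements(rec$gaze)
  blocks <- vector("list", nrow(epochs) * 5L)
  k <- 0L
  for (i in seq_len(nrow(epochs))) {
    slice <- slice_recording(rec, epochs[i, ])
    cats <- list(
      blink = blink_features(slice),
      fixations = fixation_features(slice),
      gaze = gaze_features(slice),
      saccade = saccade_features(slice),
      pupillometry = pupil_features(slice, roi_only = pupil_roi_only)
    )
    for (cat in names(cats)) {
      blk <- cats[[cat]]
      blk <- cbind(
        data.frame(participant = participant, epoch = i,
                   epoch_name = epochs$name[i],
                   epoch_start_ts = epochs$start_ts[i],
                   epoch_end_ts = epochs$end_ts[i],
                   epoch_duration_ms = ns_to_ms(epochs$end_ts[i] -
                                                epochs$start_ts[i]),
                   category = cat, stringsAsFactors = FALSE),
        blk)
      k <- k + 1L
      blocks[[k]] <- blk
    }
  }
  report <- do.call(rbind, blocks)
  rownames(report) <- NULL
  class(report) <- c("feature_report", "data.frame")
  report
}

#' @export
print.feature_report <- function(x, ...) {
  cat(sprintf("<feature_report> participant '%s': %d epochs, %d rows\n",
              x$participant[1], length(unique(x$epoch)), nrow(x)))
  invisible(x)
}

#' Look up one index value in a feature report
#'
#' @param report a `feature_report`.
#' @param category,index row selector.
#' @return numeric vector, one value per epoch (epoch order).
#' @export
report_value <- function(report, category, index) {
  rows <- report[report$category == category & report$index == index, ,
                 drop = FALSE]
  rows <- rows[order(rows$epoch), , drop = FALSE]
  stats::setNames(rows$value, rows$epoch_name)
}

#' Exclude epochs by blink count
#'
#' Data-quality filter: epochs whose blink count strictly exceeds the
#' threshold are removed from the report (blinks during short trials at
#' these rates indicate acquisition errors).  The default threshold of 5
#' encodes the "more than five blinks" exclusion rule.
#'
#' @param report a `feature_report`.
#' @param threshold maximum admissible blink count (strict inequality
#'   above it excludes; default 5).
#' @return list with `report` (filtered, same class) and `exclusions`
#'   (data.frame `epoch`, `epoch_name`, `blink_count`).
#' @export
filter_epochs_by_blinks <- function(report, threshold = 5) {
  counts <- report[report$category == "blink" & report$index == "count", ,
                   drop = FALSE]
  drop <- counts$epoch[counts$value > threshold]
  exclusions <- data.frame(
    epoch = counts$epoch[counts$epoch %in% drop],
    epoch_name = counts$epoch_name[counts$epoch %in% drop],
    blink_count = counts$value[counts$epoch %in% drop],
    stringsAsFactors = FALSE)
  kept <- report[!(report$epoch %in% drop), , drop = FALSE]
  class(kept) <- class(report)
  if (nrow(exclusions)) {
    gp_log("filter", sprintf("excluded %d epoch(s) with more than %g blinks",
                             nrow(exclusions), threshold))
  }
  list(report = kept, exclusions = exclusions)
}
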