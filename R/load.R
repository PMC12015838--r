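# Reading a recording folder in the cloud-export dialect.

#' Load a recording folder
#'
#' Reads the delimited-text export bundle of one session: gaze, fixations,
#' blinks, saccades, pupillometry (eye-state), events, plus the enrichment
#' streams carrying on-surface flags and surface-normalised coordinates.
#' Column headers are matched tolerantly (case, spacing and bracketed unit
#' suffixes are ignored); every stream is sorted by timestamp; units are
#' normalised to nanoseconds / milliseconds / millimetres.
#'
#' The enrichment streams are required in this version: region-of-interest
#' membership is consumed from the vendor's surface mapping, not recomputed.
#'
#' @param folder path to the export folder.
#' @param participant participant code attached to the recording.
#' @return a [gaze_recording].
#' @seealso [validate_recording()], [annotate_recording()]
#' @export
load_recording <- function(folder, participant = "anonymous") {
  if (!dir.exists(folder)) gp_stop("load", sprintf("no such folder: %s", folder))
  dialect <- gp_dialect()

  required <- c("gaze", "fixations", "blinks", "saccades", "pupil", "events")
  paths <- lapply(c(required, "surface_gaze", "surface_fixations"),
                  function(s) find_stream_file(folder, s))
  names(paths) <- c(required, "surface_gaze", "surface_fixations")
  for (s in required) {
    if (is.null(paths[[s]])) {
      gp_stop("load", sprintf(
        "required table '%s' not found in %s (looked for: %s)",
        s, folder, paste(gp_filenames()[[s]], collapse = ", ")))
    }
  }
  if (is.null(paths$surface_gaze)) {
    gp_stop("load", paste0(
      "enrichment table not found in ", folder, "; this version requires a ",
      "surface-mapping enrichment (on-surface flags) alongside the raw ",
      "streams (looked for: ",
      paste(gp_filenames()$surface_gaze, collapse = ", "), ")"))
  }

  gaze <- read_stream_csv(paths$gaze, dialect$gaze, "gaze")
  fixations <- read_stream_csv(paths$fixations, dialect$fixations, "fixations")
  blinks <- read_stream_csv(paths$blinks, dialect$blinks, "blinks")
  saccades <- read_stream_csv(paths$saccades, dialect$saccades, "saccades")
  pupil <- read_stream_csv(paths$pupil, dialect$pupil, "pupil")
  events <- read_stream_csv(paths$events, dialect$events, "events")
  surface_gaze <- read_stream_csv(paths$surface_gaze, dialect$surface,
                                  "surface gaze")
  surface_fixations <- if (!is.null(paths$surface_fixations)) {
    read_stream_csv(paths$surface_fixations, dialect$surface,
                    "surface fixations")
  } else {
    data.frame(ts = numeric(), on_surface = logical(), sx = numeric(),
               sy = numeric())
  }

  pupil$diameter <- resolve_pupil_diameter(pupil)
  gp_log("load", sprintf(
    "loaded %s: %d gaze, %d fixations, %d blinks, %d saccades, %d pupil, %d events",
    folder, nrow(gaze), nrow(fixations), nrow(blinks), nrow(saccades),
    nrow(pupil), nrow(events)))

  gaze_recording(gaze, fixations, blinks, saccades, pupil, events,
                 surface_gaze, surface_fixations, participant = participant)
}

#' Resolve the per-sample pupil diameter
#'
#' When both eyes are present the diameter is their mean; when one is
#' present, that one; an export that already carries a single diameter
#' column is passed through.
#'
#' @param pupil data.frame with `diameter_left`, `diameter_right` and
#'   optionally `diameter` columns (mm).
#' @return numeric vector of resolved diameters (mm).
#' @export
resolve_pupil_diameter <- function(pupil) {
  d <- pupil$diameter
  if (is.null(d)) d <- rep(NA_real_, nrow(pupil))
  l <- pupil$diameter_left
  r <- pupil$diameter_right
  if (is.null(l)) l <- rep(NA_real_, nrow(pupil))
  if (is.null(r)) r <- rep(NA_real_, nrow(pupil))
  need <- is.na(d)
  both <- need & !is.na(l) & !is.na(r)
  d[both] <- (l[both] + r[both]) / 2
  left_only <- need & !is.na(l) & is.na(r)
  d[left_only] <- l[left_only]
  right_only <- need & is.na(l) & !is.na(r)
  d[right_only] <- r[right_only]
  d
}

#' Load an external event file
#'
#' Delimited text with at least a name and a timestamp (ns) column, in the
#' same tolerant dialect as the cloud export.  Rows are returned sorted by
#' timestamp; ties keep file order (stable sort).
#'
#' @param path CSV file path.
#' @return data.frame `name`, `ts` sorted by `ts`.
#' @export
load_event_file <- function(path) {
  if (!file.exists(path)) gp_stop("events", sprintf("no such file: %s", path))
  ev <- read_stream_csv(path, gp_dialect()$events, "events")
  if (!nrow(ev)) gp_stop("events", sprintf("event file '%s' has no rows", path))
  if (any(!nzchar(ev$name))) gp_stop("events", "event names must be non-empty")
  ev <- ev[order_by_ts(ev$ts), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
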