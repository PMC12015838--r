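# End-to-end processing: the library call behind the command-line surface.
# The CLI adds no computation; everything here is reachable as plain
# function calls and produces identical outputs.

default_plot_set <- function() {
  c("pupil_roi", "blinks", "saccade_velocity", "saccade_amplitude",
    "fixation_cloud", "fixation_path", "fixation_histogram", "periodogram",
    "spectrogram")
}

build_figures <- function(rec, plots) {
  figures <- list()
  want <- function(nm) nm %in% plots
  sp <- recording_span(rec)
  if (want("pupil_roi") && nrow(rec$pupil)) {
    figures$pupil_roi <- prepare_pupil_roi_series(rec$pupil)
  }
  if (want("blinks")) {
    figures$blinks <- prepare_blink_series(rec$blinks, sp)
  }
  if (want("saccade_velocity") && nrow(rec$saccades)) {
    figures$saccade_velocity <- prepare_saccade_series(rec$saccades,
                                                       "velocity")
  }
  if (want("saccade_amplitude") && nrow(rec$saccades)) {
    figures$saccade_amplitude <- prepare_saccade_series(rec$saccades,
                                                        "amplitude")
  }
  if (want("fixation_cloud") && nrow(rec$fixations) >= 2L) {
    figures$fixation_cloud <- prepare_fixation_cloud(rec$fixations$x,
                                                     rec$fixations$y)
  }
  if (want("fixation_path") && nrow(rec$fixations) >= 2L) {
    figures$fixation_path <- prepare_path(rec$fixations$x,
                                          rec$fixations$y, "absolute")
  }
  if (want("fixation_histogram") && nrow(rec$fixations)) {
    figures$fixation_histogram <- prepare_histogram(
      rec$fixations$duration_ms, unit = "ms")
  }
  if ((want("periodogram") || want("spectrogram")) && nrow(rec$pupil) >= 2L) {
    rs <- resample_uniform(rec$pupil$ts, rec$pupil$diameter)
    seg <- min(256L, 2^floor(log2(length(rs$value))))
    if (seg >= 8L) {
      if (want("periodogram")) {
        figures$periodogram <- prepare_spectrum(
          welch_periodogram(rs, segment_length = seg))
      }
      if (want("spectrogram")) {
        figures$spectrogram <- prepare_spectrum(
          spectrogram(rs, segment_length = seg))
      }
    }
  }
  figures
}

#' Run the full processing pipeline on a recording folder
#'
#' load -> (optional) replace events -> ROI annotation -> movement indexing
#' -> per-epoch feature extraction -> blink-count exclusion -> figure
#' preparation -> output writing.  Every stage logs its counts (with
#' `options(gazeproc.verbose = TRUE)`).
#'
#' @param folder recording export folder.
#' @param participant participant name or code; prefixes all output files.
#' @param out_dir output directory (default `<folder>/output`).
#' @param events_file optional CSV replacing the recording's events.
#' @param blink_threshold blink-count exclusion threshold (strictly more
#'   excludes; default 5).
#' @param plots character vector of figure names (subset of
#'   `default_plot_set()`), `"all"` or `"none"`.
#' @param pupil_roi_only restrict pupillometry indices to on-ROI samples.
#' @return list `report` (full), `filtered` (report + exclusions),
#'   `manifest` (files written), `validation` (issues found), invisibly.
#' @export
run_process <- function(folder, participant = "anonymous",
                        out_dir = file.path(folder, "output"),
                        events_file = NULL, blink_threshold = 5,
                        plots = "all", pupil_roi_only = FALSE) {
  rec <- load_recording(folder, participant = participant)
  issues <- validate_recording(rec)
  if (nrow(issues)) {
    gp_warn("validate", sprintf("%d issue(s) found; see the validation element",
                                nrow(issues)))
  }
  if (!is.null(events_file)) {
    rec <- replace_events(rec, load_event_file(events_file))
  }
  if (nrow(rec$events) < 2L) {
    gp_stop("epochs", "the events stream needs at least start and end events")
  }
  rec <- annotate_recording(rec)
  rec$gaze <- index_movements(rec$gaze)
  epochs <- build_epochs(rec$events)
  report <- extract_report(rec, epochs, participant = participant,
                           pupil_roi_only = pupil_roi_only)
  filtered <- filter_epochs_by_blinks(report, threshold = blink_threshold)

  plots <- if (identical(plots, "all")) default_plot_set()
           else if (identical(plots, "none")) character() else plots
  figures <- build_figures(rec, plots)
  manifest <- write_outputs(filtered$report, figures, out_dir,
                            participant = participant,
                            exclusions = filtered$exclusions)
  invisible(list(report = report, filtered = filtered, manifest = manifest,
                 validation = issues, epochs = epochs, recording = rec))
}
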