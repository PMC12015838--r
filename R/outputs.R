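# Writing the analysis outputs: one human-readable text report, one tidy
# delimited feature table, and the figure files, all prefixed by the
# participant code and written in deterministic order.

#' Write the feature report, table and figures
#'
#' @param report a `feature_report`.
#' @param figures named list of `prepared_plot` objects; each is rendered
#'   to `<prefix>_<name>.png` in alphabetical order.
#' @param out_dir output directory (created if missing).
#' @param participant participant code; sanitised for filenames, preserved
#'   verbatim inside the report text.
#' @param exclusions optional exclusion log from
#'   [filter_epochs_by_blinks()], echoed into the text report.
#' @param stats_lines optional character vector of statistical results to
#'   append to the text report.
#' @return data.frame manifest (`file`, `type`) of everything written.
#' @export
write_outputs <- function(report, figures = list(), out_dir,
                          participant = report$participant[1],
                          exclusions = NULL, stats_lines = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) gp_stop("write", sprintf("cannot create directory %s", out_dir))
  }
  if (file.access(out_dir, 2) != 0) {
    gp_stop("write", sprintf("directory %s is not writable", out_dir))
  }
  prefix <- sanitize_participant(participant)
  written <- list()

  table_path <- file.path(out_dir, paste0(prefix, "_features.csv"))
  tab <- as.data.frame(report)
  tab <- tab[order(tab$epoch, tab$category, tab$index), , drop = FALSE]
  utils::write.csv(tab, table_path, row.names = FALSE, quote = FALSE)
  written[[length(written) + 1L]] <- c(table_path, "feature_table")

  report_path <- file.path(out_dir, paste0(prefix, "_report.txt"))
  writeLines(format_text_report(report, participant, exclusions,
                                stats_lines), report_path)
  written[[length(written) + 1L]] <- c(report_path, "text_report")

  for (nm in sort(names(figures))) {
    fig_path <- file.path(out_dir, paste0(prefix, "_", nm, ".png"))
    render_figure(figures[[nm]], fig_path)
    written[[length(written) + 1L]] <- c(fig_path, "figure")
  }
  manifest <- data.frame(
    file = vapply(written, `[`, "", 1L),
    type = vapply(written, `[`, "", 2L),
    stringsAsFactors = FALSE)
  gp_log("write", sprintf("wrote %d file(s) to %s", nrow(manifest), out_dir))
  manifest
}

format_text_report <- function(report, participant, exclusions = NULL,
                               stats_lines = NULL) {
  lines <- c(
    sprintf("Eye-tracking feature report — participant: %s", participant),
    sprintf("Epochs analysed: %d", length(unique(report$epoch))),
    ""
  )
  for (ep in sort(unique(report$epoch))) {
    rows <- report[report$epoch == ep, , drop = FALSE]
    lines <- c(lines, sprintf(
      "== Epoch %d '%s' [%.3f s, duration %.1f ms] ==",
      ep, rows$epoch_name[1], rows$epoch_start_ts[1] / NS_PER_S,
      rows$epoch_duration_ms[1]))
    for (cat in unique(rows$category)) {
      crows <- rows[rows$category == cat, , drop = FALSE]
      lines <- c(lines, sprintf("  [%s]", cat))
      lines <- c(lines, sprintf(
        "    %-28s %s %s", crows$index,
        ifelse(is.na(crows$value), "(empty)",
               formatC(crows$value, digits = 6, format = "g")),
        ifelse(is.na(crows$value), "", crows$unit)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(exclusions) && nrow(exclusions)) {
    lines <- c(lines, "== Excluded epochs (blink-count filter) ==",
               sprintf("  epoch %d '%s': %g blinks", exclusions$epoch,
                       exclusions$epoch_name, exclusions$blink_count), "")
  }
  if (!is.null(stats_lines)) {
    lines <- c(lines, "== Statistics ==", paste0("  ", stats_lines), "")
  }
  lines
}
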