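# Tolerant column dialect for Pupil Cloud Neon style exports.
#
# The cloud export dialect varies across versions: header case, surrounding
# whitespace and bracketed unit suffixes ("start timestamp [ns]") are all
# unstable.  Every file is therefore read through a normalising layer that
# lowercases headers, strips bracketed annotations and collapses whitespace
# before matching against a per-stream alias table.  Canonical file and
# column names are documented in the README.

#' Normalise a column header for tolerant matching
#'
#' Lowercases, removes bracketed unit annotations such as `[ns]` or `[px]`,
#' and collapses runs of whitespace/underscores to single spaces.
#'
#' @param x character vector of raw headers.
#' @return normalised headers.
#' @examples
#' normalize_header(c("Start Timestamp [ns]", "gaze_x [px]"))
#' @export
normalize_header <- function(x) {
  x <- tolower(x)
  x <- gsub("\\[[^]]*\\]", " ", x)   # drop bracketed units
  x <- gsub("[_[:space:]]+", " ", x)
  trimws(x)
}

# column spec: internal name -> list(aliases, type, required)
gp_col <- function(aliases, type, required = TRUE) {
  list(aliases = aliases, type = type, required = required)
}

# Per-stream column dialects.  Aliases are in normalised form.
gp_dialect <- function() {
  list(
    gaze = list(
      ts = gp_col(c("timestamp", "timestamp ns"), "ns"),
      x = gp_col(c("gaze x", "gaze x px", "x"), "num"),
      y = gp_col(c("gaze y", "gaze y px", "y"), "num"),
      worn = gp_col("worn", "bool", required = FALSE),
      fixation_id = gp_col("fixation id", "int", required = FALSE),
      blink_id = gp_col("blink id", "int", required = FALSE)
    ),
    fixations = list(
      id = gp_col("fixation id", "int"),
      start_ts = gp_col(c("start timestamp", "start timestamp ns"), "ns"),
      end_ts = gp_col(c("end timestamp", "end timestamp ns"), "ns"),
      duration_ms = gp_col(c("duration", "duration ms"), "num"),
      x = gp_col(c("fixation x", "fixation x px", "x"), "num"),
      y = gp_col(c("fixation y", "fixation y px", "y"), "num")
    ),
    blinks = list(
      id = gp_col("blink id", "int"),
      start_ts = gp_col(c("start timestamp", "start timestamp ns"), "ns"),
      end_ts = gp_col(c("end timestamp", "end timestamp ns"), "ns"),
      duration_ms = gp_col(c("duration", "duration ms"), "num")
    ),
    saccades = list(
      id = gp_col("saccade id", "int"),
      start_ts = gp_col(c("start timestamp", "start timestamp ns"), "ns"),
      end_ts = gp_col(c("end timestamp", "end timestamp ns"), "ns"),
      duration_ms = gp_col(c("duration", "duration ms"), "num"),
      amplitude_px = gp_col(c("amplitude", "amplitude px"), "num"),
      mean_velocity = gp_col(c("mean velocity", "mean velocity px/s"), "num"),
      peak_velocity = gp_col(c("peak velocity", "peak velocity px/s"), "num")
    ),
    pupil = list(
      ts = gp_col(c("timestamp", "timestamp ns"), "ns"),
      diameter_left = gp_col(c("pupil diameter left", "diameter left"),
                             "num", required = FALSE),
      diameter_right = gp_col(c("pupil diameter right", "diameter right"),
                              "num", required = FALSE),
      diameter = gp_col(c("pupil diameter", "diameter"), "num",
                        required = FALSE)
    ),
    events = list(
      name = gp_col(c("name", "event", "event name"), "chr"),
      ts = gp_col(c("timestamp", "timestamp ns"), "ns")
    ),
    surface = list(
      ts = gp_col(c("timestamp", "timestamp ns"), "ns"),
      on_surface = gp_col(c("gaze detected on surface",
                            "fixation detected on surface",
                            "detected on surface", "on surface"), "bool"),
      sx = gp_col(c("gaze position on surface x",
                    "fixation x normalized", "surface x", "x norm"), "num",
                  required = FALSE),
      sy = gp_col(c("gaze position on surface y",
                    "fixation y normalized", "surface y", "y norm"), "num",
                  required = FALSE)
    )
  )
}

# Canonical filenames per stream, first entry is what the generator writes.
gp_filenames <- function() {
  list(
    gaze = c("gaze.csv"),
    fixations = c("fixations.csv"),
    blinks = c("blinks.csv"),
    saccades = c("saccades.csv"),
    pupil = c("3d_eye_states.csv", "pupillometry.csv", "eye_states.csv"),
    events = c("events.csv"),
    surface_gaze = c("enrichment_gaze.csv", "gaze_on_surface.csv"),
    surface_fixations = c("enrichment_fixations.csv",
                          "fixations_on_surface.csv")
  )
}

coerce_bool <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  out
}

coerce_col <- function(x, type) {
  switch(type,
    ns = suppressWarnings(as.numeric(x)),
    num = suppressWarnings(as.numeric(x)),
    int = suppressWarnings(as.integer(as.numeric(x))),
    bool = coerce_bool(x),
    chr = as.character(x)
  )
}

#' Read one delimited stream through the tolerant dialect
#'
#' @param path CSV file path.
#' @param spec one entry of the per-stream dialect (internal name ->
#'   aliases/type/required).
#' @param stream stream label used in diagnostics.
#' @return data.frame with canonical internal columns; malformed rows
#'   (unparseable required fields) are dropped with one warning that counts
#'   them.
#' @noRd
read_stream_csv <- function(path, spec, stream) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  hdr <- normalize_header(names(raw))
  out <- list()
  for (col in names(spec)) {
    hit <- which(hdr %in% spec[[col]]$aliases)
    if (length(hit) == 0L) {
      if (spec[[col]]$required) {
        gp_stop("load", sprintf(
          "file '%s' (%s stream) is missing required column '%s'",
          basename(path), stream, spec[[col]]$aliases[1]))
      }
      out[[col]] <- coerce_col(rep(NA_character_, nrow(raw)), spec[[col]]$type)
    } else {
      out[[col]] <- coerce_col(raw[[hit[1]]], spec[[col]]$type)
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  # warn-and-skip malformed rows: required fields must parse
  req <- names(spec)[vapply(spec, function(s) s$required, logical(1))]
  req_num <- req[vapply(spec[req], function(s) s$type != "chr", logical(1))]
  if (length(req_num) && nrow(df)) {
    bad <- Reduce(`|`, lapply(df[req_num], is.na))
    if (any(bad)) {
      gp_warn("load", sprintf("%d malformed row(s) skipped in '%s'",
                              sum(bad), basename(path)))
      df <- df[!bad, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  df
}

find_stream_file <- function(folder, stream) {
  for (fn in gp_filenames()[[stream]]) {
    p <- file.path(folder, fn)
    if (file.exists(p)) return(p)
  }
  NULL
}
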