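# Synthetic recording generator.
#
# Emits complete recording folders in the cloud-export dialect with fully
# known ground truth, so every pipeline stage can be tested without
# hardware.  The simulation is statistical scaffolding, not oculomotor
# science: fixation durations are lognormal, inter-fixation gaps carry one
# saccade each with a monotone amplitude-velocity link, blinks arrive as a
# Poisson process at a physiological rate, and the pupil series is a
# baseline plus drift, optional oscillation, and Gaussian noise.  Gaze and
# pupil samples inside blinks are omitted from the files, mirroring device
# behaviour during lid closure.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: 200 Hz
#' nominal sampling, ~300 ms lognormal fixations, 18 blinks/min (the
#' physiological 15-20/min band), ~150 ms blinks, a 3.5 mm pupil baseline.
#'
#' @param duration_s recording length in seconds.
#' @param gaze_rate gaze/pupil sampling rate (Hz).
#' @param fixation_mean_ms,fixation_sd_ms lognormal fixation-duration
#'   moments (ms).
#' @param movement_mean_ms,movement_sd_ms lognormal inter-fixation gap
#'   moments (ms); each gap carries one saccade.
#' @param blink_rate_per_min Poisson blink rate.
#' @param blink_mean_ms,blink_sd_ms lognormal blink-duration moments (ms).
#' @param pupil_baseline_mm,pupil_drift_mm_per_min,pupil_noise_sd_mm pupil
#'   model: baseline + linear drift + N(0, sd) noise.
#' @param pupil_osc_freq_hz,pupil_osc_amp_mm optional planted sinusoidal
#'   pupil oscillation (0 = none), used by the spectral checks.
#' @param anisocoria_sd_mm half-difference between left and right pupil
#'   (left = d + e, right = d - e) so diameter resolution is exercised.
#' @param scene_w,scene_h scene-camera frame in pixels.
#' @param fixation_step_sd_px spread of consecutive fixation centroids.
#' @param gaze_jitter_px within-fixation gaze scatter.
#' @param peak_velocity_factor peak/mean saccade velocity ratio (> 1).
#' @param roi_schedule data.frame `start_s`, `end_s`, `on` (logical);
#'   default: the whole recording on the ROI.
#' @param events data.frame `name`, `t_s`; default start/end only.
#' @param seed integer seed; the folder is reproducible from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(duration_s = 60,
                              gaze_rate = 200,
                              fixation_mean_ms = 300,
                              fixation_sd_ms = 150,
                              movement_mean_ms = 50,
                              movement_sd_ms = 15,
                              blink_rate_per_min = 18,
                              blink_mean_ms = 150,
                              blink_sd_ms = 40,
                              pupil_baseline_mm = 3.5,
                              pupil_drift_mm_per_min = 0.05,
                              pupil_noise_sd_mm = 0.05,
                              pupil_osc_freq_hz = 0,
                              pupil_osc_amp_mm = 0,
                              anisocoria_sd_mm = 0.05,
                              scene_w = 1600, scene_h = 1200,
                              fixation_step_sd_px = 200,
                              gaze_jitter_px = 3,
                              peak_velocity_factor = 1.6,
                              roi_schedule = NULL,
                              events = NULL,
                              seed = 1L) {
  if (is.null(roi_schedule)) {
    roi_schedule <- data.frame(start_s = 0, end_s = duration_s, on = TRUE)
  }
  if (is.null(events)) {
    events <- data.frame(name = c("start", "end"), t_s = c(0, duration_s),
                         stringsAsFactors = FALSE)
  }
  cfg <- list(
    duration_s = duration_s, gaze_rate = gaze_rate,
    fixation_mean_ms = fixation_mean_ms, fixation_sd_ms = fixation_sd_ms,
    movement_mean_ms = movement_mean_ms, movement_sd_ms = movement_sd_ms,
    blink_rate_per_min = blink_rate_per_min, blink_mean_ms = blink_mean_ms,
    blink_sd_ms = blink_sd_ms, pupil_baseline_mm = pupil_baseline_mm,
    pupil_drift_mm_per_min = pupil_drift_mm_per_min,
    pupil_noise_sd_mm = pupil_noise_sd_mm,
    pupil_osc_freq_hz = pupil_osc_freq_hz,
    pupil_osc_amp_mm = pupil_osc_amp_mm,
    anisocoria_sd_mm = anisocoria_sd_mm,
    scene_w = scene_w, scene_h = scene_h,
    fixation_step_sd_px = fixation_step_sd_px,
    gaze_jitter_px = gaze_jitter_px,
    peak_velocity_factor = peak_velocity_factor,
    roi_schedule = roi_schedule, events = events, seed = as.integer(seed)
  )
  stopifnot(duration_s > 0, gaze_rate > 0, fixation_mean_ms > 0,
            blink_rate_per_min >= 0, pupil_baseline_mm > 0,
            peak_velocity_factor > 1)
  if (any(roi_schedule$start_s < 0) || any(roi_schedule$end_s > duration_s) ||
      any(roi_schedule$end_s <= roi_schedule$start_s)) {
    gp_stop("simulate", "roi_schedule must hold ordered windows within the recording duration")
  }
  structure(cfg, class = "simulation_config")
}

# lognormal parameterised by its own mean/sd
rlnorm_ms <- function(n, mean_ms, sd_ms) {
  cv2 <- (sd_ms / mean_ms)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean_ms) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

roi_on_at <- function(t_s, schedule) {
  on <- rep(FALSE, length(t_s))
  for (i in seq_len(nrow(schedule))) {
    if (schedule$on[i]) {
      on <- on | (t_s >= schedule$start_s[i] & t_s < schedule$end_s[i])
    }
  }
  on
}

#' Generate a synthetic recording folder
#'
#' Writes all dialect files (gaze, fixations, blinks, saccades, eye-state
#' pupillometry, events, enrichment gaze + fixations) plus a ground-truth
#' manifest (`manifest.json`) to `folder`.  Byte-identical folders result
#' from identical configurations (same seed).
#'
#' @param config a [simulation_config()].
#' @param folder output directory (created).
#' @return invisibly, a list `folder`, `manifest` (the manifest is also
#'   written as JSON in the folder).
#' @export
generate_recording <- function(config, folder) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  dur_ns <- s_to_ns(config$duration_s)

  # --- fixation / movement alternation ---------------------------------
  fx_start <- numeric()
  fx_end <- numeric()
  fx_x <- numeric()
  fx_y <- numeric()
  t <- round(rlnorm_ms(1, config$movement_mean_ms, config$movement_sd_ms) *
             NS_PER_MS)  # lead-in before the first fixation
  x <- stats::runif(1, 0.25, 0.75) * config$scene_w
  y <- stats::runif(1, 0.25, 0.75) * config$scene_h
  while (TRUE) {
    d_fix <- round(rlnorm_ms(1, config$fixation_mean_ms,
                             config$fixation_sd_ms) * NS_PER_MS)
    if (t + d_fix > dur_ns) break
    fx_start <- c(fx_start, t)
    fx_end <- c(fx_end, t + d_fix)
    fx_x <- c(fx_x, x)
    fx_y <- c(fx_y, y)
    d_mov <- round(rlnorm_ms(1, config$movement_mean_ms,
                             config$movement_sd_ms) * NS_PER_MS)
    t <- t + d_fix + d_mov
    x <- min(max(x + stats::rnorm(1, 0, config$fixation_step_sd_px), 0),
             config$scene_w)
    y <- min(max(y + stats::rnorm(1, 0, config$fixation_step_sd_px), 0),
             config$scene_h)
  }
  n_fix <- length(fx_start)
  if (n_fix < 2L) {
    gp_stop("simulate", "duration too short to plant at least 2 fixations")
  }
  fixations <- data.frame(
    id = seq_len(n_fix), start_ts = fx_start, end_ts = fx_end,
    duration_ms = ns_to_ms(fx_end - fx_start), x = fx_x, y = fx_y)

  # --- one saccade per inter-fixation gap ------------------------------
  sc_start <- fx_end[-n_fix]
  sc_end <- fx_start[-1L]
  amp <- sqrt(diff(fx_x)^2 + diff(fx_y)^2)
  dur_s <- (sc_end - sc_start) / NS_PER_S
  mean_vel <- amp / dur_s
  saccades <- data.frame(
    id = seq_len(n_fix - 1L), start_ts = sc_start, end_ts = sc_end,
    duration_ms = ns_to_ms(sc_end - sc_start), amplitude_px = amp,
    mean_velocity = mean_vel,
    peak_velocity = mean_vel * config$peak_velocity_factor)

  # --- blinks: Poisson arrivals, non-overlapping -----------------------
  n_blink <- stats::rpois(1, config$blink_rate_per_min *
                             config$duration_s / 60)
  blinks <- data.frame(id = integer(), start_ts = numeric(),
                       end_ts = numeric(), duration_ms = numeric())
  if (n_blink > 0L) {
    bs <- sort(round(stats::runif(n_blink) * dur_ns))
    bd <- round(rlnorm_ms(n_blink, config$blink_mean_ms, config$blink_sd_ms) *
                NS_PER_MS)
    be <- pmin(bs + bd, dur_ns)
    keep <- rep(TRUE, n_blink)
    last_end <- -Inf
    for (i in seq_len(n_blink)) {   # drop arrivals that would overlap
      if (bs[i] < last_end) keep[i] <- FALSE else last_end <- be[i]
    }
    bs <- bs[keep]
    be <- be[keep]
    blinks <- data.frame(id = seq_along(bs), start_ts = bs, end_ts = be,
                         duration_ms = ns_to_ms(be - bs))
  }
  in_blink <- function(ts) {
    out <- rep(FALSE, length(ts))
    for (i in seq_len(nrow(blinks))) {
      out <- out | (ts >= blinks$start_ts[i] & ts < blinks$end_ts[i])
    }
    out
  }

  # --- gaze samples on the nominal grid --------------------------------
  ts <- seq(0, dur_ns, by = round(NS_PER_S / config$gaze_rate))
  fid <- rep(NA_integer_, length(ts))
  gx <- numeric(length(ts))
  gy <- numeric(length(ts))
  fi <- findInterval(ts, fx_start)
  for (i in seq_along(ts)) {
    k <- fi[i]
    if (k >= 1L && ts[i] < fx_end[k]) {        # inside fixation k
      fid[i] <- k
      gx[i] <- fx_x[k]
      gy[i] <- fx_y[k]
    } else if (k >= 1L && k < n_fix) {          # movement between k, k+1
      frac <- (ts[i] - fx_end[k]) / (fx_start[k + 1L] - fx_end[k])
      gx[i] <- fx_x[k] + frac * (fx_x[k + 1L] - fx_x[k])
      gy[i] <- fx_y[k] + frac * (fx_y[k + 1L] - fx_y[k])
    } else if (k < 1L) {                        # before the first fixation
      gx[i] <- fx_x[1]
      gy[i] <- fx_y[1]
    } else {                                    # after the last fixation
      gx[i] <- fx_x[n_fix]
      gy[i] <- fx_y[n_fix]
    }
  }
  gx <- gx + stats::rnorm(length(ts), 0, config$gaze_jitter_px)
  gy <- gy + stats::rnorm(length(ts), 0, config$gaze_jitter_px)
  closed <- in_blink(ts)
  gaze <- data.frame(ts = ts, x = gx, y = gy, worn = TRUE,
                     fixation_id = fid,
                     blink_id = NA_integer_)[!closed, , drop = FALSE]

  # --- pupil series (dropped during blinks, like gaze) -----------------
  t_s_all <- ts / NS_PER_S
  d <- config$pupil_baseline_mm +
    config$pupil_drift_mm_per_min * t_s_all / 60 +
    config$pupil_osc_amp_mm * sin(2 * pi * config$pupil_osc_freq_hz *
                                  t_s_all) +
    stats::rnorm(length(ts), 0, config$pupil_noise_sd_mm)
  e <- stats::rnorm(length(ts), 0, config$anisocoria_sd_mm)
  pupil <- data.frame(ts = ts, diameter_left = d + e, diameter_right = d - e,
                      diameter = NA_real_)[!closed, , drop = FALSE]

  # --- enrichment streams ----------------------------------------------
  on_gaze <- roi_on_at(gaze$ts / NS_PER_S, config$roi_schedule)
  surface_gaze <- data.frame(
    ts = gaze$ts, on_surface = on_gaze,
    sx = ifelse(on_gaze, pmin(pmax(gaze$x / config$scene_w, 0), 1), NA),
    sy = ifelse(on_gaze, pmin(pmax(gaze$y / config$scene_h, 0), 1), NA))
  fx_mid <- (fixations$start_ts + fixations$end_ts) / 2
  on_fix <- roi_on_at(fx_mid / NS_PER_S, config$roi_schedule)
  surface_fixations <- data.frame(
    ts = fx_mid, on_surface = on_fix,
    sx = ifelse(on_fix, pmin(pmax(fixations$x / config$scene_w, 0), 1), NA),
    sy = ifelse(on_fix, pmin(pmax(fixations$y / config$scene_h, 0), 1), NA))

  events <- data.frame(name = config$events$name,
                       ts = s_to_ns(config$events$t_s),
                       stringsAsFactors = FALSE)

  streams <- list(gaze = gaze, fixations = fixations, blinks = blinks,
                  saccades = saccades, pupil = pupil, events = events,
                  surface_gaze = surface_gaze,
                  surface_fixations = surface_fixations)
  manifest <- build_manifest(streams, config)
  write_recording_folder(streams, folder, manifest)
  invisible(list(folder = folder, manifest = manifest))
}

build_manifest <- function(streams, config = NULL) {
  epochs <- if (nrow(streams$events) >= 2L) build_epochs(streams$events) else
    NULL
  manifest <- list(
    counts = list(
      gaze = nrow(streams$gaze), fixations = nrow(streams$fixations),
      blinks = nrow(streams$blinks), saccades = nrow(streams$saccades),
      pupil = nrow(streams$pupil), events = nrow(streams$events)),
    blink = list(total_duration_ms = sum(streams$blinks$duration_ms),
                 start_ts = streams$blinks$start_ts,
                 durations_ms = streams$blinks$duration_ms),
    fixation = list(durations_ms = streams$fixations$duration_ms,
                    x = streams$fixations$x, y = streams$fixations$y),
    saccade = list(amplitudes_px = streams$saccades$amplitude_px,
                   peak_velocity_max = if (nrow(streams$saccades))
                     max(streams$saccades$peak_velocity) else NA),
    roi = list(
      gaze_on_fraction = if (nrow(streams$surface_gaze))
        mean(streams$surface_gaze$on_surface) else NA,
      fixation_on_fraction = if (nrow(streams$surface_fixations))
        mean(streams$surface_fixations$on_surface) else NA),
    epochs = if (!is.null(epochs)) list(
      name = epochs$name, start_ts = epochs$start_ts,
      end_ts = epochs$end_ts, duration_ms = epochs$duration_ms) else NULL,
    seed = if (!is.null(config)) config$seed else NULL,
    parameters = if (!is.null(config))
      config[setdiff(names(config), c("roi_schedule", "events"))] else NULL
  )
  manifest
}

# CSV headers in the canonical cloud-export dialect, per stream.
gp_export_headers <- function() {
  list(
    gaze = c("timestamp [ns]", "gaze x [px]", "gaze y [px]", "worn",
             "fixation id", "blink id"),
    fixations = c("fixation id", "start timestamp [ns]",
                  "end timestamp [ns]", "duration [ms]", "fixation x [px]",
                  "fixation y [px]"),
    blinks = c("blink id", "start timestamp [ns]", "end timestamp [ns]",
               "duration [ms]"),
    saccades = c("saccade id", "start timestamp [ns]", "end timestamp [ns]",
                 "duration [ms]", "amplitude [px]", "mean velocity [px/s]",
                 "peak velocity [px/s]"),
    pupil = c("timestamp [ns]", "pupil diameter left [mm]",
              "pupil diameter right [mm]"),
    events = c("name", "timestamp [ns]"),
    surface_gaze = c("timestamp [ns]", "gaze detected on surface",
                     "gaze position on surface x [normalized]",
                     "gaze position on surface y [normalized]"),
    surface_fixations = c("timestamp [ns]", "fixation detected on surface",
                          "fixation x [normalized]",
                          "fixation y [normalized]")
  )
}

fmt_ns <- function(x) sprintf("%.0f", x)

write_dialect_csv <- function(df, headers, path) {
  names(df) <- headers
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
}

#' Write recording streams to a dialect folder
#'
#' Low-level writer used by [generate_recording()] and
#' [scripted_recording()]: emits the canonical CSV files and
#' `manifest.json`.
#'
#' @param streams named list of internal-form stream data.frames.
#' @param folder output directory.
#' @param manifest manifest list to serialise alongside.
#' @return the folder, invisibly.
#' @export
write_recording_folder <- function(streams, folder, manifest = NULL) {
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  hdr <- gp_export_headers()
  g <- streams$gaze
  write_dialect_csv(
    data.frame(fmt_ns(g$ts), g$x, g$y, tolower(as.character(g$worn)),
               g$fixation_id, g$blink_id, check.names = FALSE),
    hdr$gaze, file.path(folder, "gaze.csv"))
  f <- streams$fixations
  write_dialect_csv(
    data.frame(f$id, fmt_ns(f$start_ts), fmt_ns(f$end_ts), f$duration_ms,
               f$x, f$y, check.names = FALSE),
    hdr$fixations, file.path(folder, "fixations.csv"))
  b <- streams$blinks
  write_dialect_csv(
    data.frame(id = b$id, s = fmt_ns(b$start_ts), e = fmt_ns(b$end_ts),
               d = b$duration_ms, check.names = FALSE),
    hdr$blinks, file.path(folder, "blinks.csv"))
  s <- streams$saccades
  write_dialect_csv(
    data.frame(s$id, fmt_ns(s$start_ts), fmt_ns(s$end_ts), s$duration_ms,
               s$amplitude_px, s$mean_velocity, s$peak_velocity,
               check.names = FALSE),
    hdr$saccades, file.path(folder, "saccades.csv"))
  p <- streams$pupil
  write_dialect_csv(
    data.frame(fmt_ns(p$ts), p$diameter_left, p$diameter_right,
               check.names = FALSE),
    hdr$pupil, file.path(folder, "3d_eye_states.csv"))
  e <- streams$events
  write_dialect_csv(
    data.frame(e$name, fmt_ns(e$ts), check.names = FALSE),
    hdr$events, file.path(folder, "events.csv"))
  sg <- streams$surface_gaze
  write_dialect_csv(
    data.frame(fmt_ns(sg$ts), tolower(as.character(sg$on_surface)), sg$sx,
               sg$sy, check.names = FALSE),
    hdr$surface_gaze, file.path(folder, "enrichment_gaze.csv"))
  sf <- streams$surface_fixations
  write_dialect_csv(
    data.frame(fmt_ns(sf$ts), tolower(as.character(sf$on_surface)), sf$sx,
               sf$sy, check.names = FALSE),
    hdr$surface_fixations, file.path(folder, "enrichment_fixations.csv"))
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, file.path(folder, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(folder)
}

#' Read a folder's ground-truth manifest
#'
#' @param folder recording folder written by the generator.
#' @return the manifest list.
#' @export
read_manifest <- function(folder) {
  path <- file.path(folder, "manifest.json")
  if (!file.exists(path)) gp_stop("simulate", sprintf("no manifest in %s", folder))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a scripted (noise-free) recording
#'
#' Takes explicit stream tables with exact timestamps/positions, checks
#' internal consistency (ordering, blink overlap, gaze label references),
#' and writes a deterministic folder plus manifest for exact-equality
#' tests.
#'
#' @param script named list of internal-form stream data.frames: `gaze`,
#'   `fixations`, `blinks`, `saccades`, `pupil`, `events`, `surface_gaze`,
#'   `surface_fixations`.  Missing optional streams default to empty.
#' @param folder output directory.
#' @return invisibly, a list `folder`, `manifest`.
#' @export
scripted_recording <- function(script, folder) {
  empty <- list(
    gaze = data.frame(ts = numeric(), x = numeric(), y = numeric(),
                      worn = logical(), fixation_id = integer(),
                      blink_id = integer()),
    fixations = data.frame(id = integer(), start_ts = numeric(),
                           end_ts = numeric(), duration_ms = numeric(),
                           x = numeric(), y = numeric()),
    blinks = data.frame(id = integer(), start_ts = numeric(),
                        end_ts = numeric(), duration_ms = numeric()),
    saccades = data.frame(id = integer(), start_ts = numeric(),
                          end_ts = numeric(), duration_ms = numeric(),
                          amplitude_px = numeric(),
                          mean_velocity = numeric(),
                          peak_velocity = numeric()),
    pupil = data.frame(ts = numeric(), diameter_left = numeric(),
                       diameter_right = numeric(), diameter = numeric()),
    events = data.frame(name = character(), ts = numeric()),
    surface_gaze = data.frame(ts = numeric(), on_surface = logical(),
                              sx = numeric(), sy = numeric()),
    surface_fixations = data.frame(ts = numeric(), on_surface = logical(),
                                   sx = numeric(), sy = numeric())
  )
  streams <- empty
  for (nm in intersect(names(script), names(empty))) {
    streams[[nm]] <- script[[nm]]
  }

  # consistency checks: fail before writing, naming the clash
  b <- streams$blinks
  if (nrow(b) > 1L) {
    b <- b[order(b$start_ts), ]
    ov <- which(b$end_ts[-nrow(b)] > b$start_ts[-1L])
    if (length(ov)) {
      gp_stop("simulate", sprintf("scripted blinks %d and %d overlap",
                                  b$id[ov[1]], b$id[ov[1] + 1L]))
    }
  }
  for (nm in c("fixations", "blinks", "saccades")) {
    tab <- streams[[nm]]
    if (nrow(tab) && any(tab$end_ts <= tab$start_ts)) {
      gp_stop("simulate", sprintf("scripted %s contain an empty interval", nm))
    }
  }
  fid <- streams$gaze$fixation_id
  dangling <- setdiff(unique(fid[!is.na(fid)]), streams$fixations$id)
  if (length(dangling)) {
    gp_stop("simulate", sprintf(
      "scripted gaze references missing fixation id(s): %s",
      paste(dangling, collapse = ", ")))
  }
  manifest <- build_manifest(streams)
  write_recording_folder(streams, folder, manifest)
  invisible(list(folder = folder, manifest = manifest))
}
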