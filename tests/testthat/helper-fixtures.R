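# Deterministic scripted fixture used across the suite.
#
# Layout: n_fix fixations of 200 ms every 400 ms (200 ms inter-fixation
# gaps), gaze and pupil sampled at 100 Hz, one saccade per gap, n_blinks
# non-overlapping blinks with durations cycling 100/150/200 ms, a linear
# pupil ramp, an all-on (configurable) surface schedule, and start/end
# events.  Every derived quantity is computed here, independently of the
# pipeline, as the test oracle.

scripted_streams <- function(n_fix = 12, n_blinks = 7,
                             roi_on = function(t_s) rep(TRUE, length(t_s))) {
  # all timing in exact integer nanoseconds (10 ms sample pitch)
  fix_dur_ns <- 2e8
  pitch_ns <- 4e8
  step_ns <- 1e7  # 100 Hz
  rate <- 100
  duration_ns <- n_fix * pitch_ns
  duration_s <- duration_ns / 1e9

  fx_start <- (seq_len(n_fix) - 1) * pitch_ns
  fx_end <- fx_start + fix_dur_ns
  fx_x <- 100 * seq_len(n_fix)
  fx_y <- 50 * seq_len(n_fix)
  fixations <- data.frame(
    id = seq_len(n_fix), start_ts = fx_start, end_ts = fx_end,
    duration_ms = rep(fix_dur_ns / 1e6, n_fix), x = fx_x, y = fx_y)

  gap_s <- (pitch_ns - fix_dur_ns) / 1e9
  sc_amp <- sqrt(diff(fx_x)^2 + diff(fx_y)^2)
  saccades <- data.frame(
    id = seq_len(n_fix - 1), start_ts = fx_end[-n_fix],
    end_ts = fx_start[-1],
    duration_ms = rep(gap_s * 1000, n_fix - 1),
    amplitude_px = sc_amp,
    mean_velocity = sc_amp / gap_s,
    peak_velocity = 1.5 * sc_amp / gap_s)

  blink_durs_ms <- rep(c(100, 150, 200), length.out = n_blinks)
  blink_starts <- 2.5e8 + 4e8 * (seq_len(n_blinks) - 1)
  stopifnot(max(blink_starts) + max(blink_durs_ms) * 1e6 < duration_ns)
  blinks <- data.frame(
    id = seq_len(n_blinks), start_ts = blink_starts,
    end_ts = blink_starts + blink_durs_ms * 1e6,
    duration_ms = blink_durs_ms)

  ts <- seq(0, duration_ns - step_ns, by = step_ns)
  k <- findInterval(ts, fx_start)
  fid <- ifelse(k >= 1 & ts < fx_end[pmax(k, 1)], k, NA_integer_)
  gx <- numeric(length(ts))
  gy <- numeric(length(ts))
  for (i in seq_along(ts)) {
    ki <- k[i]
    if (!is.na(fid[i])) {
      gx[i] <- fx_x[ki]; gy[i] <- fx_y[ki]
    } else if (ki >= 1 && ki < n_fix) {
      frac <- (ts[i] - fx_end[ki]) / (fx_start[ki + 1] - fx_end[ki])
      gx[i] <- fx_x[ki] + frac * (fx_x[ki + 1] - fx_x[ki])
      gy[i] <- fx_y[ki] + frac * (fx_y[ki + 1] - fx_y[ki])
    } else {
      gx[i] <- fx_x[n_fix]; gy[i] <- fx_y[n_fix]
    }
  }
  gaze <- data.frame(ts = ts, x = gx, y = gy, worn = TRUE,
                     fixation_id = as.integer(fid),
                     blink_id = NA_integer_)

  t_s <- ts / 1e9
  d <- 3 + 0.2 * t_s
  pupil <- data.frame(ts = ts, diameter_left = d + 0.1,
                      diameter_right = d - 0.1, diameter = NA_real_)

  on_g <- roi_on(t_s)
  surface_gaze <- data.frame(ts = ts, on_surface = on_g,
                             sx = ifelse(on_g, pmin(gx / 1600, 1), NA),
                             sy = ifelse(on_g, pmin(gy / 1200, 1), NA))
  mid <- (fx_start + fx_end) / 2
  on_f <- roi_on(mid / 1e9)
  surface_fixations <- data.frame(ts = mid, on_surface = on_f,
                                  sx = ifelse(on_f, fx_x / 1600, NA),
                                  sy = ifelse(on_f, fx_y / 1200, NA))
  events <- data.frame(name = c("start", "end"), ts = c(0, duration_ns),
                       stringsAsFactors = FALSE)

  streams <- list(gaze = gaze, fixations = fixations, blinks = blinks,
                  saccades = saccades, pupil = pupil, events = events,
                  surface_gaze = surface_gaze,
                  surface_fixations = surface_fixations)
  truth <- list(
    n_fix = n_fix, n_blinks = n_blinks, n_saccades = n_fix - 1,
    n_movements = n_fix - 1, n_gaze = length(ts),
    samples_per_fixation = as.integer(fix_dur_ns / step_ns),
    samples_per_movement = as.integer((pitch_ns - fix_dur_ns) / step_ns),
    duration_s = duration_s,
    blink_total_ms = sum(blink_durs_ms),
    blink_durs_ms = blink_durs_ms,
    fixation_duration_ms = fix_dur_ns / 1e6,
    fixation_step_px = sqrt(100^2 + 50^2),
    saccade_mean_vel = sc_amp / gap_s,
    pupil_first = 3, pupil_last = 3 + 0.2 * max(t_s),
    # movement runs cover 19/20 of each gap (last sample sits 10 ms short)
    movement_path_px = 0.95 * sqrt(100^2 + 50^2),
    movement_duration_ms = 190)
  list(streams = streams, truth = truth)
}

scripted_rec <- function(fx = scripted_streams()) {
  s <- fx$streams
  gaze_recording(s$gaze, s$fixations, s$blinks, s$saccades, s$pupil,
                 s$events, s$surface_gaze, s$surface_fixations,
                 participant = "T01")
}

write_fixture_folder <- function(fx = scripted_streams(),
                                 dir = withr::local_tempdir(
                                   .local_envir = parent.frame())) {
  scripted_recording(fx$streams, dir)
  dir
}

# whole-recording single epoch of a recording
whole_epoch <- function(rec) {
  sp <- recording_span(rec)
  data.frame(name = "all", start_ts = sp[1], end_ts = sp[2] + 1,
             duration_ms = (sp[2] + 1 - sp[1]) / 1e6)
}

expect_same_recording <- function(a, b) {
  for (s in c("gaze", "fixations", "blinks", "saccades", "pupil", "events",
              "surface_gaze", "surface_fixations")) {
    expect_equal(a[[s]], b[[s]], ignore_attr = TRUE, label = s)
  }
}
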