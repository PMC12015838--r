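# ROI membership annotation from the enrichment stream.

test_that("an all-on surface stream flags every gaze frame 1", {
  fx <- scripted_streams()
  flags <- annotate_gaze_on_roi(fx$streams$gaze, fx$streams$surface_gaze)
  expect_true(all(flags == 1L))
})

test_that("a planted 60%-on schedule is annotated exactly on the grid fixture", {
  # first 60% of the 4.8 s recording on the surface, rest off
  fx <- scripted_streams(roi_on = function(t_s) t_s < 0.6 * 4.8)
  flags <- annotate_gaze_on_roi(fx$streams$gaze, fx$streams$surface_gaze)
  expect_equal(mean(flags), 0.6)
})

test_that("gaze frames far from any surface sample get 0 plus one gap warning", {
  gaze <- data.frame(ts = c(0, 5e8, 1e9))
  surf <- data.frame(ts = c(0, 1e9), on_surface = c(TRUE, TRUE))
  expect_warning(flags <- annotate_gaze_on_roi(gaze, surf), "tolerance")
  expect_equal(flags, c(1L, 0L, 1L))
})

test_that("pupil flags are logical and follow the nearest-sample rule", {
  fx <- scripted_streams(roi_on = function(t_s) floor(t_s) %% 2 == 0)
  flags <- annotate_pupil_on_roi(fx$streams$pupil, fx$streams$surface_gaze)
  expect_type(flags, "logical")
  # 1 s on / 1 s off alternation over 4.8 s: on during [0,1),[2,3),[4,4.8)
  planted <- floor(fx$streams$pupil$ts / 1e9) %% 2 == 0
  expect_lte(sum(flags != planted), 2)  # at most one sample per transition
  expect_equal(annotate_pupil_on_roi(fx$streams$pupil[0, ],
                                     fx$streams$surface_gaze), logical(0))
})

test_that("a blink inside a continuously-on span is on-ROI", {
  fx <- scripted_streams()
  out <- annotate_intervals_on_roi(fx$streams$blinks,
                                   fx$streams$surface_gaze,
                                   policy = "blink")
  expect_true(all(out$on_roi))
})

test_that("saccade policy is a majority vote over overlapping samples", {
  surf <- data.frame(ts = c(0, 1e7, 2e7, 3e7),
                     on_surface = c(TRUE, TRUE, TRUE, FALSE))
  sac <- data.frame(id = 1L, start_ts = 0, end_ts = 4e7,
                    duration_ms = 40)
  out <- annotate_intervals_on_roi(sac, surf, policy = "majority")
  expect_true(out$on_roi)    # 3 on vs 1 off
  surf$on_surface <- c(FALSE, FALSE, FALSE, TRUE)
  expect_false(annotate_intervals_on_roi(sac, surf,
                                         policy = "majority")$on_roi)
  # tie breaks to the status at onset
  surf$on_surface <- c(TRUE, TRUE, FALSE, FALSE)
  expect_true(annotate_intervals_on_roi(sac, surf,
                                        policy = "majority")$on_roi)
})

test_that("an isolated blink defaults to off-ROI with a warning", {
  surf <- data.frame(ts = 0, on_surface = TRUE)
  blink <- data.frame(id = 1L, start_ts = 5e9, end_ts = 5.1e9,
                      duration_ms = 100)
  expect_warning(out <- annotate_intervals_on_roi(blink, surf,
                                                  policy = "blink"),
                 "defaulted")
  expect_false(out$on_roi)
})

test_that("blink lookback precedes lookahead", {
  # last sample before onset is off, first after offset is on -> off wins
  surf <- data.frame(ts = c(0.9e9, 1.25e9),
                     on_surface = c(FALSE, TRUE))
  blink <- data.frame(id = 1L, start_ts = 1e9, end_ts = 1.1e9,
                      duration_ms = 100)
  expect_false(annotate_intervals_on_roi(blink, surf,
                                         policy = "blink")$on_roi)
  # with no pre-onset sample in range the lookahead decides
  surf2 <- data.frame(ts = 1.25e9, on_surface = TRUE)
  expect_true(annotate_intervals_on_roi(blink, surf2,
                                        policy = "blink")$on_roi)
})

test_that("annotation only adds flags, never mutates streams", {
  fx <- scripted_streams()
  rec <- scripted_rec(fx)
  ann <- annotate_recording(rec)
  for (s in c("blinks", "saccades")) {
    expect_equal(ann[[s]][names(rec[[s]])], rec[[s]])
  }
  expect_equal(nrow(ann$gaze), nrow(rec$gaze))
  expect_equal(ann$pupil$ts, rec$pupil$ts)
})

test_that("flipping a surface sample on never turns an interval off", {
  set.seed(3)
  surf <- data.frame(ts = seq(0, 1e9, by = 5e7),
                     on_surface = runif(21) < 0.5)
  sacs <- data.frame(id = 1:4,
                     start_ts = c(0, 2.6e8, 5.1e8, 7.6e8),
                     end_ts = c(2.5e8, 5.0e8, 7.5e8, 1e9),
                     duration_ms = rep(250, 4))
  base <- annotate_intervals_on_roi(sacs, surf, policy = "majority")$on_roi
  for (j in which(!surf$on_surface)) {
    surf2 <- surf
    surf2$on_surface[j] <- TRUE
    flipped <- annotate_intervals_on_roi(sacs, surf2,
                                         policy = "majority")$on_roi
    expect_true(all(flipped >= base))
  }
})

test_that("constant surface flags are inherited by every interval", {
  fx <- scripted_streams(roi_on = function(t_s) rep(FALSE, length(t_s)))
  blinks <- annotate_intervals_on_roi(fx$streams$blinks,
                                      fx$streams$surface_gaze, "blink")
  sacs <- annotate_intervals_on_roi(fx$streams$saccades,
                                    fx$streams$surface_gaze, "majority")
  expect_true(all(!blinks$on_roi))
  expect_true(all(!sacs$on_roi))
})

test_that("roi_occupancy_fraction is the mean flag with binomial accuracy", {
  expect_equal(roi_occupancy_fraction(c(1, 1, 1)), 1)
  expect_equal(roi_occupancy_fraction(c(1, 0, 1, 0)), 0.5)
  expect_error(roi_occupancy_fraction(numeric()), "empty")
  set.seed(5)
  p <- 0.37
  n <- 1e4
  flags <- runif(n) < p
  expect_lt(abs(roi_occupancy_fraction(flags) - p),
            3 * sqrt(p * (1 - p) / n))
})
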