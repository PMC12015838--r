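# The per-epoch index battery, descriptive statistics and the comparison
# machinery.

test_that("euclidean distance follows the closed form", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  p <- point2d(2.5, -1)
  expect_equal(euclidean_distance(p, p), 0)
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(2) * 100
    b <- rnorm(2) * 100
    expect_equal(euclidean_distance(a, b),
                 sqrt(sum((b - a)^2)), tolerance = 1e-12)
  }
  expect_error(
    euclidean_distance(point2d(0, 0, "px"), point2d(1, 1, "norm")),
    "mixed coordinate units")
})

test_that("descriptive stats use the population standard deviation", {
  s <- descriptive_stats(c(2, 2, 2))
  expect_equal(s$mean, 2)
  expect_equal(s$std, 0)
  s2 <- descriptive_stats(c(1, 2, 3))
  expect_equal(s2$mean, 2)
  expect_equal(s2$std, sqrt(2 / 3))   # divisor n, not n-1
  expect_equal(s2$total, 6)
  expect_equal(s2$count, 3)
  expect_error(descriptive_stats(numeric()), "empty")
})

test_that("descriptive stats respect ordering and scaling properties", {
  set.seed(4)
  for (i in 1:10) {
    v <- rnorm(sample(2:30, 1), sd = 10)
    s <- descriptive_stats(v)
    expect_lte(s$minimum, s$mean)
    expect_lte(s$mean, s$maximum)
    c_scale <- runif(1, -5, 5)
    expect_equal(descriptive_stats(v * c_scale)$std, abs(c_scale) * s$std)
  }
  expect_equal(descriptive_stats(c(7.3, 7.3))$std, 0)
})

test_that("blink indices match a hand-built fixture", {
  rec <- scripted_rec()
  rec$blinks <- data.frame(id = 1:3,
                           start_ts = c(0, 1e9, 2e9),
                           end_ts = c(1e8, 1.15e9, 2.2e9),
                           duration_ms = c(100, 150, 200),
                           on_roi = c(TRUE, TRUE, FALSE))
  f <- blink_features(rec)
  v <- setNames(f$value, f$index)
  expect_equal(v[["count"]], 3)
  expect_equal(v[["duration_total"]], 450)
  expect_equal(v[["duration_average"]], 150)
  expect_equal(v[["duration_surface"]], 250)
})

test_that("zero blinks report zeros; all-on-ROI makes surface equal total", {
  rec <- scripted_rec()
  rec$blinks <- rec$blinks[0, ]
  rec$blinks$on_roi <- logical()
  v <- setNames(blink_features(rec)$value, blink_features(rec)$index)
  expect_equal(unname(v[c("count", "duration_total", "duration_average",
                          "duration_surface")]), c(0, 0, 0, 0))
  rec2 <- annotate_recording(scripted_rec())
  v2 <- setNames(blink_features(rec2)$value, blink_features(rec2)$index)
  expect_equal(v2[["duration_surface"]], v2[["duration_total"]])
})

test_that("fixation indices: collinear distances, argmax position, manifest", {
  rec <- scripted_rec()
  rec$fixations <- data.frame(id = 1:3,
                              start_ts = c(0, 1e9, 2e9),
                              end_ts = c(2e8, 1.4e9, 2.3e9),
                              duration_ms = c(200, 400, 300),
                              x = c(0, 10, 30), y = c(5, 5, 5))
  rec$surface_fixations <- rec$surface_fixations[0, ]
  f <- fixation_features(rec)
  v <- setNames(f$value, f$index)
  expect_equal(v[["count"]], 3)
  expect_equal(v[["distance_absolute_total"]], 30)
  expect_equal(v[["distance_absolute_average"]], 15)
  expect_equal(v[["position_max_duration_x"]], 10)  # the 400 ms fixation
  expect_equal(v[["duration_max"]], 400)
  expect_equal(v[["duration_min"]], 200)
  # scripted fixture: every index from the planted layout
  fx <- scripted_streams()
  v2 <- setNames(fixation_features(scripted_rec(fx))$value,
                 fixation_features(scripted_rec(fx))$index)
  expect_equal(v2[["count"]], fx$truth$n_fix)
  expect_equal(v2[["duration_total"]],
               fx$truth$n_fix * fx$truth$fixation_duration_ms)
  expect_equal(v2[["distance_absolute_total"]],
               (fx$truth$n_fix - 1) * fx$truth$fixation_step_px)
})

test_that("single fixations empty-mark the distance indices", {
  rec <- scripted_rec()
  rec$fixations <- rec$fixations[1, ]
  v <- setNames(fixation_features(rec)$value, fixation_features(rec)$index)
  expect_equal(v[["distance_absolute_total"]], 0)  # additive: empty sums to 0
  expect_true(is.na(v[["distance_absolute_average"]]))
  expect_true(is.na(v[["distance_relative_average"]]))
  expect_equal(v[["count"]], 1)
})

test_that("gaze indices aggregate groups and movements", {
  fx <- scripted_streams()
  rec <- scripted_rec(fx)
  rec$gaze <- index_movements(rec$gaze)
  v <- setNames(gaze_features(rec)$value, gaze_features(rec)$index)
  expect_equal(v[["count_total"]], fx$truth$n_gaze)
  expect_equal(v[["count_per_fixation"]], fx$truth$samples_per_fixation)
  expect_equal(v[["count_per_movement"]], fx$truth$samples_per_movement)
  expect_equal(v[["movement_duration_average"]],
               fx$truth$movement_duration_ms)
  expect_equal(v[["movement_distance_absolute_average"]],
               fx$truth$movement_path_px, tolerance = 1e-9)
  # per-fixation mean with groups {5, 7} is 6
  g <- data.frame(ts = (0:11) * 1e7, x = 0, y = 0,
                  fixation_id = rep(c(1L, 2L), c(5, 7)),
                  blink_id = NA_integer_)
  rec2 <- rec
  rec2$gaze <- index_movements(g)
  v2 <- setNames(gaze_features(rec2)$value, gaze_features(rec2)$index)
  expect_equal(v2[["count_per_fixation"]], 6)
})

test_that("saccade indices reduce the planted kinematics", {
  rec <- scripted_rec()
  rec$saccades <- data.frame(id = 1:3,
                             start_ts = c(0, 1e9, 2e9),
                             end_ts = c(5e7, 1.05e9, 2.05e9),
                             duration_ms = c(50, 50, 50),
                             amplitude_px = c(10, 20, 30),
                             mean_velocity = c(200, 400, 600),
                             peak_velocity = c(300, 500, 450))
  v <- setNames(saccade_features(rec)$value, saccade_features(rec)$index)
  expect_equal(v[["count"]], 3)
  expect_equal(v[["amplitude_average"]], 20)
  expect_equal(v[["peak_velocity"]], 500)
  expect_equal(v[["mean_velocity_max"]], 600)
  rec$saccades <- rec$saccades[0, ]
  v0 <- setNames(saccade_features(rec)$value, saccade_features(rec)$index)
  expect_equal(v0[["count"]], 0)
  expect_true(is.na(v0[["amplitude_average"]]))
})

test_that("pupil indices: constant, ramp, and on-ROI restriction", {
  rec <- scripted_rec()
  rec$pupil <- data.frame(ts = (0:9) * 1e7, diameter_left = NA_real_,
                          diameter_right = NA_real_, diameter = 3.0)
  v <- setNames(pupil_features(rec)$value, pupil_features(rec)$index)
  expect_equal(unname(v[c("diameter_first", "diameter_last", "diameter_max",
                          "diameter_min", "diameter_average")]),
               rep(3, 5))
  rec$pupil$diameter <- seq(2, 4, length.out = 10)
  v2 <- setNames(pupil_features(rec)$value, pupil_features(rec)$index)
  expect_equal(v2[["diameter_first"]], 2)
  expect_equal(v2[["diameter_last"]], 4)
  rec$pupil$on_roi <- rep(c(TRUE, FALSE), 5)
  v3 <- setNames(pupil_features(rec, roi_only = TRUE)$value,
                 pupil_features(rec, roi_only = TRUE)$index)
  expect_equal(v3[["diameter_average"]],
               mean(rec$pupil$diameter[c(1, 3, 5, 7, 9)]))
})

test_that("extract_report fills the epoch-by-category grid deterministically", {
  rec <- annotate_recording(scripted_rec())
  rec$gaze <- index_movements(rec$gaze)
  ev <- data.frame(name = c("start", "mid", "end"), ts = c(0, 2e9, 4.8e9))
  rep1 <- extract_report(rec, build_epochs(ev))
  rep2 <- extract_report(rec, build_epochs(ev))
  expect_identical(rep1, rep2)
  expect_equal(nrow(unique(rep1[, c("epoch", "category")])), 10)
})

test_that("additive indices are conserved over an epoch partition", {
  fx <- scripted_streams()
  rec <- annotate_recording(scripted_rec(fx))
  rec$gaze <- index_movements(rec$gaze)
  whole <- extract_report(rec, build_epochs(
    data.frame(name = c("start", "end"), ts = c(0, 4.8e9))))
  split2 <- extract_report(rec, build_epochs(
    data.frame(name = c("a", "b", "end"), ts = c(0, 2.2e9, 4.8e9))))
  for (sel in list(c("blink", "count"), c("blink", "duration_total"),
                   c("fixations", "count"), c("fixations", "duration_total"),
                   c("saccade", "count"), c("saccade", "duration_total"),
                   c("gaze", "count_total"))) {
    w <- report_value(whole, sel[1], sel[2])
    s <- report_value(split2, sel[1], sel[2])
    expect_equal(unname(sum(s)), unname(w), label = paste(sel, collapse = "/"))
  }
})

test_that("the blink-count filter removes epochs strictly above threshold", {
  rec <- annotate_recording(scripted_rec())
  rec$gaze <- index_movements(rec$gaze)
  ev <- data.frame(name = c("e1", "e2", "end"), ts = c(0, 2.4e9, 4.8e9))
  report <- extract_report(rec, build_epochs(ev))
  # plant blink counts by editing the report directly
  counts <- c(6, 3)
  rows <- report$category == "blink" & report$index == "count"
  report$value[rows] <- counts[report$epoch[rows]]
  out <- filter_epochs_by_blinks(report, threshold = 5)
  expect_equal(unique(out$report$epoch), 2)
  expect_equal(out$exclusions$epoch, 1)
  expect_equal(out$exclusions$blink_count, 6)
  # threshold at infinity is the identity
  all_kept <- filter_epochs_by_blinks(report, threshold = Inf)
  expect_equal(nrow(all_kept$report), nrow(report))
  # exactly at the boundary is kept (strict inequality)
  report$value[rows] <- c(5, 6)
  kept <- filter_epochs_by_blinks(report, threshold = 5)
  expect_equal(unique(kept$report$epoch), 1)
  # everything above threshold empties the report
  report$value[rows] <- c(9, 7)
  none <- filter_epochs_by_blinks(report, threshold = 5)
  expect_equal(nrow(none$report), 0)
  expect_equal(nrow(none$exclusions), 2)
})

test_that("the pooled t statistic matches direct formula evaluation", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  fit <- two_sample_ttest(a, b)
  # textbook pooled formula, evaluated directly
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_direct <- (mean(a) - mean(b)) /
    sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(fit$t, t_direct, tolerance = 1e-10)
  expect_equal(fit$df, 4)
  expect_equal(fit$p, 2 * pt(-abs(t_direct), 4), tolerance = 1e-10)
})

test_that("the t statistic is antisymmetric and zero for identical groups", {
  set.seed(8)
  x <- rnorm(10)
  y <- rnorm(12, mean = 1)
  expect_equal(two_sample_ttest(x, y)$t, -two_sample_ttest(y, x)$t)
  expect_equal(two_sample_ttest(x, x)$t, 0)
  degenerate <- two_sample_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(degenerate$t, 0)
  expect_equal(degenerate$p, 1)
  welch <- two_sample_ttest(x, y, var_equal = FALSE)
  expect_false(isTRUE(all.equal(welch$df, 20)))
})
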