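# Prepared-plot numeric content; rendering is checked only for side effects.

test_that("pupil ROI series segments follow the planted schedule", {
  pupil <- data.frame(ts = (0:9) * 1e7, diameter = 3,
                      on_roi = rep(c(TRUE, FALSE), each = 5))
  p <- prepare_pupil_roi_series(pupil)
  expect_equal(nrow(p$annotations$segments), 2)
  expect_equal(p$annotations$segments$colour, c("green", "red"))
  pupil$on_roi <- TRUE
  expect_equal(nrow(prepare_pupil_roi_series(pupil)$annotations$segments), 1)
  # alternating schedule: transitions + 1 segments
  pupil$on_roi <- rep(c(TRUE, FALSE), 5)
  expect_equal(nrow(prepare_pupil_roi_series(pupil)$annotations$segments),
               10)
  expect_error(prepare_pupil_roi_series(pupil[0, ]), "empty")
  pupil$on_roi <- NULL
  expect_error(prepare_pupil_roi_series(pupil), "not ROI-annotated")
})

test_that("the blink raster integrates to the total blink duration", {
  fx <- scripted_streams()
  p <- prepare_blink_series(fx$streams$blinks, c(0, 4.8e9))
  # integrate the step series by the trapezoid on its edge representation
  t <- p$series$t_s
  v <- p$series$value
  integral_ms <- sum((t[-1] - t[-length(t)]) *
                     (v[-1] + v[-length(v)]) / 2) * 1000
  expect_equal(integral_ms, fx$truth$blink_total_ms)
  expect_equal(p$annotations$n_blinks, fx$truth$n_blinks)
  # no blinks: constant zero
  p0 <- prepare_blink_series(fx$streams$blinks[0, ], c(0, 1e9))
  expect_true(all(p0$series$value == 0))
})

test_that("saccade series convert units and keep peak above mean", {
  fx <- scripted_streams()
  p <- prepare_saccade_series(fx$streams$saccades, "velocity")
  expect_true(all(p$series$peak_px_ms >= p$series$mean_px_ms))
  expect_equal(p$series$mean_px_ms,
               fx$streams$saccades$mean_velocity / 1000)
  pa <- prepare_saccade_series(fx$streams$saccades, "amplitude")
  expect_equal(pa$series$amplitude_px, fx$streams$saccades$amplitude_px)
})

test_that("the fixation-cloud density integrates to one", {
  set.seed(12)
  x <- rnorm(200, 500, 60)
  y <- rnorm(200, 400, 50)
  p <- prepare_fixation_cloud(x, y)
  dx <- diff(p$series$gx[1:2])
  dy <- diff(p$series$gy[1:2])
  mass <- sum(p$series$density) * dx * dy
  expect_equal(mass, 1, tolerance = 0.02)
})

test_that("two well-separated clusters produce two density modes", {
  set.seed(13)
  x <- c(rnorm(150, 200, 15), rnorm(150, 900, 15))
  y <- c(rnorm(150, 200, 15), rnorm(150, 800, 15))
  p <- prepare_fixation_cloud(x, y)
  z <- matrix(p$series$density, nrow = length(p$series$gx))
  # local maxima of the grid
  top <- order(z, decreasing = TRUE)[1]
  i1 <- arrayInd(top, dim(z))
  m1 <- c(p$series$gx[i1[1]], p$series$gy[i1[2]])
  # mask out a broad region around the first mode, find the second
  d1 <- outer(p$series$gx - m1[1], p$series$gy - m1[2],
              function(a, b) sqrt(a^2 + b^2))
  z2 <- z
  z2[d1 < 250] <- 0
  i2 <- arrayInd(order(z2, decreasing = TRUE)[1], dim(z))
  m2 <- c(p$series$gx[i2[1]], p$series$gy[i2[2]])
  centroids <- rbind(c(200, 200), c(900, 800))
  d_assign <- function(m) min(sqrt(rowSums((centroids - rep(m, each = 2))^2)))
  expect_lt(d_assign(m1), 30)
  expect_lt(d_assign(m2), 30)
})

test_that("a single tight cluster has its mode at the centroid", {
  set.seed(14)
  x <- rnorm(100, 300, 5)
  y <- rnorm(100, 300, 5)
  p <- prepare_fixation_cloud(x, y)
  z <- matrix(p$series$density, nrow = length(p$series$gx))
  i <- arrayInd(which.max(z), dim(z))
  cell <- c(diff(p$series$gx[1:2]), diff(p$series$gy[1:2]))
  expect_lt(abs(p$series$gx[i[1]] - mean(x)), 3 * cell[1] + 2)
  expect_lt(abs(p$series$gy[i[2]] - mean(y)), 3 * cell[2] + 2)
})

test_that("fewer than two points degrade to a scatter with a warning", {
  expect_warning(p <- prepare_fixation_cloud(1, 2), "scatter only")
  expect_false(isTRUE(p$annotations$density))
})

test_that("paths preserve geometry and mode constraints", {
  fx <- scripted_streams()
  f <- fx$streams$fixations
  p <- prepare_path(f$x, f$y, "absolute")
  expect_equal(p$annotations$total_length,
               (fx$truth$n_fix - 1) * fx$truth$fixation_step_px)
  rel <- prepare_path(f$x / 1600, f$y / 1200, "relative")
  expect_true(all(rel$series$x >= 0 & rel$series$x <= 1))
  # reversal flips marker order, keeps geometry
  pr <- prepare_path(rev(f$x), rev(f$y), "absolute")
  expect_equal(pr$annotations$total_length, p$annotations$total_length)
  expect_equal(pr$series$x, rev(p$series$x))
  expect_error(prepare_path(1, 1, "absolute"), "at least 2")
  expect_error(prepare_path(c(0, 2), c(0, 1), "relative"), "\\[0, 1\\]")
})

test_that("histograms conserve counts and spread uniform data evenly", {
  v <- c(1, 1, 1, 5, 9)
  h <- prepare_histogram(v, bins = 4)
  expect_equal(sum(h$series$counts), 5)
  expect_length(h$series$edges, 5)
  h1 <- prepare_histogram(rep(2, 10), bins = 7)
  expect_equal(sum(h1$series$counts > 0), 1)
  set.seed(15)
  n <- 1e4
  h2 <- prepare_histogram(runif(n), bins = 10)
  expect_equal(sum(h2$series$counts), n)
  sigma <- sqrt(n * 0.1 * 0.9)
  expect_true(all(abs(h2$series$counts - n / 10) < 3 * sigma))
  expect_error(prepare_histogram(numeric()), "empty")
})

test_that("rendering writes non-empty files for every plot kind", {
  dir <- withr::local_tempdir()
  fx <- scripted_streams()
  pupil <- data.frame(ts = fx$streams$pupil$ts,
                      diameter = 3 + 0.2 * fx$streams$pupil$ts / 1e9,
                      on_roi = TRUE)
  plots <- list(
    prepare_pupil_roi_series(pupil),
    prepare_blink_series(fx$streams$blinks, c(0, 4.8e9)),
    prepare_saccade_series(fx$streams$saccades, "velocity"),
    prepare_fixation_cloud(fx$streams$fixations$x, fx$streams$fixations$y),
    prepare_path(fx$streams$fixations$x, fx$streams$fixations$y),
    prepare_histogram(fx$streams$fixations$duration_ms)
  )
  for (i in seq_along(plots)) {
    path <- file.path(dir, sprintf("fig%d.png", i))
    render_figure(plots[[i]], path)
    expect_true(file.exists(path))
    expect_gt(file.size(path), 0)
  }
  # empty-allowed kinds render a placeholder
  expect_warning(
    p_empty <- prepare_saccade_series(fx$streams$saccades[0, ], "amplitude"),
    "no saccades")
  path <- file.path(dir, "empty.png")
  render_figure(p_empty, path)
  expect_gt(file.size(path), 0)
})

test_that("prepared arrays are identical across repeated preparation", {
  fx <- scripted_streams()
  a <- prepare_fixation_cloud(fx$streams$fixations$x,
                              fx$streams$fixations$y)
  b <- prepare_fixation_cloud(fx$streams$fixations$x,
                              fx$streams$fixations$y)
  expect_identical(a$series, b$series)
})
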