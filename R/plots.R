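# Visualisation: data preparation (testable numeric content) strictly
# separated from rendering (thin device drawing, no numeric transformation
# beyond axis mapping).  Colour semantics — green = on-ROI, red = off-ROI —
# live in the annotations, not the renderer.

new_prepared_plot <- function(kind, series, annotations = list()) {
  lens <- vapply(series, length, 0L)
  structure(list(kind = kind, series = series, annotations = annotations,
                 lengths = lens),
            class = "prepared_plot")
}

#' @export
print.prepared_plot <- function(x, ...) {
  cat(sprintf("<prepared_plot:%s> series: %s\n", x$kind,
              paste(sprintf("%s[%d]", names(x$series), x$lengths),
                    collapse = ", ")))
  invisible(x)
}

#' Prepare the ROI-coloured pupillometry trace
#'
#' The pupil diameter series with contiguous on-ROI runs labelled green and
#' off-ROI runs red; gaps where samples were dropped around blinks show up
#' as drops in the trace.
#'
#' @param pupil annotated pupil data.frame (`ts`, `diameter`, `on_roi`).
#' @return a `prepared_plot` of kind `pupil_roi_series` whose annotations
#'   carry the run segmentation (`start`, `end` sample indices, `colour`).
#' @export
prepare_pupil_roi_series <- function(pupil) {
  if (nrow(pupil) == 0L) gp_stop("plots", "empty pupil stream")
  if (is.null(pupil$on_roi)) {
    gp_stop("plots", "pupil stream is not ROI-annotated")
  }
  runs <- rle(pupil$on_roi %in% TRUE)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  segments <- data.frame(
    start = starts, end = ends,
    colour = ifelse(runs$values, "green", "red"),
    stringsAsFactors = FALSE)
  new_prepared_plot(
    "pupil_roi_series",
    series = list(t_s = (pupil$ts - pupil$ts[1]) / NS_PER_S,
                  diameter_mm = pupil$diameter),
    annotations = list(segments = segments,
                       xlab = "time [s]", ylab = "pupil diameter [mm]",
                       colour_semantics = c(green = "on ROI",
                                            red = "off ROI")))
}

#' Prepare the binary blink raster
#'
#' Step series over the span: 1 inside blink intervals, 0 elsewhere, so the
#' integral of the series equals the total blink duration.
#'
#' @param blinks blink data.frame (`start_ts`, `end_ts`), sorted.
#' @param span numeric `c(start_ts, end_ts)` in ns.
#' @return a `prepared_plot` of kind `blink_series` with the step-edge
#'   arrays (`t_s`, `value`).
#' @export
prepare_blink_series <- function(blinks, span) {
  t0 <- span[1]
  t <- c(span[1])
  v <- c(0)
  if (nrow(blinks)) {
    for (i in seq_len(nrow(blinks))) {
      t <- c(t, blinks$start_ts[i], blinks$start_ts[i],
             blinks$end_ts[i], blinks$end_ts[i])
      v <- c(v, 0, 1, 1, 0)
    }
  }
  t <- c(t, span[2])
  v <- c(v, 0)
  new_prepared_plot(
    "blink_series",
    series = list(t_s = (t - t0) / NS_PER_S, value = v),
    annotations = list(n_blinks = nrow(blinks),
                       total_duration_ms = sum(blinks$duration_ms),
                       xlab = "time [s]", ylab = "blink (1 = eyelid closed)"))
}

#' Prepare saccade velocity or amplitude series
#'
#' Velocity mode carries two series — mean and peak velocity per saccade,
#' converted to px/ms — indexed by saccade order; amplitude mode carries
#' one series in px.
#'
#' @param saccades saccade data.frame, sorted.
#' @param which `"velocity"` or `"amplitude"`.
#' @return a `prepared_plot` of kind `saccade_velocity` or
#'   `saccade_amplitude`.
#' @export
prepare_saccade_series <- function(saccades, which = c("velocity",
                                                       "amplitude")) {
  which <- match.arg(which)
  if (nrow(saccades) == 0L) {
    gp_warn("plots", "no saccades; preparing an empty saccade plot")
  }
  idx <- seq_len(nrow(saccades))
  if (which == "velocity") {
    new_prepared_plot(
      "saccade_velocity",
      series = list(index = idx,
                    mean_px_ms = saccades$mean_velocity / 1000,
                    peak_px_ms = saccades$peak_velocity / 1000),
      annotations = list(xlab = "saccade index",
                         ylab = "saccade velocity [px/ms]"))
  } else {
    new_prepared_plot(
      "saccade_amplitude",
      series = list(index = idx, amplitude_px = saccades$amplitude_px),
      annotations = list(xlab = "saccade index",
                         ylab = "saccade amplitude [px]"))
  }
}

#' Prepare the fixation point cloud with Gaussian kernel density
#'
#' Scatter of fixation (or gaze) positions plus a Gaussian kernel density
#' estimate on a square grid covering the point extent widened by three
#' kernel standard deviations, so the density integrates to ~1 by grid
#' quadrature.  The bandwidth defaults to the normal-reference (Scott-type)
#' rule per axis.
#'
#' @param x,y point coordinates (>= 2 points for the density).
#' @param bandwidth optional numeric scalar or length-2 bandwidth override
#'   (same scale as [MASS::bandwidth.nrd()]).
#' @param grid_n grid resolution per axis (default 256).
#' @param background optional path to a background image, recorded as an
#'   annotation and drawn behind the cloud at render time.
#' @return a `prepared_plot` of kind `fixation_cloud`; series carry the
#'   points and, when computable, `gx`, `gy`, `density` (column-major grid).
#' @export
prepare_fixation_cloud <- function(x, y, bandwidth = NULL, grid_n = 256,
                                   background = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (length(x) < 2L) {
    gp_warn("plots", "fewer than 2 points; scatter only, no density")
    return(new_prepared_plot(
      "fixation_cloud", series = list(x = x, y = y),
      annotations = list(density = FALSE, background = background)))
  }
  bw <- if (is.null(bandwidth)) {
    c(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y))
  } else {
    rep_len(as.numeric(bandwidth), 2L)
  }
  # degenerate spread (e.g. identical coordinates on one axis)
  bw[bw <= 0] <- max(bw, diff(range(x)), diff(range(y)), 1) * 0.05
  # kde2d's kernel sd is bandwidth/4; widen by 3 sd so the grid holds ~all mass
  pad <- 3 * bw / 4
  lims <- c(range(x) + c(-1, 1) * pad[1], range(y) + c(-1, 1) * pad[2])
  kde <- MASS::kde2d(x, y, h = bw, n = grid_n, lims = lims)
  new_prepared_plot(
    "fixation_cloud",
    series = list(x = x, y = y, gx = kde$x, gy = kde$y,
                  density = as.numeric(kde$z)),
    annotations = list(density = TRUE, grid_n = grid_n, bandwidth = bw,
                       background = background,
                       xlab = "x [px]", ylab = "y [px]"))
}

#' Prepare a scan-path polyline
#'
#' Ordered polyline through fixation centroids or movement samples, with
#' order markers; absolute mode is in scene/reference pixels, relative mode
#' in surface-normalised coordinates (all within `[0, 1]`).
#'
#' @param x,y ordered coordinates (>= 2 points).
#' @param mode `"absolute"` (px) or `"relative"` (normalised).
#' @return a `prepared_plot` of kind `path`.
#' @export
prepare_path <- function(x, y, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) gp_stop("plots", "a path needs at least 2 points")
  if (mode == "relative" && (any(x < 0 | x > 1) || any(y < 0 | y > 1))) {
    gp_stop("plots", "relative-mode coordinates must lie in [0, 1]")
  }
  seg_lengths <- sqrt(diff(x)^2 + diff(y)^2)
  new_prepared_plot(
    "path",
    series = list(x = x, y = y, order = seq_along(x)),
    annotations = list(mode = mode, total_length = sum(seg_lengths),
                       xlab = if (mode == "absolute") "x [px]" else "x [norm]",
                       ylab = if (mode == "absolute") "y [px]" else "y [norm]"))
}

#' Prepare a histogram
#'
#' Equal-width bins over the value range; counts sum to the number of
#' values.
#'
#' @param values non-empty numeric vector.
#' @param bins number of bins (default 30).
#' @param unit value unit recorded on the axis label.
#' @return a `prepared_plot` of kind `histogram` with `counts` and
#'   `edges` (length `bins + 1`).
#' @export
prepare_histogram <- function(values, bins = 30, unit = "") {
  if (length(values) == 0L) gp_stop("plots", "histogram of an empty vector")
  stopifnot(is_count(bins), bins >= 1)
  r <- range(values)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  edges <- seq(r[1], r[2], length.out = bins + 1L)
  h <- graphics::hist(values, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  new_prepared_plot(
    "histogram",
    series = list(counts = h$counts, edges = h$breaks),
    annotations = list(n = length(values),
                       xlab = if (nzchar(unit)) sprintf("value [%s]", unit)
                              else "value",
                       ylab = "count"))
}

#' Prepare a periodogram or spectrogram plot
#'
#' Wraps the output of [welch_periodogram()] or [spectrogram()] as a
#' prepared plot.
#'
#' @param spec list from [welch_periodogram()] or [spectrogram()].
#' @return a `prepared_plot` of kind `periodogram` or `spectrogram`.
#' @export
prepare_spectrum <- function(spec) {
  if (is.matrix(spec$power)) {
    new_prepared_plot(
      "spectrogram",
      series = list(freq = spec$freq, time = spec$time,
                    power = as.numeric(spec$power)),
      annotations = list(dim = dim(spec$power), xlab = "time [s]",
                         ylab = "frequency [Hz]"))
  } else {
    new_prepared_plot(
      "periodogram",
      series = list(freq = spec$freq, power = spec$power),
      annotations = list(xlab = "frequency [Hz]",
                         ylab = "power spectral density"))
  }
}

#' Render a prepared plot to a raster file
#'
#' Presentation only: draws the prepared arrays with no numeric
#' transformation beyond axis mapping.  Plots whose prepared content is
#' empty render a placeholder annotation.
#'
#' @param plot a `prepared_plot`.
#' @param path output file (PNG).
#' @param width,height device size in pixels.
#' @param dpi nominal resolution.
#' @return the path, invisibly.
#' @export
render_figure <- function(plot, path, width = 1200, height = 800,
                          dpi = 150) {
  stopifnot(inherits(plot, "prepared_plot"))
  grDevices::png(path, width = width, height = height, res = dpi)
  on.exit(grDevices::dev.off(), add = TRUE)
  s <- plot$series
  a <- plot$annotations
  empty <- length(s) == 0L || all(vapply(s, length, 0L) == 0L)
  if (empty) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, sprintf("no data for %s", plot$kind))
    return(invisible(path))
  }
  switch(plot$kind,
    pupil_roi_series = {
      graphics::plot(s$t_s, s$diameter_mm, type = "n", xlab = a$xlab,
                     ylab = a$ylab)
      for (i in seq_len(nrow(a$segments))) {
        idx <- a$segments$start[i]:a$segments$end[i]
        graphics::lines(s$t_s[idx], s$diameter_mm[idx],
                        col = a$segments$colour[i])
      }
    },
    blink_series = graphics::plot(s$t_s, s$value, type = "l",
                                  xlab = a$xlab, ylab = a$ylab),
    saccade_velocity = {
      graphics::plot(s$index, s$peak_px_ms, type = "l", col = "orange",
                     xlab = a$xlab, ylab = a$ylab,
                     ylim = range(c(s$mean_px_ms, s$peak_px_ms)))
      graphics::lines(s$index, s$mean_px_ms, col = "blue")
      graphics::legend("topright", legend = c("peak", "mean"),
                       col = c("orange", "blue"), lty = 1)
    },
    saccade_amplitude = graphics::plot(s$index, s$amplitude_px, type = "l",
                                       xlab = a$xlab, ylab = a$ylab),
    fixation_cloud = {
      if (isTRUE(a$density)) {
        z <- matrix(s$density, nrow = length(s$gx))
        graphics::image(s$gx, s$gy, z, col = grDevices::hcl.colors(64),
                        xlab = a$xlab, ylab = a$ylab)
        graphics::points(s$x, s$y, pch = 16, cex = 0.4)
      } else {
        graphics::plot(s$x, s$y, pch = 16)
      }
    },
    path = {
      graphics::plot(s$x, s$y, type = "o", pch = 16, cex = 0.6,
                     xlab = a$xlab, ylab = a$ylab)
      graphics::text(s$x[1], s$y[1], "start", pos = 3, col = "darkgreen")
    },
    histogram = {
      n_bins <- length(s$counts)
      graphics::plot(NULL, xlim = range(s$edges), ylim = c(0, max(s$counts)),
                     xlab = a$xlab, ylab = a$ylab)
      graphics::rect(s$edges[seq_len(n_bins)], 0, s$edges[-1], s$counts,
                     col = "grey70")
    },
    periodogram = graphics::plot(s$freq, s$power, type = "l",
                                 xlab = a$xlab, ylab = a$ylab),
    spectrogram = {
      z <- matrix(s$power, nrow = a$dim[1])
      graphics::image(s$time, s$freq, t(z), col = grDevices::hcl.colors(64),
                      xlab = a$xlab, ylab = a$ylab)
    },
    {
      graphics::plot.new()
      graphics::text(0.5, 0.5, sprintf("unknown plot kind %s", plot$kind))
    }
  )
  invisible(path)
}
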