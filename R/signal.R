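# Frequency-domain analysis of the pupil diameter series.
#
# The raw series is irregular (dropped samples around blinks), so spectra
# are computed after linear resampling onto a uniform grid; gaps longer
# than 1 s are interpolated through but flagged, and the gap fraction is
# reported so spectral estimates over heavily interrupted stretches can be
# discounted.

#' Resample an irregular series onto a uniform grid
#'
#' Linear interpolation onto `rate` Hz spanning the input series.  Gaps
#' between consecutive input samples longer than `gap_flag_s` are filled by
#' the interpolant but reported in the `gaps` element.
#'
#' @param ts timestamps in nanoseconds (ascending, length >= 2).
#' @param values sample values.
#' @param rate target rate in Hz; the default 200 Hz matches the nominal
#'   device rate.
#' @param gap_flag_s gap-length threshold for flagging (seconds).
#' @return list `t` (seconds from series start), `value`, `rate`,
#'   `gaps` (data.frame `start_s`, `length_s`), `gap_fraction` (flagged gap
#'   time over total span).
#' @export
resample_uniform <- function(ts, values, rate = 200, gap_flag_s = 1) {
  stopifnot(rate > 0)
  ok <- !is.na(ts) & !is.na(values)
  ts <- ts[ok]
  values <- values[ok]
  if (length(ts) < 2L) {
    gp_stop("signal", "resampling needs at least 2 finite samples")
  }
  t_s <- (ts - ts[1]) / NS_PER_S
  grid <- seq(0, t_s[length(t_s)], by = 1 / rate)
  out <- stats::approx(t_s, values, xout = grid, method = "linear",
                       ties = "ordered")$y
  dt <- diff(t_s)
  gap_idx <- which(dt > gap_flag_s)
  gaps <- data.frame(start_s = t_s[gap_idx], length_s = dt[gap_idx])
  list(t = grid, value = out, rate = rate, gaps = gaps,
       gap_fraction = if (length(dt)) sum(dt[gap_idx]) / sum(dt) else 0)
}

gp_window <- function(window, n) {
  if (is.numeric(window)) {
    stopifnot(length(window) == n)
    return(window)
  }
  switch(match.arg(window, c("hann", "hamming", "rectangular")),
    hann = as.numeric(signal::hanning(n)),
    hamming = as.numeric(signal::hamming(n)),
    rectangular = rep(1, n)
  )
}

# Segment starts for Welch-style averaging.
segment_starts <- function(n, segment_length, overlap) {
  hop <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  starts <- seq(1L, n - segment_length + 1L, by = hop)
  list(starts = starts, hop = hop)
}

# One-sided modified periodogram of one segment, density scaling.
segment_psd <- function(x, w, rate, detrend) {
  if (detrend) x <- x - mean(x)
  X <- stats::fft(x * w)
  n <- length(x)
  half <- seq_len(n %/% 2 + 1L)
  p <- (Mod(X[half])^2) / (rate * sum(w^2))
  # fold the negative frequencies into the one-sided density
  interior <- 2:(length(half) - if (n %% 2 == 0L) 1L else 0L)
  p[interior] <- 2 * p[interior]
  p
}

#' Welch periodogram
#'
#' Averaged modified periodogram: the series is cut into tapered,
#' overlapping segments, each mean-detrended, windowed and transformed, and
#' the one-sided power spectral densities are averaged.  Frequencies run
#' from 0 to `rate/2`; the density integrates (sum times bin width) to the
#' series variance for stationary input.
#'
#' @param x uniform series (numeric), or the list returned by
#'   [resample_uniform()].
#' @param rate sampling rate in Hz (taken from the resampled list when
#'   given).
#' @param segment_length samples per segment (default 256).
#' @param overlap fractional segment overlap in `[0, 1)` (default 0.5).
#' @param window `"hann"` (default), `"hamming"`, `"rectangular"`, or a
#'   numeric taper of length `segment_length`.
#' @param detrend remove each segment's mean before tapering (default TRUE).
#' @return list `freq` (Hz), `power` (density, unit^2/Hz), `n_segments`.
#' @export
welch_periodogram <- function(x, rate = 200, segment_length = 256,
                              overlap = 0.5, window = "hann",
                              detrend = TRUE) {
  if (is.list(x)) {
    rate <- x$rate
    x <- x$value
  }
  n <- length(x)
  if (n < segment_length) {
    gp_stop("signal", sprintf(
      "series of %d samples is shorter than one segment (%d); lower segment_length or record longer",
      n, segment_length))
  }
  w <- gp_window(window, segment_length)
  seg <- segment_starts(n, segment_length, overlap)
  acc <- 0
  for (s in seg$starts) {
    acc <- acc + segment_psd(x[s:(s + segment_length - 1L)], w, rate, detrend)
  }
  list(freq = (seq_len(segment_length %/% 2 + 1L) - 1L) *
         rate / segment_length,
       power = acc / length(seg$starts),
       n_segments = length(seg$starts))
}

#' Short-time spectrogram
#'
#' Power spectral density on a sliding window: the same per-segment
#' estimator as [welch_periodogram()], kept per segment instead of
#' averaged.  Columns are segments; the time axis is the segment centre in
#' seconds from series start.
#'
#' @inheritParams welch_periodogram
#' @return list `freq` (Hz), `time` (s, segment centres), `power` (matrix,
#'   frequency x time).
#' @export
spectrogram <- function(x, rate = 200, segment_length = 256, overlap = 0.5,
                        window = "hann", detrend = TRUE) {
  if (is.list(x)) {
    rate <- x$rate
    x <- x$value
  }
  n <- length(x)
  if (n < segment_length) {
    gp_stop("signal", sprintf(
      "series of %d samples is shorter than one segment (%d)", n,
      segment_length))
  }
  w <- gp_window(window, segment_length)
  seg <- segment_starts(n, segment_length, overlap)
  mat <- vapply(seg$starts, function(s) {
    segment_psd(x[s:(s + segment_length - 1L)], w, rate, detrend)
  }, numeric(segment_length %/% 2 + 1L))
  list(freq = (seq_len(segment_length %/% 2 + 1L) - 1L) *
         rate / segment_length,
       time = (seg$starts - 1L + segment_length / 2) / rate,
       power = mat)
}
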