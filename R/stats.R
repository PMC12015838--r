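# Elementary statistics used throughout the feature battery.

#' Tag a 2-D point with its coordinate unit
#'
#' @param x,y coordinates.
#' @param unit coordinate tag, e.g. `"px"` (scene/reference-image pixels) or
#'   `"norm"` (surface-normalised units).
#' @return numeric `c(x, y)` carrying a `unit` attribute.
#' @export
point2d <- function(x, y, unit = "px") {
  stopifnot(is.finite(x), is.finite(y))
  structure(c(x = x, y = y), unit = unit)
}

#' Euclidean distance between two points
#'
#' `sqrt((x2 - x1)^2 + (y2 - y1)^2)`.  Points tagged with different
#' coordinate units (pixels vs surface-normalised) must not be mixed.
#'
#' @param p1,p2 numeric `c(x, y)`, optionally tagged via [point2d()].
#' @return the distance, in the points' unit.
#' @export
euclidean_distance <- function(p1, p2) {
  u1 <- attr(p1, "unit")
  u2 <- attr(p2, "unit")
  if (!is.null(u1) && !is.null(u2) && !identical(u1, u2)) {
    gp_stop("stats", sprintf("mixed coordinate units: '%s' vs '%s'", u1, u2))
  }
  sqrt((p2[[1]] - p1[[1]])^2 + (p2[[2]] - p1[[2]])^2)
}

#' Descriptive statistics of a value list
#'
#' The six summary quantities used by every feature category: maximum,
#' minimum, total, count, mean, and the population standard deviation
#' (divisor = count, not count - 1).
#'
#' @param values non-empty numeric vector.
#' @return list `maximum`, `minimum`, `total`, `count`, `mean`, `std`.
#' @export
descriptive_stats <- function(values) {
  if (length(values) == 0L) gp_stop("stats", "descriptive_stats on empty list")
  stopifnot(all(is.finite(values)))
  m <- mean(values)
  list(
    maximum = max(values),
    minimum = min(values),
    total = sum(values),
    count = length(values),
    mean = m,
    std = sqrt(mean((values - m)^2))
  )
}

#' Independent two-sample t-test
#'
#' Student's pooled-variance statistic by default, with a Welch
#' unequal-variance option; p is two-tailed.  Degenerate identical
#' zero-variance groups return t = 0, p = 1 rather than NaN.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pool the variances (default TRUE).
#' @return list `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    df <- if (var_equal) length(a) + length(b) - 2 else NA_real_
    return(list(t = 0, df = df, p = 1))
  }
  fit <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}
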