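# Internal helpers shared across the pipeline.

#' Stage-tagged log line
#'
#' Line-oriented logging used by the pipeline; quiet unless the session opts
#' in via `options(gazeproc.verbose = TRUE)`.
#' @noRd
gp_log <- function(stage, ...) {
  if (isTRUE(getOption("gazeproc.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  invisible(NULL)
}

gp_warn <- function(stage, ...) {
  warning(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

gp_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

#' Convert seconds to integer nanoseconds
#' @noRd
s_to_ns <- function(s) round(s * NS_PER_S)

#' Milliseconds from a nanosecond interval
#' @noRd
ns_to_ms <- function(ns) ns / NS_PER_MS

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' Sanitise a participant code into a filesystem-safe filename prefix.
#' The original code is preserved inside reports; only filenames use this.
#' @noRd
sanitize_participant <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  out <- gsub("[^A-Za-z0-9._-]+", "-", code)
  out <- gsub("^-+|-+$", "", out)
  if (!nzchar(out)) out <- "participant"
  out
}

#' Stable order by timestamp (ties keep file order).
#' @noRd
order_by_ts <- function(ts) order(ts, seq_along(ts))
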