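#' Construct a recording
#'
#' A recording is a set of named channels sampled uniformly on a shared time
#' base. Sample `i` (1-based) is located at `start_offset + (i - 1) / rate`
#' seconds on the global clock, and all windows in the package follow the
#' half-open convention `[start, end)`.
#'
#' @param channels named list of equal-length numeric vectors (missing values
#'   allowed; they propagate through transforms).
#' @param rate sampling rate in Hz, strictly positive.
#' @param start_offset global clock time of the first sample, seconds.
#' @param name dataset name used in event tables and exports.
#' @param provenance character vector logging applied transforms.
#' @return an object of class `fp_recording`.
#' @export
fp_recording <- function(channels, rate, start_offset = 0, name = "recording",
                         provenance = character()) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list of numeric vectors")
  nm <- names(channels)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every channel must be named")
  if (anyDuplicated(nm))
    stop("duplicate channel names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  lens <- lengths(channels)
  if (length(unique(lens)) != 1L)
    stop("all channels must have the same length (got ",
         paste(lens, collapse = ", "), ")")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  channels <- lapply(channels, as.double)
  structure(
    list(name = as.character(name), start_offset = as.double(start_offset),
         rate = as.double(rate), channels = channels,
         provenance = as.character(provenance)),
    class = "fp_recording")
}

#' @export
print.fp_recording <- function(x, ...) {
  n <- n_samples(x)
  cat(sprintf("<fp_recording> %s: %d samples @ %g Hz, t = [%g, %g) s\n",
              x$name, n, x$rate, x$start_offset, recording_end(x)))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (length(x$provenance))
    cat("  provenance:", length(x$provenance), "step(s)\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `fp_recording`.
#' @export
n_samples <- function(rec) length(rec$channels[[1L]])

#' End of the recording span (half-open), seconds
#'
#' The span of a recording is `[start_offset, start_offset + n / rate)`: the
#' last sample "owns" one sampling period.
#' @param rec an `fp_recording`.
#' @export
recording_end <- function(rec) rec$start_offset + n_samples(rec) / rec$rate

#' Time axis of a recording
#'
#' @param rec an `fp_recording`.
#' @return numeric vector of length `n_samples(rec)`; element `i` equals
#'   `start_offset + (i - 1) / rate`.
#' @export
time_axis <- function(rec) {
  rec$start_offset + (seq_len(n_samples(rec)) - 1L) / rec$rate
}

get_channel <- function(rec, channel) {
  if (!channel %in% names(rec$channels))
    stop("unknown channel '", channel, "' in recording '", rec$name,
         "' (have: ", paste(names(rec$channels), collapse = ", "), ")")
  rec$channels[[channel]]
}

#' Extract a half-open time slice of one channel
#'
#' @param rec an `fp_recording`.
#' @param channel channel name.
#' @param start,end slice bounds in seconds; samples with
#'   `start <= t < end` are returned. An empty slice is allowed.
#' @return list with components `times` and `values`.
#' @export
slice_channel <- function(rec, channel, start, end) {
  if (start >= end) stop("`start` must be < `end`")
  x <- get_channel(rec, channel)
  tt <- time_axis(rec)
  keep <- tt >= start & tt < end
  list(times = tt[keep], values = x[keep])
}

#' Trapezoidal area under a curve
#'
#' @param times strictly increasing sample times, seconds.
#' @param values numeric values at `times`.
#' @return the trapezoidal integral, in value-seconds.
#' @export
trapezoid_auc <- function(times, values) {
  n <- length(times)
  if (n < 2L) stop("trapezoid_auc needs at least 2 samples, got ", n)
  if (length(values) != n) stop("`times` and `values` lengths differ")
  dt <- diff(times)
  if (any(dt <= 0)) stop("`times` must be strictly increasing")
  sum(dt * (values[-n] + values[-1L]) / 2)
}

# indices of samples whose time falls in [start, end)
span_indices <- function(rec, start, end) {
  tt <- time_axis(rec)
  which(tt >= start & tt < end)
}

add_provenance <- function(rec, msg) {
  rec$provenance <- c(rec$provenance, msg)
  rec
}
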