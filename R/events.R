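#' Event series
#'
#' An ordered list of half-open events `[start, end)` in seconds, together
#' with the definition that produced them and the span of the recording they
#' were detected on (used to clip shifted or padded events).
#'
#' @param events data.frame with numeric columns `start` and `end`.
#' @param definition free-text description of detector/conditions/filters.
#' @param dataset name of the source recording.
#' @param span numeric length-2 `[start, end)` span of the source recording.
#' @param source_label label stored per event (defaults to `definition`).
#' @return an object of class `fp_events`.
#' @export
fp_events <- function(events, definition = "", dataset = "", span = c(-Inf, Inf),
                      source_label = definition) {
  events <- as.data.frame(events)
  if (nrow(events) == 0L)
    events <- data.frame(start = numeric(), end = numeric())
  if (is.unsorted(events$start)) events <- events[order(events$start), , drop = FALSE]
  events$index <- seq_len(nrow(events))
  events$source_label <- rep_len(if (nrow(events)) source_label else character(), nrow(events))
  rownames(events) <- NULL
  structure(list(events = events[, c("start", "end", "index", "source_label")],
                 definition = definition, dataset = dataset,
                 span = as.double(span)),
            class = "fp_events")
}

#' @export
print.fp_events <- function(x, ...) {
  cat(sprintf("<fp_events> %d event(s) on '%s'\n", nrow(x$events), x$dataset))
  if (nzchar(x$definition)) cat("  definition:", x$definition, "\n")
  if (nrow(x$events)) print(utils::head(x$events, 10L))
  invisible(x)
}

#' Number of events in a series
#' @param series an `fp_events`.
#' @export
n_events <- function(series) nrow(series$events)

reindex <- function(series) {
  ev <- series$events
  ev <- ev[order(ev$start), , drop = FALSE]
  ev$index <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  series$events <- ev
  series
}

#' Detect events from a binary indicator channel
#'
#' One event per maximal run of ones: each event begins at a rising edge
#' (0 to 1) and extends to the following falling edge (1 to 0), half-open on
#' the sample grid. A run reaching the final sample closes at the recording
#' end. With `inverted = TRUE` the logical complement of the channel is used.
#'
#' @param rec an `fp_recording`.
#' @param variable binary channel name (non-zero values count as 1, with a
#'   warning if any value is neither 0 nor 1; missing counts as 0).
#' @param inverted detect runs of zeros instead.
#' @return an `fp_events`.
#' @export
detect_binary <- function(rec, variable, inverted = FALSE) {
  x <- get_channel(rec, variable)
  if (any(!x %in% c(0, 1), na.rm = TRUE))
    warning("channel '", variable, "' is not strictly 0/1; non-zero values treated as 1")
  b <- !is.na(x) & x != 0
  if (inverted) b <- !b
  tt <- time_axis(rec)
  r <- rle(b)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  on <- which(r$values)
  ev <- data.frame(
    start = tt[starts_idx[on]],
    end = ifelse(ends_idx[on] < length(b), tt[ends_idx[on] + 1L], recording_end(rec)))
  fp_events(ev,
            definition = sprintf("binary%s runs of '%s'",
                                 if (inverted) " (inverted)" else "", variable),
            dataset = rec$name, span = c(rec$start_offset, recording_end(rec)))
}

#' Detect equally sized binned events
#'
#' Starting at time `t`, each successive interval of length `L` is one event:
#' `[t, t+L), [t+L, t+2L), ...`; a trailing partial bin is dropped.
#'
#' @param rec an `fp_recording`.
#' @param t start time, seconds (within the recording span).
#' @param L bin length, seconds (> 0).
#' @return an `fp_events`.
#' @export
detect_binned <- function(rec, t, L) {
  if (L <= 0) stop("bin length `L` must be > 0")
  end <- recording_end(rec)
  if (t < rec$start_offset) stop("`t` is before the recording starts")
  nbins <- max(0L, floor((end - t) / L + 1e-12))
  starts <- t + (seq_len(nbins) - 1L) * L
  fp_events(data.frame(start = starts, end = starts + L),
            definition = sprintf("bins of %g s from t = %g s", L, t),
            dataset = rec$name, span = c(rec$start_offset, end))
}

#' Detect peak events with a moving-window threshold
#'
#' Flags samples exceeding the mean of a trailing window (the last `L`
#' seconds up to and including the current sample) by more than `k` standard
#' deviations (sample SD, n-1); maximal runs of flagged samples become
#' events. Early samples use the available partial window, requiring at
#' least 2 samples; a zero-variance window flags nothing.
#'
#' @param rec an `fp_recording`.
#' @param variable continuous channel name.
#' @param L window length, seconds (at least 2 sampling periods).
#' @param k threshold in standard deviations (> 0).
#' @return an `fp_events`.
#' @export
detect_peaks <- function(rec, variable, L, k) {
  if (k <= 0) stop("`k` must be > 0")
  w <- round(L * rec$rate)
  if (w < 2) stop("window `L` must cover at least 2 samples")
  x <- get_channel(rec, variable)
  n <- length(x)
  # cumulative sums for trailing-window mean/SD (window: max(1, i-w+1)..i)
  cs <- cumsum(ifelse(is.na(x), 0, x))
  cs2 <- cumsum(ifelse(is.na(x), 0, x^2))
  cn <- cumsum(!is.na(x))
  i <- seq_len(n)
  lo <- pmax(i - w, 0L)
  at <- function(v) ifelse(lo > 0, v[pmax(lo, 1L)], 0)  # prefix sum before window
  m <- cn[i] - at(cn)
  s1 <- cs[i] - at(cs)
  s2 <- cs2[i] - at(cs2)
  mu <- s1 / m
  varr <- pmax((s2 - s1^2 / m) / (m - 1), 0)
  sdv <- sqrt(varr)
  flag <- m >= 2 & !is.na(x) & sdv > 0 & x > mu + k * sdv
  tt <- time_axis(rec)
  r <- rle(as.vector(flag))
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  on <- which(r$values)
  ev <- data.frame(
    start = tt[starts_idx[on]],
    end = ifelse(ends_idx[on] < n, tt[ends_idx[on] + 1L], recording_end(rec)))
  fp_events(ev,
            definition = sprintf("peaks of '%s' > mean + %g SD over trailing %g s",
                                 variable, k, L),
            dataset = rec$name, span = c(rec$start_offset, recording_end(rec)))
}

#' Events from a manual list of timestamps
#'
#' @param rec an `fp_recording`.
#' @param stamps data.frame with columns `start` and `end` (seconds), sorted,
#'   `end > start`. Events overhanging the recording are clipped; events
#'   entirely outside are dropped with a warning.
#' @return an `fp_events`.
#' @export
detect_timestamped <- function(rec, stamps) {
  stamps <- as.data.frame(stamps)
  if (nrow(stamps) && any(stamps$end <= stamps$start))
    stop("every timestamp must satisfy end > start")
  if (nrow(stamps) && is.unsorted(stamps$start))
    stop("timestamps must be sorted by start")
  lo <- rec$start_offset; hi <- recording_end(rec)
  keep <- stamps$end > lo & stamps$start < hi
  if (any(!keep))
    warning(sum(!keep), " timestamp(s) entirely outside the recording span dropped")
  st <- pmax(stamps$start[keep], lo)
  en <- pmin(stamps$end[keep], hi)
  fp_events(data.frame(start = st, end = en),
            definition = "manual timestamps", dataset = rec$name,
            span = c(lo, hi))
}

# ---- conditions --------------------------------------------------------

cond_allowed_calls <- c("+", "-", "*", "/", "^", "%%", "%/%",
                        "<", ">", "<=", ">=", "==", "!=",
                        "&", "|", "!", "&&", "||", "(",
                        "abs", "exp", "log", "log2", "log10", "sqrt",
                        "is.na", "c", "T", "F")

check_cond_ast <- function(e, known) {
  if (is.atomic(e)) return(invisible(TRUE))
  if (is.name(e)) {
    nm <- as.character(e)
    if (!nm %in% c(known, "time", "T", "F", "TRUE", "FALSE"))
      stop("unknown identifier '", nm, "' in condition (channels: ",
           paste(known, collapse = ", "), ")")
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1L]])
    if (!fn %in% cond_allowed_calls)
      stop("function '", fn, "' is not allowed in condition expressions")
    for (a in as.list(e)[-1L]) check_cond_ast(a, known)
    return(invisible(TRUE))
  }
  stop("unsupported construct in condition expression")
}

#' Keep events satisfying a per-sample condition
#'
#' Evaluates a boolean expression over the recording's channels at every time
#' step (channels are visible by name; `(time)` or `time` gives the time axis
#' in seconds). In `"entire"` mode an event is kept only if every sample it
#' covers satisfies the predicate; in `"any"` mode one satisfying sample
#' suffices. Only comparisons, arithmetic, and/or/not and a few elementary
#' functions are allowed in the expression.
#'
#' @param series an `fp_events`.
#' @param rec the source `fp_recording`.
#' @param expression condition as text, e.g. `"(time) < 360 & cue == 1"`.
#' @param mode `"entire"` or `"any"`.
#' @return the filtered `fp_events`.
#' @export
apply_condition <- function(series, rec, expression, mode = c("entire", "any")) {
  mode <- match.arg(mode)
  expr <- str2lang(expression)
  check_cond_ast(expr, names(rec$channels))
  env <- list2env(rec$channels, parent = baseenv())
  assign("time", time_axis(rec), envir = env)
  mask <- eval(expr, env)
  if (!is.logical(mask)) mask <- as.logical(mask)
  mask <- rep_len(mask, n_samples(rec))
  mask[is.na(mask)] <- FALSE
  tt <- time_axis(rec)
  keep <- vapply(seq_len(n_events(series)), function(i) {
    sel <- tt >= series$events$start[i] & tt < series$events$end[i]
    if (!any(sel)) return(mode == "entire")
    if (mode == "entire") all(mask[sel]) else any(mask[sel])
  }, logical(1))
  series$events <- series$events[keep, , drop = FALSE]
  series$definition <- paste0(series$definition, sprintf(" | condition [%s] %s",
                                                         mode, expression))
  reindex(series)
}

# ---- filters -----------------------------------------------------------

#' Construct one event-filter step
#'
#' Filters successively modify the list of potential events; they are applied
#' strictly in the order given to [apply_filters()]. Available kinds and
#' their parameters:
#' \describe{
#'   \item{first_last}{`which` ("first"/"last"), `action` ("drop"/"keep"):
#'     drop, or keep only, the first or last event.}
#'   \item{shift}{`delta` seconds added to both boundaries; results are
#'     clipped to the recording span.}
#'   \item{pad_min}{`min_length`: events shorter than this are extended at
#'     the end to reach it (onset is the meaningful anchor).}
#'   \item{truncate_max}{`max_length`: ends are cut to `start + max_length`.}
#'   \item{drop_short}{`min_length`: remove events with length below it.}
#'   \item{drop_long}{`max_length`: remove events with length above it.}
#'   \item{aggregate}{`gap`: merge consecutive events whose gap
#'     (next start minus previous end) is at most `gap` seconds; a zero gap
#'     (touching events) merges.}
#'   \item{coalesce}{merge overlapping events (no parameters).}
#'   \item{min_rate}{`count`, `window`: keep events having at least `count`
#'     events (including themselves) whose starts lie within a window of
#'     `window` seconds centred on their own start.}
#'   \item{before_after}{`timestamp`, `side` ("before": start < timestamp;
#'     "after": start >= timestamp), `action` ("keep"/"drop") on the selected
#'     events.}
#'   \item{debounce}{`separation`: scanning chronologically, drop any event
#'     whose start is less than `separation` seconds after the previous
#'     *kept* event's start.}
#' }
#'
#' @param kind one of the eleven kinds above.
#' @param ... kind-specific parameters.
#' @return a list of class `fp_filter_step`.
#' @export
filter_step <- function(kind, ...) {
  kinds <- c("first_last", "shift", "pad_min", "truncate_max", "drop_short",
             "drop_long", "aggregate", "coalesce", "min_rate", "before_after",
             "debounce")
  kind <- match.arg(kind, kinds)
  p <- list(...)
  dur <- intersect(names(p), c("min_length", "max_length", "gap", "window",
                               "separation"))
  for (d in dur) if (p[[d]] < 0) stop("filter parameter `", d, "` must be non-negative")
  structure(c(list(kind = kind), p), class = "fp_filter_step")
}

merge_runs <- function(ev, joinable) {
  # joinable[i]: event i+1 merges into the growing run ending at event i
  if (nrow(ev) < 2L) return(ev)
  grp <- cumsum(c(TRUE, !joinable))
  data.frame(start = tapply(ev$start, grp, min),
             end = tapply(ev$end, grp, max),
             row.names = NULL)
}

apply_one_filter <- function(ev, step, span) {
  k <- step$kind
  if (nrow(ev) == 0L && k != "first_last") return(ev)
  if (k == "first_last") {
    if (nrow(ev) == 0L) return(ev)
    i <- if (step$which == "first") 1L else nrow(ev)
    if (step$action == "drop") ev[-i, , drop = FALSE] else ev[i, , drop = FALSE]
  } else if (k == "shift") {
    ev$start <- ev$start + step$delta
    ev$end <- ev$end + step$delta
    ev$start <- pmax(ev$start, span[1]); ev$end <- pmin(ev$end, span[2])
    ev[ev$end > ev$start, , drop = FALSE]
  } else if (k == "pad_min") {
    len <- ev$end - ev$start
    ev$end <- ifelse(len < step$min_length, ev$start + step$min_length, ev$end)
    ev$end <- pmin(ev$end, span[2])
    ev
  } else if (k == "truncate_max") {
    ev$end <- pmin(ev$end, ev$start + step$max_length)
    ev
  } else if (k == "drop_short") {
    ev[ev$end - ev$start >= step$min_length, , drop = FALSE]
  } else if (k == "drop_long") {
    ev[ev$end - ev$start <= step$max_length, , drop = FALSE]
  } else if (k == "aggregate") {
    runmax <- cummax(ev$end)
    gaps <- ev$start[-1L] - runmax[-nrow(ev)]
    merge_runs(ev, gaps <= step$gap)
  } else if (k == "coalesce") {
    runmax <- cummax(ev$end)
    merge_runs(ev, ev$start[-1L] < runmax[-nrow(ev)])
  } else if (k == "min_rate") {
    half <- step$window / 2
    cnt <- vapply(ev$start, function(s) sum(abs(ev$start - s) <= half), integer(1))
    ev[cnt >= step$count, , drop = FALSE]
  } else if (k == "before_after") {
    sel <- if (step$side == "before") ev$start < step$timestamp
           else ev$start >= step$timestamp
    keep <- if (step$action == "keep") sel else !sel
    ev[keep, , drop = FALSE]
  } else if (k == "debounce") {
    keep <- logical(nrow(ev))
    last <- -Inf
    for (i in seq_len(nrow(ev))) {
      if (ev$start[i] - last >= step$separation) {
        keep[i] <- TRUE
        last <- ev$start[i]
      }
    }
    ev[keep, , drop = FALSE]
  } else stop("unknown filter kind '", k, "'")
}

#' Apply an ordered chain of event filters
#'
#' @param series an `fp_events`.
#' @param steps list of [filter_step()] objects, applied strictly in order.
#' @return the filtered `fp_events`; per-step event counts are appended to
#'   the series definition.
#' @export
apply_filters <- function(series, steps) {
  if (inherits(steps, "fp_filter_step")) steps <- list(steps)
  ev <- series$events
  for (step in steps) {
    stopifnot(inherits(step, "fp_filter_step"))
    ev <- apply_one_filter(ev[, c("start", "end"), drop = FALSE], step, series$span)
    ev <- ev[order(ev$start), , drop = FALSE]
    series$definition <- paste0(series$definition,
                                sprintf(" | %s -> %d", step$kind, nrow(ev)))
  }
  series$events <- data.frame(start = ev$start, end = ev$end,
                              index = seq_len(nrow(ev)),
                              source_label = rep_len(series$definition, nrow(ev)))
  reindex(series)
}

# ---- intervals ---------------------------------------------------------

#' Define a named peri-event interval
#'
#' @param name unique interval name (e.g. `"baseline"`, `"response"`).
#' @param reference anchor: `"event_start"`, `"event_end"`, `"event_signal"`
#'   (the raw event itself, offsets ignored) or `"event_start_no_overlap"`
#'   (anchored at the start, but the interval start is raised so it never
#'   overlaps preceding events or their intervals).
#' @param start_off,end_off offsets from the anchor, seconds
#'   (`end_off > start_off`); ignored for `"event_signal"`.
#' @return a list of class `fp_interval`.
#' @export
interval_spec <- function(name, reference = c("event_start", "event_end",
                                              "event_signal",
                                              "event_start_no_overlap"),
                          start_off = 0, end_off = 0) {
  reference <- match.arg(reference)
  if (reference != "event_signal" && end_off <= start_off)
    stop("interval '", name, "': end_off must be > start_off")
  structure(list(name = name, reference = reference,
                 start_off = start_off, end_off = end_off),
            class = "fp_interval")
}

#' Materialize per-event interval samples into an event table
#'
#' For every event and every interval, collects the recording samples whose
#' times fall in the half-open interval window, producing the long-format
#' table all downstream products consume. Windows are clipped to the
#' recording span (clips logged in the `"log"` attribute).
#'
#' @param series an `fp_events`.
#' @param intervals list of [interval_spec()]s with unique names.
#' @param rec the source `fp_recording`.
#' @param channel channel whose raw values populate the table.
#' @return an `fp_event_table` data.frame with columns `dataset`, `series`,
#'   `event`, `interval`, `t_dataset` (recording clock), `t_event` (relative
#'   to the event-signal start), `t_interval` (within the interval) and
#'   `value`.
#' @export
resolve_intervals <- function(series, intervals, rec, channel) {
  if (inherits(intervals, "fp_interval")) intervals <- list(intervals)
  nms <- vapply(intervals, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("interval names must be unique: ", paste(nms[duplicated(nms)], collapse = ", "))
  x <- get_channel(rec, channel)
  tt <- time_axis(rec)
  lo <- rec$start_offset; hi <- recording_end(rec)
  log <- character()
  rows <- list()
  bound <- -Inf   # latest time claimed by preceding events / their intervals
  for (i in seq_len(n_events(series))) {
    e <- series$events[i, ]
    ev_claim <- e$end
    for (iv in intervals) {
      if (iv$reference == "event_signal") {
        ws <- e$start; we <- e$end
      } else {
        anchor <- if (iv$reference == "event_end") e$end else e$start
        ws <- anchor + iv$start_off
        we <- anchor + iv$end_off
        if (iv$reference == "event_start_no_overlap") ws <- max(ws, bound)
      }
      cs <- max(ws, lo); ce <- min(we, hi)
      if (cs > ws || ce < we)
        log <- c(log, sprintf("event %d interval '%s' clipped to [%g, %g)",
                              e$index, iv$name, cs, ce))
      sel <- which(tt >= cs & tt < ce)
      if (length(sel) == 0L) {
        log <- c(log, sprintf("event %d interval '%s' is empty", e$index, iv$name))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = rec$name, series = series$definition, event = e$index,
        interval = iv$name, t_dataset = tt[sel], t_event = tt[sel] - e$start,
        t_interval = tt[sel] - cs, value = x[sel])
      ev_claim <- max(ev_claim, ce)
    }
    bound <- max(bound, ev_claim)
  }
  tbl <- if (length(rows)) do.call(rbind, rows)
         else data.frame(dataset = character(), series = character(),
                         event = integer(), interval = character(),
                         t_dataset = numeric(), t_event = numeric(),
                         t_interval = numeric(), value = numeric())
  attr(tbl, "log") <- log
  attr(tbl, "intervals") <- nms
  class(tbl) <- c("fp_event_table", "data.frame")
  tbl
}
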