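#' Normalization specification
#'
#' @param scheme `"zscore"`, `"dff"` or `"robust_z"`.
#' @param reference name of the interval used as the reference period
#'   (must exist in the event table, with >= 2 samples per event).
#' @param percent report dff as percent (x100).
#' @param robust_on_raw robust_z variant: centre/scale the raw values by the
#'   reference median/MAD instead of percent changes (see Details).
#' @param mad_constant scale constant for the MAD; the default 1 is the plain
#'   median absolute deviation, 1.4826 rescales it to a normal SD.
#'
#' @details The three schemes, per event, with reference samples `ref`:
#' \describe{
#'   \item{zscore}{`(x - mean(ref)) / sd(ref)` (sample SD, n-1). Suited to
#'     normally distributed, uncorrelated observations.}
#'   \item{dff}{`(x - mean(ref)) / mean(ref)`: the fractional (or percent)
#'     change in intensity relative to the reference period — the z-score
#'     with the SD replaced by the mean. Sensitive to large values.}
#'   \item{robust_z}{first the percent change `p(x) = (x - median(ref)) /
#'     median(ref)`, then `(p(x) - median(p(ref))) / MAD(p(ref))` — an
#'     outlier-resistant z-score built from medians. With
#'     `robust_on_raw = TRUE` the variant `(x - median(ref)) / MAD(ref)` is
#'     used instead.}
#' }
#' @return a list of class `fp_norm`.
#' @export
norm_spec <- function(scheme = c("zscore", "dff", "robust_z"),
                      reference = "baseline", percent = FALSE,
                      robust_on_raw = FALSE, mad_constant = 1) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, reference = reference, percent = percent,
                 robust_on_raw = robust_on_raw, mad_constant = mad_constant),
            class = "fp_norm")
}

#' Normalize values against reference samples
#'
#' The per-event workhorse behind [normalize_events()]; see [norm_spec()] for
#' the formulas.
#'
#' @param x numeric values to normalize.
#' @param ref reference-period samples (>= 2 non-missing).
#' @param spec an `fp_norm`.
#' @param context label used in error messages (event id etc.).
#' @return normalized numeric vector.
#' @export
normalize_values <- function(x, ref, spec, context = "") {
  ref <- ref[!is.na(ref)]
  fail <- function(msg) stop(spec$scheme, " normalization", context, ": ", msg)
  if (length(ref) < 2L) fail("reference interval has < 2 samples")
  if (spec$scheme == "zscore") {
    s <- stats::sd(ref)
    if (s == 0) fail("reference SD is 0")
    (x - mean(ref)) / s
  } else if (spec$scheme == "dff") {
    m <- mean(ref)
    if (m == 0) fail("reference mean is 0")
    out <- (x - m) / m
    if (spec$percent) out * 100 else out
  } else {                                   # robust_z
    med <- stats::median(ref)
    if (spec$robust_on_raw) {
      md <- stats::mad(ref, constant = spec$mad_constant)
      if (md == 0) fail("reference MAD is 0")
      (x - med) / md
    } else {
      if (med == 0) fail("reference median is 0")
      p <- (x - med) / med
      pref <- (ref - med) / med
      md <- stats::mad(pref, constant = spec$mad_constant)
      if (md == 0) fail("reference MAD is 0")
      (p - stats::median(pref)) / md
    }
  }
}

#' Add normalized value columns to an event table
#'
#' Each event is normalized against its own reference-interval samples; a new
#' column per scheme is appended (named after the scheme, or `names(specs)`).
#'
#' @param tbl an `fp_event_table` from [resolve_intervals()].
#' @param specs an `fp_norm` or named list of them.
#' @return the table with one extra column per normalization.
#' @export
normalize_events <- function(tbl, specs) {
  if (inherits(specs, "fp_norm")) specs <- stats::setNames(list(specs), specs$scheme)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, character(1), "scheme")
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    out <- rep(NA_real_, nrow(tbl))
    for (ev in unique(tbl$event)) {
      sel <- tbl$event == ev
      ref <- tbl$value[sel & tbl$interval == spec$reference]
      if (length(ref) == 0L)
        stop("event ", ev, ": reference interval '", spec$reference,
             "' not present in the table")
      out[sel] <- normalize_values(tbl$value[sel], ref, spec,
                                   context = paste0(" (event ", ev, ")"))
    }
    tbl[[nm]] <- out
  }
  tbl
}

grid_key <- function(t_event, rate) as.integer(round(t_event * rate))

#' Aligned per-event traces
#'
#' Re-indexes every event's samples so the event signal starts at
#' `t_event = 0` (pre-event intervals carry negative times) and lays events
#' out as columns on the common peri-event time grid.
#'
#' @param tbl an `fp_event_table` (normalized or raw).
#' @param value name of the value column to align (e.g. `"dff"`).
#' @param rate sampling rate of the source recording, Hz (used to snap
#'   `t_event` onto an exact grid).
#' @return data.frame with `t_event` and one `event_<i>` column per event;
#'   times an event does not cover are missing.
#' @export
event_traces <- function(tbl, value = "value", rate) {
  if (!value %in% names(tbl)) stop("no column '", value, "' in the event table")
  evs <- sort(unique(tbl$event))
  keys <- grid_key(tbl$t_event, rate)
  all_keys <- sort(unique(keys))
  out <- data.frame(t_event = all_keys / rate)
  for (ev in evs) {
    sel <- tbl$event == ev
    col <- rep(NA_real_, length(all_keys))
    # an event may list the same sample under two intervals (e.g. signal +
    # response window); values are identical so take the first
    first <- !duplicated(keys[sel])
    col[match(keys[sel][first], all_keys)] <- tbl[[value]][sel][first]
    out[[paste0("event_", ev)]] <- col
  }
  out
}

#' Mean event-triggered trace with a variability band
#'
#' Pointwise mean over events at each aligned time, with a band of
#' `multiplier` standard deviations (`band = "sd"`) or standard errors
#' (`band = "se"`). Events shorter than the longest drop out pointwise; the
#' number of contributing events is reported per time point.
#'
#' @param aligned output of [event_traces()].
#' @param band `"sd"` or `"se"`.
#' @param multiplier band half-width in SDs/SEs.
#' @return data.frame with `t_event`, `mean`, `lower`, `upper`, `n`.
#' @export
mean_trace <- function(aligned, band = c("sd", "se"), multiplier = 1) {
  band <- match.arg(band)
  vals <- as.matrix(aligned[, setdiff(names(aligned), "t_event"), drop = FALSE])
  n <- rowSums(!is.na(vals))
  m <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  half <- multiplier * if (band == "se") s / sqrt(n) else s
  data.frame(t_event = aligned$t_event, mean = m,
             lower = m - half, upper = m + half, n = n)
}

#' Peri-event heatmap matrix
#'
#' One row per event on the aligned time grid, in a chosen row order:
#' chronological (`"order"`), total event length descending (`"length"`), or
#' area under the curve descending (`"auc"`, over the full aligned trace or
#' a `[t1, t2)` window of `t_event`). Ties resolve chronologically. Ragged
#' rows are padded with missing values.
#'
#' @param aligned output of [event_traces()].
#' @param sort `"order"`, `"length"` or `"auc"`.
#' @param auc_window optional numeric `c(t1, t2)` on the `t_event` axis.
#' @return list with `matrix` (events x time, dimnames set), `t_event`, and
#'   `order` (original event indices row by row).
#' @export
heatmap_matrix <- function(aligned, sort = c("order", "length", "auc"),
                           auc_window = NULL) {
  sort <- match.arg(sort)
  tev <- aligned$t_event
  cols <- setdiff(names(aligned), "t_event")
  vals <- t(as.matrix(aligned[, cols, drop = FALSE]))
  idx <- as.integer(sub("^event_", "", cols))
  key <- switch(sort,
    order = seq_along(cols) * -1,            # negate: descending order() below
    length = vapply(seq_len(nrow(vals)), function(i) {
      tt <- tev[!is.na(vals[i, ])]
      if (length(tt)) diff(range(tt)) else 0
    }, numeric(1)),
    auc = {
      if (!is.null(auc_window)) {
        if (auc_window[1] < min(tev) - 1e-9 || auc_window[2] > max(tev) + 1e-9)
          stop("auc_window [", auc_window[1], ", ", auc_window[2],
               ") is outside the aligned span")
      }
      vapply(seq_len(nrow(vals)), function(i) {
        ok <- !is.na(vals[i, ])
        if (!is.null(auc_window))
          ok <- ok & tev >= auc_window[1] & tev < auc_window[2]
        if (sum(ok) < 2L) return(-Inf)
        trapezoid_auc(tev[ok], vals[i, ok])
      }, numeric(1))
    })
  ord <- order(-key, seq_along(cols))        # descending, ties chronological
  m <- vals[ord, , drop = FALSE]
  rownames(m) <- cols[ord]
  list(matrix = m, t_event = tev, order = idx[ord])
}

#' Per-event interval summary values
#'
#' One summary value per event x interval, the unit plotted as box-and-whisker
#' summaries: the interval mean, median, or area under the curve (optionally
#' between two time points on the interval clock).
#'
#' @param tbl an `fp_event_table`.
#' @param stat `"mean"`, `"median"` or `"auc"`.
#' @param value value column to summarize.
#' @param auc_window optional `c(t1, t2)` on the `t_interval` axis.
#' @return data.frame with `dataset`, `series`, `event`, `interval`, `value`;
#'   empty intervals yield a missing value.
#' @export
interval_summaries <- function(tbl, stat = c("mean", "median", "auc"),
                               value = "value", auc_window = NULL) {
  stat <- match.arg(stat)
  if (!value %in% names(tbl)) stop("no column '", value, "' in the event table")
  combos <- unique(tbl[, c("dataset", "series", "event", "interval")])
  rownames(combos) <- NULL
  combos$value <- vapply(seq_len(nrow(combos)), function(i) {
    sel <- tbl$event == combos$event[i] & tbl$interval == combos$interval[i] &
      tbl$dataset == combos$dataset[i]
    v <- tbl[[value]][sel]
    ti <- tbl$t_interval[sel]
    if (!is.null(auc_window) && stat == "auc") {
      keep <- ti >= auc_window[1] & ti < auc_window[2]
      v <- v[keep]; ti <- ti[keep]
    }
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    switch(stat,
           mean = mean(v[ok]),
           median = stats::median(v[ok]),
           auc = if (sum(ok) < 2L) NA_real_ else trapezoid_auc(ti[ok], v[ok]))
  }, numeric(1))
  combos
}
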