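#' Align and join a channel from another recording
#'
#' Appends channels from `other` (typically a behavioral stream on its own
#' clock and rate) to `target` by nearest-neighbor sampling on the global
#' clock: each target sample time takes the value of `other`'s closest sample.
#' Equidistant ties resolve to the earlier sample; target times outside
#' `other`'s span become missing — values are never extrapolated.
#'
#' @param target,other `fp_recording`s whose time supports overlap.
#' @param channels channel names of `other` to append (default: all).
#' @param rename optional named character vector `c(old = "new")` applied to
#'   the appended columns; required on a name collision.
#' @return `target` with the appended columns.
#' @export
align_join <- function(target, other, channels = names(other$channels),
                       rename = NULL) {
  tt <- time_axis(target)
  ot <- time_axis(other)
  if (max(ot) < min(tt) || min(ot) > max(tt))
    stop("time supports of '", target$name, "' and '", other$name,
         "' do not overlap")
  # nearest neighbour with tie -> earlier sample
  lo <- findInterval(tt, ot)               # index of last ot <= tt (0 if none)
  hi <- pmin(lo + 1L, length(ot))
  lo_c <- pmax(lo, 1L)
  d_lo <- abs(tt - ot[lo_c])
  d_hi <- abs(ot[hi] - tt)
  pick <- ifelse(lo == 0L, hi, ifelse(d_lo <= d_hi, lo_c, hi))
  outside <- tt < ot[1L] | tt > ot[length(ot)]
  for (ch in channels) {
    vals <- get_channel(other, ch)[pick]
    vals[outside] <- NA_real_
    new_name <- if (!is.null(rename) && ch %in% names(rename)) rename[[ch]] else ch
    if (new_name %in% names(target$channels))
      stop("channel name collision on '", new_name,
           "'; supply `rename = c(", ch, " = \"...\")`")
    target$channels[[new_name]] <- vals
    target <- add_provenance(target,
      sprintf("aligned '%s' from '%s' (%g Hz) as '%s'; %d sample(s) outside span -> missing",
              ch, other$name, other$rate, new_name, sum(outside)))
  }
  target
}

#' Append one recording after another (row-wise)
#'
#' Concatenates two recordings of identical channel sets and rates on the
#' global clock, e.g. pre- and post-treatment sessions analyzed jointly.
#' `b`'s own start offset is preserved (snapped to `a`'s sampling grid); any
#' clock gap between the recordings is filled with missing samples so the
#' result stays uniformly sampled. The seam time is logged in provenance.
#'
#' @param a,b `fp_recording`s with the same channels and rate.
#' @return the combined `fp_recording`.
#' @export
append_rows <- function(a, b) {
  if (n_samples(b) == 0L) return(a)
  if (!setequal(names(a$channels), names(b$channels)))
    stop("channel sets differ: ", paste(names(a$channels), collapse = ","),
         " vs ", paste(names(b$channels), collapse = ","))
  if (a$rate != b$rate)
    stop("rates differ: ", a$rate, " vs ", b$rate, " Hz")
  end_a <- recording_end(a)
  if (b$start_offset < end_a - 1e-9)
    stop("recordings overlap in time: '", b$name, "' starts at ",
         b$start_offset, " s before '", a$name, "' ends at ", end_a, " s")
  gap_samples <- round((b$start_offset - end_a) * a$rate)
  chans <- lapply(names(a$channels), function(ch)
    c(a$channels[[ch]], rep(NA_real_, gap_samples), b$channels[[ch]]))
  names(chans) <- names(a$channels)
  out <- fp_recording(chans, rate = a$rate, start_offset = a$start_offset,
                      name = a$name, provenance = a$provenance)
  add_provenance(out,
    sprintf("appended '%s' after '%s'; seam at %g s, %d gap sample(s) set missing",
            b$name, a$name, end_a, gap_samples))
}

#' Ratio of two channels
#'
#' @param rec an `fp_recording`.
#' @param num,den channel names for numerator and denominator.
#' @param name name for the new channel (default `"num/den"`).
#' @return the recording with the added ratio channel; samples where the
#'   denominator is 0 become missing (count logged).
#' @export
ratio_channel <- function(rec, num, den, name = paste0(num, "/", den)) {
  x <- get_channel(rec, num)
  y <- get_channel(rec, den)
  out <- x / y
  nzero <- sum(y == 0, na.rm = TRUE)
  out[!is.na(y) & y == 0] <- NA_real_
  rec$channels[[name]] <- out
  add_provenance(rec, sprintf("ratio '%s' = %s / %s; %d zero-denominator sample(s) -> missing",
                              name, num, den, nzero))
}

#' Zero-phase low-pass filter with downsampling
#'
#' Applies an order-4 Butterworth low-pass filter forward and backward
#' (zero phase, so event timing is not lagged), then keeps every
#' `factor`-th sample. Interior missing values are linearly interpolated for
#' filtering and restored to missing afterwards.
#'
#' @param rec an `fp_recording`.
#' @param cutoff cutoff frequency, Hz; must be below the Nyquist rate.
#' @param factor integer decimation factor (>= 1).
#' @param channels channels to filter (default: all).
#' @return the filtered recording at rate `rate / factor`.
#' @export
lowpass_downsample <- function(rec, cutoff, factor = 1L,
                               channels = names(rec$channels)) {
  nyq <- rec$rate / 2
  if (cutoff >= nyq)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  if (factor < 1L || factor != round(factor)) stop("`factor` must be a whole number >= 1")
  bf <- signal::butter(4, cutoff / nyq, type = "low")
  keep <- seq(1L, n_samples(rec), by = factor)
  out <- rec
  for (ch in channels) {
    x <- get_channel(rec, ch)
    nas <- is.na(x)
    if (any(nas)) {
      if (all(nas)) { out$channels[[ch]] <- x[keep]; next }
      x <- stats::approx(which(!nas), x[!nas], xout = seq_along(x),
                         rule = 2)$y
    }
    # reflect about the endpoints to suppress zero-state edge transients
    n <- length(x)
    pad <- min(n - 1L, max(100L, as.integer(ceiling(3 * rec$rate / cutoff))))
    xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    y <- signal::filtfilt(bf, xp)[(pad + 1L):(pad + n)]
    y[nas] <- NA_real_
    out$channels[[ch]] <- y[keep]
  }
  out$channels[setdiff(names(rec$channels), channels)] <-
    lapply(rec$channels[setdiff(names(rec$channels), channels)], `[`, keep)
  out$rate <- rec$rate / factor
  add_provenance(out, sprintf("low-pass %g Hz (order-4 Butterworth, zero phase), downsample x%d",
                              cutoff, factor))
}

#' Linear scaling of a channel
#'
#' Either applies `x -> gain * x + offset` directly, or (fit mode, when
#' `match_to` is given) chooses gain and offset so the scaled channel's mean
#' and standard deviation equal those of another channel — the standard step
#' when overlaying a behavioral trace on a fluorescence trace.
#'
#' @param rec an `fp_recording`.
#' @param channel channel to scale.
#' @param gain,offset scaling coefficients (ignored when `match_to` given).
#' @param match_to optional channel name whose mean/SD to match.
#' @return the recording with the channel scaled in place.
#' @export
linear_scale <- function(rec, channel, gain = 1, offset = 0, match_to = NULL) {
  x <- get_channel(rec, channel)
  if (!is.null(match_to)) {
    y <- get_channel(rec, match_to)
    sx <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(sx) || sx == 0)
      stop("cannot match moments: channel '", channel, "' has zero variance")
    gain <- stats::sd(y, na.rm = TRUE) / sx
    offset <- mean(y, na.rm = TRUE) - gain * mean(x, na.rm = TRUE)
  }
  rec$channels[[channel]] <- gain * x + offset
  add_provenance(rec, sprintf("linear scale '%s': gain %g, offset %g%s", channel,
                              gain, offset,
                              if (is.null(match_to)) "" else paste0(" (matched to '", match_to, "')")))
}

#' Fit a photobleaching trend model
#'
#' Photobleaching makes fluorescence decay over a session; it is modelled as
#' a decreasing function of time, either linear `F(t) = alpha + beta * t` or
#' exponential `F(t) = a * exp(-b * t) + c`. The linear fit is closed-form
#' least squares; the exponential fit is nonlinear least squares
#' (Levenberg-Marquardt) initialized by a log-linear regression of
#' `log(F - c0)` on `t` with `c0` just below the channel minimum, under the
#' constraints `a >= 0`, `b >= 0`. Parameters may instead be supplied
#' manually, skipping the fit.
#'
#' @param rec an `fp_recording`.
#' @param channel channel to model.
#' @param form `"exponential"` or `"linear"`.
#' @param params optional named numeric of manual parameters
#'   (`c(alpha=, beta=)` or `c(a=, b=, c=)`).
#' @return an object of class `fp_bleach` with elements `form`, `coef`,
#'   `fitted` (logical), `rss`, and `degenerate` (TRUE when the exponential
#'   collapses to a constant, `b` at 0).
#' @export
fit_bleach <- function(rec, channel, form = c("exponential", "linear"),
                       params = NULL) {
  form <- match.arg(form)
  x <- get_channel(rec, channel)
  tt <- time_axis(rec)
  ok <- !is.na(x)
  predfun <- function(coef, t) {
    if (form == "linear") coef[["alpha"]] + coef[["beta"]] * t
    else coef[["a"]] * exp(-coef[["b"]] * t) + coef[["c"]]
  }
  if (!is.null(params)) {
    need <- if (form == "linear") c("alpha", "beta") else c("a", "b", "c")
    if (!all(need %in% names(params)))
      stop("manual `params` must name ", paste(need, collapse = ", "))
    coef <- params[need]
    rss <- sum((x[ok] - predfun(coef, tt[ok]))^2)
    return(structure(list(form = form, coef = coef, fitted = FALSE,
                          rss = rss, degenerate = FALSE),
                     class = "fp_bleach"))
  }
  minimum <- if (form == "linear") 3L else 4L
  if (sum(ok) < minimum)
    stop("need >= ", minimum, " non-missing samples to fit a ", form, " model")
  t1 <- tt[ok]; y1 <- x[ok]
  if (form == "linear") {
    fit <- stats::lm.fit(cbind(1, t1), y1)
    coef <- c(alpha = unname(fit$coefficients[1]), beta = unname(fit$coefficients[2]))
    rss <- sum(fit$residuals^2)
    return(structure(list(form = "linear", coef = coef, fitted = TRUE,
                          rss = rss, degenerate = FALSE),
                     class = "fp_bleach"))
  }
  # exponential: log-linear initialization, bounded Levenberg-Marquardt
  span <- diff(range(y1))
  c0 <- min(y1) - max(span, abs(min(y1)), 1) * 1e-3
  pos <- y1 - c0
  ll <- stats::lm.fit(cbind(1, t1), log(pos))
  a0 <- max(exp(ll$coefficients[1]), span * 0.1, 1e-8)
  b0 <- max(-ll$coefficients[2], 1e-9)
  starts <- list(c(a = a0, b = b0, c = c0),
                 c(a = max(span, 1e-6), b = 1 / max(max(t1), 1), c = min(y1)),
                 c(a = max(mean(y1), 1e-6), b = 1e-4, c = 0))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-b * t) + c,
                        data = data.frame(t = t1, y = y1),
                        start = as.list(st),
                        lower = c(a = 0, b = 0, c = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best))
    stop("exponential bleach fit failed to converge from ", length(starts),
         " starting points")
  coef <- best$coef[c("a", "b", "c")]
  degenerate <- coef[["b"]] < 1e-12 ||
    coef[["a"]] * (1 - exp(-coef[["b"]] * max(t1))) < 1e-9 * max(abs(y1), 1)
  structure(list(form = "exponential", coef = coef, fitted = TRUE,
                 rss = best$rss, degenerate = degenerate),
            class = "fp_bleach")
}

#' @export
print.fp_bleach <- function(x, ...) {
  cat(sprintf("<fp_bleach> %s model (%s)%s\n", x$form,
              if (x$fitted) "least squares" else "manual",
              if (x$degenerate) " [degenerate: ~constant]" else ""))
  print(x$coef)
  cat("RSS:", x$rss, "\n")
  invisible(x)
}

#' Predict a bleach model over a set of times
#' @param object an `fp_bleach`.
#' @param times times in seconds.
#' @param ... unused.
#' @export
predict.fp_bleach <- function(object, times, ...) {
  cf <- object$coef
  if (object$form == "linear") cf[["alpha"]] + cf[["beta"]] * times
  else cf[["a"]] * exp(-cf[["b"]] * times) + cf[["c"]]
}

#' Detrend a channel with a bleach model
#'
#' @param rec an `fp_recording`.
#' @param channel channel to detrend.
#' @param model an `fp_bleach`.
#' @param mode `"residual"` (`F - Fhat`), `"predicted"` (`Fhat`), or `"dff"`
#'   (`F / Fhat - 1`, the fractional change about the trend).
#' @return the recording with the channel replaced.
#' @export
detrend <- function(rec, channel, model, mode = c("residual", "predicted", "dff")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "fp_bleach"))
  x <- get_channel(rec, channel)
  fhat <- predict(model, time_axis(rec))
  if (any(!is.finite(fhat)))
    stop("bleach model is not finite over the recording span")
  if (mode == "dff" && any(fhat <= 0))
    stop("dff detrend undefined: fitted trend is <= 0 at some samples")
  rec$channels[[channel]] <- switch(mode,
                                    residual = x - fhat,
                                    predicted = fhat,
                                    dff = x / fhat - 1)
  add_provenance(rec, sprintf("detrended '%s' (%s model, mode %s)", channel,
                              model$form, mode))
}

#' Rename a channel
#' @param rec an `fp_recording`.
#' @param old,new channel names.
#' @export
rename_channel <- function(rec, old, new) {
  if (!old %in% names(rec$channels)) stop("unknown channel '", old, "'")
  if (new %in% names(rec$channels)) stop("channel '", new, "' already exists")
  names(rec$channels)[names(rec$channels) == old] <- new
  add_provenance(rec, sprintf("renamed channel '%s' -> '%s'", old, new))
}

#' Rename a recording
#' @param rec an `fp_recording`.
#' @param new new dataset name.
#' @export
rename_recording <- function(rec, new) {
  old <- rec$name
  rec$name <- as.character(new)
  add_provenance(rec, sprintf("renamed dataset '%s' -> '%s'", old, new))
}

#' Apply a custom transformation function
#'
#' Escape hatch for operations the built-in transforms do not cover: `fn`
#' receives a data.frame with a `time` column plus one column per channel and
#' must return a data.frame of the same number of rows with a `time` column;
#' its non-time columns become the recording's channels.
#'
#' @param rec an `fp_recording`.
#' @param fn a function `data.frame -> data.frame`.
#' @param label provenance label for the step.
#' @return the transformed recording.
#' @export
apply_custom <- function(rec, fn, label = "custom transform") {
  df <- as.data.frame(c(list(time = time_axis(rec)), rec$channels),
                      check.names = FALSE)
  out <- fn(df)
  if (!is.data.frame(out) || !"time" %in% names(out))
    stop("custom transform must return a data.frame with a `time` column")
  if (nrow(out) != nrow(df))
    stop("custom transform must preserve the number of samples (",
         nrow(df), " -> ", nrow(out), ")")
  rec$channels <- lapply(out[setdiff(names(out), "time")], as.double)
  add_provenance(rec, label)
}
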