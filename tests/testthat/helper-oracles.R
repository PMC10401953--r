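# Shared fixtures and independent brute-force reference implementations.
# The oracles deliberately use literal per-sample loops so they share no code
# with the package's vectorized detectors.

make_rec <- function(..., rate = 1, offset = 0, name = "toy") {
  fp_recording(list(...), rate = rate, start_offset = offset, name = name)
}

# --- brute-force detectors ---------------------------------------------

brute_binary_events <- function(x, rate, offset, inverted = FALSE) {
  b <- ifelse(is.na(x), FALSE, x != 0)
  if (inverted) b <- !b
  n <- length(b)
  tt <- offset + (seq_len(n) - 1) / rate
  end_time <- offset + n / rate
  starts <- c(); ends <- c()
  inside <- FALSE
  for (i in seq_len(n)) {
    if (b[i] && !inside) { starts <- c(starts, tt[i]); inside <- TRUE }
    if (!b[i] && inside) { ends <- c(ends, tt[i]); inside <- FALSE }
  }
  if (inside) ends <- c(ends, end_time)
  data.frame(start = starts %||% numeric(), end = ends %||% numeric())
}

brute_binned_events <- function(t0, L, end_time) {
  starts <- c(); s <- t0
  while (s + L <= end_time + 1e-12) { starts <- c(starts, s); s <- s + L }
  data.frame(start = starts %||% numeric(),
             end = (starts + L) %||% numeric())
}

# literal trailing-window recomputation, one sample at a time
brute_peak_flags <- function(x, rate, L, k) {
  n <- length(x)
  w <- round(L * rate)
  flag <- logical(n)
  for (i in seq_len(n)) {
    win <- x[max(1, i - w + 1):i]
    win <- win[!is.na(win)]
    if (length(win) < 2 || is.na(x[i])) next
    mu <- mean(win); s <- sd(win)
    if (s > 0 && x[i] > mu + k * s) flag[i] <- TRUE
  }
  flag
}

brute_flags_to_events <- function(flag, rate, offset) {
  brute_binary_events(as.numeric(flag), rate, offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_events_equal <- function(series, expected, tol = 1e-9) {
  expect_equal(nrow(series$events), nrow(expected))
  if (nrow(expected)) {
    expect_equal(series$events$start, expected$start, tolerance = tol)
    expect_equal(series$events$end, expected$end, tolerance = tol)
  }
}

# events data.frame shorthand
ev_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(start = m[, 1], end = m[, 2])
}

make_series <- function(..., span = c(0, 1000)) {
  fp_events(ev_df(...), definition = "fixture", dataset = "toy", span = span)
}
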