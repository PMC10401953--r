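# ---- detectors ---------------------------------------------------------

test_that("binary detection finds rising/falling edge runs", {
  rec <- make_rec(ttl = c(0, 0, 1, 1, 0, 1, 0), rate = 1)
  expect_events_equal(detect_binary(rec, "ttl"), ev_df(2, 4, 5, 6))

  ones <- make_rec(ttl = rep(1, 5), rate = 1, offset = 2)
  expect_events_equal(detect_binary(ones, "ttl"), ev_df(2, 7))

  inv <- make_rec(ttl = c(0, 0, 1, 1, 0), rate = 1)
  expect_events_equal(detect_binary(inv, "ttl", inverted = TRUE),
                      ev_df(0, 2, 4, 5))

  expect_equal(n_events(detect_binary(make_rec(ttl = rep(0, 5)), "ttl")), 0)
  expect_warning(detect_binary(make_rec(ttl = c(0, 2, 0), rate = 1), "ttl"),
                 "0/1")
})

test_that("binned detection drops the trailing partial bin", {
  rec <- make_rec(x = numeric(35), rate = 1)
  expect_events_equal(detect_binned(rec, 0, 10), ev_df(0, 10, 10, 20, 20, 30))
  expect_events_equal(detect_binned(rec, 5, 10), ev_df(5, 15, 15, 25, 25, 35))
  expect_equal(n_events(detect_binned(rec, 0, 100)), 0)
  expect_equal(n_events(detect_binned(rec, 40, 1)), 0)
})

test_that("peak detection flags trailing-window threshold crossings", {
  # constant signal: no variance, no events
  expect_equal(n_events(detect_peaks(make_rec(x = rep(5, 50)), "x", L = 5, k = 2)), 0)

  # one 10-sigma spike in seeded noise at k = 4 -> exactly one event
  set.seed(7)
  x <- rnorm(400, 0, 1)
  x[250] <- x[250] + 10
  rec <- make_rec(x = x, rate = 1)
  s <- detect_peaks(rec, "x", L = 50, k = 4)
  expect_equal(n_events(s), 1)
  expect_true(s$events$start <= 249 && s$events$end > 249)  # t of sample 250
})

test_that("timestamped events are clipped to the span", {
  rec <- make_rec(x = numeric(10), rate = 1)
  st <- data.frame(start = c(1, 8), end = c(3, 12))
  s <- detect_timestamped(rec, st)
  expect_events_equal(s, ev_df(1, 3, 8, 10))
  expect_warning(detect_timestamped(rec, data.frame(start = 50, end = 60)),
                 "outside")
  expect_equal(n_events(detect_timestamped(rec, data.frame(start = numeric(),
                                                           end = numeric()))), 0)
})

test_that("all detectors match brute-force references on random inputs", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(20:80, 1)
    rate <- sample(c(1, 2, 5, 20), 1)
    offset <- sample(c(0, 3), 1)
    x <- sample(c(0, 1), n, replace = TRUE)
    rec <- make_rec(ttl = x, rate = rate, offset = offset)
    for (inv in c(FALSE, TRUE))
      expect_events_equal(detect_binary(rec, "ttl", inverted = inv),
                          brute_binary_events(x, rate, offset, inverted = inv))

    y <- rnorm(n)
    recy <- make_rec(y = y, rate = rate, offset = offset)
    L <- sample(2:10, 1) / rate * 2
    k <- runif(1, 0.5, 3)
    flags <- brute_peak_flags(y, rate, L, k)
    expect_events_equal(detect_peaks(recy, "y", L, k),
                        brute_flags_to_events(flags, rate, offset))

    t0 <- offset + runif(1, 0, 2)
    L2 <- runif(1, 0.5, 5)
    expect_events_equal(detect_binned(recy, t0, L2),
                        brute_binned_events(t0, L2, offset + n / rate))
  }
})

# ---- conditions --------------------------------------------------------

test_that("conditions gate events per sample in entire/any mode", {
  rec <- make_rec(ttl = c(1, 1, 0, 1, 1, 0), cue = c(1, 1, 0, 1, 0, 0), rate = 1)
  s <- detect_binary(rec, "ttl")           # [0,2), [3,5)
  expect_equal(n_events(apply_condition(s, rec, "TRUE")), 2)
  # the classic time gate
  expect_events_equal(apply_condition(s, rec, "(time) < 360"), ev_df(0, 2, 3, 5))
  expect_events_equal(apply_condition(s, rec, "(time) < 4"), ev_df(0, 2))
  # second event satisfies cue==1 only at its first sample
  expect_events_equal(apply_condition(s, rec, "cue == 1", mode = "entire"),
                      ev_df(0, 2))
  expect_events_equal(apply_condition(s, rec, "cue == 1", mode = "any"),
                      ev_df(0, 2, 3, 5))
  expect_error(apply_condition(s, rec, "bogus > 1"), "bogus")
  expect_error(apply_condition(s, rec, "system('ls')"), "not allowed")
})

# ---- filters -----------------------------------------------------------

test_that("each filter kind matches its stated semantics", {
  # aggregate: gap-merge (gap <= g), zero-gap merges
  expect_events_equal(
    apply_filters(make_series(0, 1, 2, 3, 10, 11),
                  filter_step("aggregate", gap = 2)),
    ev_df(0, 3, 10, 11))
  expect_events_equal(
    apply_filters(make_series(0, 1, 1, 2), filter_step("aggregate", gap = 0)),
    ev_df(0, 2))
  # coalesce: overlap merge; touching events stay separate
  expect_events_equal(
    apply_filters(make_series(0, 5, 3, 8), filter_step("coalesce")),
    ev_df(0, 8))
  expect_events_equal(
    apply_filters(make_series(0, 5, 5, 8), filter_step("coalesce")),
    ev_df(0, 5, 5, 8))
  # length rules
  expect_events_equal(
    apply_filters(make_series(0, 1, 2, 4), filter_step("drop_short", min_length = 1.5)),
    ev_df(2, 4))
  expect_events_equal(
    apply_filters(make_series(0, 1, 2, 4), filter_step("drop_long", max_length = 1.5)),
    ev_df(0, 1))
  expect_events_equal(
    apply_filters(make_series(0, 1, 5, 9), filter_step("pad_min", min_length = 3)),
    ev_df(0, 3, 5, 9))
  expect_events_equal(
    apply_filters(make_series(0, 1, 5, 9), filter_step("truncate_max", max_length = 3)),
    ev_df(0, 1, 5, 8))
  # shift clips to the recording span
  expect_events_equal(
    apply_filters(fp_events(ev_df(0, 2, 8, 10), span = c(0, 10)),
                  filter_step("shift", delta = -1)),
    ev_df(0, 1, 7, 9))
  # first/last
  expect_events_equal(
    apply_filters(make_series(0, 1, 2, 3, 4, 5),
                  filter_step("first_last", which = "first", action = "drop")),
    ev_df(2, 3, 4, 5))
  expect_events_equal(
    apply_filters(make_series(0, 1, 2, 3, 4, 5),
                  filter_step("first_last", which = "last", action = "keep")),
    ev_df(4, 5))
  # before/after a timestamp
  expect_events_equal(
    apply_filters(make_series(0, 1, 5, 6, 9, 10),
                  filter_step("before_after", timestamp = 5, side = "before",
                              action = "keep")),
    ev_df(0, 1))
  expect_events_equal(
    apply_filters(make_series(0, 1, 5, 6, 9, 10),
                  filter_step("before_after", timestamp = 5, side = "after",
                              action = "drop")),
    ev_df(0, 1))
  # debounce compares against the last KEPT event
  expect_events_equal(
    apply_filters(make_series(0, 1, 2, 3, 4, 5, 9, 10),
                  filter_step("debounce", separation = 3)),
    ev_df(0, 1, 4, 5, 9, 10))
  # min_rate: neighbourhood count within +/- window/2
  expect_events_equal(
    apply_filters(make_series(0, 1, 2, 3, 4, 5, 50, 51),
                  filter_step("min_rate", count = 2, window = 10)),
    ev_df(0, 1, 2, 3, 4, 5))
  expect_error(filter_step("drop_short", min_length = -1), "non-negative")
})

test_that("coalesce and aggregate are idempotent; empty chain is identity", {
  s <- make_series(0, 5, 3, 8, 9, 12, 12.5, 13)
  once <- apply_filters(s, filter_step("coalesce"))
  twice <- apply_filters(once, filter_step("coalesce"))
  expect_equal(once$events[, c("start", "end")], twice$events[, c("start", "end")])
  agg1 <- apply_filters(s, filter_step("aggregate", gap = 1))
  agg2 <- apply_filters(agg1, filter_step("aggregate", gap = 1))
  expect_equal(agg1$events[, c("start", "end")], agg2$events[, c("start", "end")])

  same <- apply_filters(s, list())
  expect_equal(same$events[, c("start", "end")], s$events[, c("start", "end")])
})

test_that("filter order matters: pad then drop differs from drop then pad", {
  s <- make_series(0, 1, 10, 14)
  pad_then_drop <- apply_filters(s, list(filter_step("pad_min", min_length = 2),
                                         filter_step("drop_short", min_length = 2)))
  drop_then_pad <- apply_filters(s, list(filter_step("drop_short", min_length = 2),
                                         filter_step("pad_min", min_length = 2)))
  expect_equal(n_events(pad_then_drop), 2)
  expect_equal(n_events(drop_then_pad), 1)
})

test_that("filter outputs stay sorted, half-open and within span", {
  set.seed(5)
  for (rep in 1:50) {
    starts <- sort(runif(8, 0, 90))
    s <- fp_events(data.frame(start = starts, end = starts + runif(8, 0.1, 15)),
                   span = c(0, 100))
    steps <- list(filter_step("shift", delta = runif(1, -20, 20)),
                  filter_step("coalesce"),
                  filter_step("pad_min", min_length = runif(1, 0, 5)),
                  filter_step("truncate_max", max_length = runif(1, 1, 10)),
                  filter_step("debounce", separation = runif(1, 0, 5)))
    out <- apply_filters(s, steps)$events
    if (nrow(out)) {
      expect_false(is.unsorted(out$start))
      expect_true(all(out$end > out$start))
      expect_true(all(out$start >= 0 & out$end <= 100))
      expect_equal(out$index, seq_len(nrow(out)))
    }
  }
})

# ---- intervals ---------------------------------------------------------

test_that("tone-protocol intervals yield 60 baseline samples per event", {
  rec <- simulate_recording(tone_protocol())
  s <- detect_binary(rec, "ttl")
  tbl <- resolve_intervals(s, list(
    interval_spec("baseline", "event_start", -3, 0),
    interval_spec("signal", "event_signal"),
    interval_spec("post", "event_end", 0, 5)), rec, "fluorescence")
  counts <- table(tbl$interval, tbl$event)
  expect_true(all(counts["baseline", ] == 60))   # 3 s x 20 Hz
  expect_true(all(counts["signal", ] == 200))    # 10 s tone
  expect_true(all(counts["post", ] == 100))      # 5 s x 20 Hz
})

test_that("event_signal interval reproduces exactly the detector's samples", {
  rec <- make_rec(ttl = c(0, 1, 1, 0, 0, 1, 1, 1, 0, 0), sig = 1:10, rate = 1)
  s <- detect_binary(rec, "ttl")
  tbl <- resolve_intervals(s, list(interval_spec("signal", "event_signal")),
                           rec, "sig")
  expect_equal(tbl$t_dataset[tbl$event == 1], c(1, 2))
  expect_equal(tbl$value[tbl$event == 2], c(6, 7, 8))
  expect_equal(tbl$t_event, tbl$t_dataset - rep(c(1, 5), times = c(2, 3)))
  # t_event strictly increasing within each event
  for (ev in unique(tbl$event))
    expect_true(all(diff(tbl$t_event[tbl$event == ev]) > 0))
})

test_that("no-overlap baselines are raised to the preceding event's claim", {
  rec <- make_rec(x = 1:100, rate = 1)
  s <- fp_events(ev_df(30, 35, 36, 40), dataset = "toy", span = c(0, 100))
  s$events$source_label <- ""
  tbl <- resolve_intervals(s, list(
    interval_spec("baseline", "event_start_no_overlap", -20, 0)), rec, "x")
  b1 <- tbl[tbl$event == 1, ]
  b2 <- tbl[tbl$event == 2, ]
  expect_equal(min(b1$t_dataset), 10)            # full 20 s available
  expect_equal(min(b2$t_dataset), 35)            # raised to event 1's end
  expect_equal(max(b2$t_dataset), 35)            # [35, 36) at 1 Hz
})

test_that("out-of-span intervals clip or empty out with a log, not an error", {
  rec <- make_rec(x = 1:10, rate = 1)
  s <- fp_events(ev_df(1, 3), dataset = "toy", span = c(0, 10))
  tbl <- resolve_intervals(s, list(interval_spec("pre", "event_start", -5, 0),
                                   interval_spec("far", "event_end", 50, 60)),
                           rec, "x")
  expect_equal(sum(tbl$interval == "pre"), 1)    # clipped to [0, 1)
  expect_equal(sum(tbl$interval == "far"), 0)
  expect_true(any(grepl("clipped", attr(tbl, "log"))))
  expect_true(any(grepl("empty", attr(tbl, "log"))))
})
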