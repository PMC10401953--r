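test_that("align_join resamples by nearest neighbour with earlier-sample ties", {
  a <- make_rec(f = rnorm(10), rate = 2, name = "photo")
  b <- make_rec(beh = as.double(1:5), rate = 1, name = "beh")
  j <- align_join(a, b)
  # identical clocks at shared times; target t=0.5 ties between beh t=0 and 1
  expect_equal(j$channels$beh[1], 1)            # t = 0
  expect_equal(j$channels$beh[2], 1)            # t = 0.5 tie -> earlier
  expect_equal(j$channels$beh[3], 2)            # t = 1
  expect_equal(j$channels$beh[9], 5)            # t = 4
  expect_true(is.na(j$channels$beh[10]))        # t = 4.5 is past beh's span
  same <- align_join(make_rec(f = rnorm(5), rate = 1),
                     make_rec(g = as.double(11:15), rate = 1))
  expect_equal(same$channels$g, as.double(11:15))
})

test_that("align_join marks times outside the other stream as missing", {
  a <- make_rec(f = rnorm(30), rate = 1, name = "photo")
  b <- fp_recording(list(beh = as.double(1:10)), rate = 1, start_offset = 10,
                    name = "beh")
  j <- align_join(a, b)
  expect_true(all(is.na(j$channels$beh[1:10])))   # first 10 s before b starts
  expect_false(anyNA(j$channels$beh[11:20]))
  expect_true(all(is.na(j$channels$beh[22:30])))  # after b's last sample (t=19)
  expect_error(align_join(a, b, rename = NULL) -> x, NA)
  expect_error(align_join(j, b), "collision")
})

test_that("align_join is idempotent under a new name", {
  a <- make_rec(f = rnorm(10), rate = 2, name = "photo")
  b <- make_rec(beh = rnorm(7), rate = 1.5, name = "beh")
  j1 <- align_join(a, b)
  j2 <- align_join(j1, b, rename = c(beh = "beh2"))
  expect_equal(j2$channels$beh, j2$channels$beh2)
})

test_that("append_rows joins sessions on the global clock, gap as missing", {
  a <- make_rec(f = as.double(1:100), rate = 1, name = "pre")
  b <- fp_recording(list(f = as.double(1:50)), rate = 1, start_offset = 100,
                    name = "post")
  ab <- append_rows(a, b)
  expect_equal(n_samples(ab), 150)
  expect_equal(ab$channels$f, c(1:100, 1:50))
  empty <- fp_recording(list(f = numeric()), rate = 1, start_offset = 100)
  expect_equal(append_rows(a, empty)$channels$f, a$channels$f)

  gap <- fp_recording(list(f = as.double(1:10)), rate = 1, start_offset = 105)
  agap <- append_rows(a, gap)
  expect_equal(n_samples(agap), 115)
  expect_true(all(is.na(agap$channels$f[101:105])))
  expect_error(append_rows(a, a), "overlap")
  expect_error(append_rows(a, fp_recording(list(g = 1), rate = 1,
                                           start_offset = 200)), "channel sets")
  expect_error(append_rows(a, fp_recording(list(f = 1), rate = 2,
                                           start_offset = 200)), "rates")
})

test_that("events remain detectable across an append seam", {
  half1 <- make_rec(ttl = c(rep(0, 5), rep(1, 5)), rate = 1, name = "pre")
  half2 <- fp_recording(list(ttl = c(rep(1, 3), rep(0, 7))), rate = 1,
                        start_offset = 10, name = "post")
  joined <- append_rows(half1, half2)
  s <- detect_binary(joined, "ttl")
  expect_events_equal(s, ev_df(5, 13))   # one event spanning the seam
})

test_that("ratio_channel divides elementwise and logs zero denominators", {
  rec <- make_rec(a = c(1, 2, 3, 4), b = c(2, 0, 3, 8), rate = 1)
  r <- ratio_channel(rec, "a", "b")
  expect_equal(r$channels[["a/b"]], c(0.5, NA, 1, 0.5))
  expect_equal(sum(is.na(r$channels[["a/b"]])), 1)
  rr <- ratio_channel(rec, "a", "a")
  expect_equal(rr$channels[["a/a"]], rep(1, 4))
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50)
  rec2 <- make_rec(x = x, y = y, rate = 1)
  expect_equal(ratio_channel(rec2, "x", "y")$channels[["x/y"]], x / y)
})

test_that("lowpass_downsample preserves the pass band and kills the stop band", {
  rate <- 20
  tt <- (0:(60 * rate - 1)) / rate
  slow <- sin(2 * pi * 0.1 * tt)
  fast <- sin(2 * pi * 8 * tt)
  rec <- make_rec(slow = slow, fast = fast, rate = rate)

  # near-identity: factor 1, cutoff near Nyquist
  ident <- lowpass_downsample(rec, cutoff = 9.5, factor = 1)
  expect_lt(max(abs(ident$channels$slow - slow)), 1e-3)

  # 0.1 Hz passes a 1 Hz cutoff with < 1% amplitude loss even downsampled x10
  lp <- lowpass_downsample(rec, cutoff = 1, factor = 10)
  expect_equal(lp$rate, 2)
  mid <- 21:100   # avoid filter edge transients
  expect_lt(max(abs(lp$channels$slow[mid] -
                    sin(2 * pi * 0.1 * time_axis(lp))[mid])) , 0.01)

  # 8 Hz is attenuated by > 20 dB
  gain <- max(abs(lowpass_downsample(rec, cutoff = 1, factor = 1)$channels$fast[200:1000]))
  expect_lt(20 * log10(gain / 1), -20)

  expect_error(lowpass_downsample(rec, cutoff = 10), "Nyquist")
})

test_that("band-limited mean survives filter + downsample + hold within 1e-6", {
  rate <- 50
  tt <- (0:(40 * rate - 1)) / rate
  x <- 2 + 0.5 * sin(2 * pi * 0.2 * tt)
  rec <- make_rec(x = x, rate = rate)
  lp <- lowpass_downsample(rec, cutoff = 2, factor = 5)
  held <- rep(lp$channels$x, each = 5)
  expect_lt(abs(mean(held) - mean(x)) / abs(mean(x)), 1e-6)
})

test_that("linear_scale applies gain/offset and matches moments in fit mode", {
  rec <- make_rec(x = c(1, 2, 3), y = c(10, 20, 60), rate = 1)
  expect_equal(linear_scale(rec, "x", gain = 1, offset = 0)$channels$x, c(1, 2, 3))
  expect_equal(linear_scale(rec, "x", gain = -1)$channels$x, c(-1, -2, -3))
  fit <- linear_scale(rec, "x", match_to = "y")
  expect_equal(mean(fit$channels$x), mean(rec$channels$y), tolerance = 1e-9)
  expect_equal(sd(fit$channels$x), sd(rec$channels$y), tolerance = 1e-9)
  flat <- make_rec(x = rep(1, 5), y = rnorm(5), rate = 1)
  expect_error(linear_scale(flat, "x", match_to = "y"), "zero variance")
})

test_that("fit_bleach recovers exact models and accepts manual parameters", {
  tt <- (0:999) / 10
  lin <- make_rec(x = 5 - 0.01 * tt, rate = 10)
  ml <- fit_bleach(lin, "x", form = "linear")
  expect_equal(unname(ml$coef), c(5, -0.01), tolerance = 1e-9)

  ex <- make_rec(x = 2 * exp(-0.001 * tt) + 1, rate = 10)
  me <- fit_bleach(ex, "x", form = "exponential")
  expect_equal(unname(me$coef[c("a", "b", "c")]), c(2, 0.001, 1),
               tolerance = 1e-5)

  manual <- fit_bleach(ex, "x", form = "exponential",
                       params = c(a = 2, b = 0.001, c = 1))
  expect_false(manual$fitted)
  expect_lt(manual$rss, 1e-15)

  const <- make_rec(x = rep(4, 100), rate = 1)
  mc <- fit_bleach(const, "x", form = "exponential")
  expect_true(mc$degenerate)
  expect_lt(max(abs(predict(mc, (0:99)) - 4)), 1e-6)

  expect_error(fit_bleach(make_rec(x = c(1, 2, NA), rate = 1), "x", "linear"),
               ">= 3")
})

test_that("exponential bleach recovery from the generator's ground truth", {
  cfg <- tone_protocol(noise_sd = 0,
                       kernel = c(amplitude = 0, tau_rise = 0.5, tau_decay = 2))
  rec <- simulate_recording(cfg)
  m <- fit_bleach(rec, "fluorescence", form = "exponential")
  expect_equal(unname(m$coef[c("a", "b", "c")]), c(2, 0.001, 1),
               tolerance = 1e-6)
})

test_that("detrend modes satisfy their conservation identities", {
  tt <- (0:999) / 10
  truth <- c(a = 2, b = 0.01, c = 1)
  x <- truth[["a"]] * exp(-truth[["b"]] * tt) + truth[["c"]]
  rec <- make_rec(x = x, rate = 10)
  m <- fit_bleach(rec, "x", form = "exponential")
  res <- detrend(rec, "x", m, mode = "residual")$channels$x
  expect_lt(max(abs(res)), 1e-7)
  pred <- detrend(rec, "x", m, mode = "predicted")$channels$x
  expect_equal(pred + res, x, tolerance = 1e-12)
  dff <- detrend(rec, "x", m, mode = "dff")$channels$x
  expect_lt(max(abs(dff)), 1e-7)

  neg <- fit_bleach(rec, "x", params = c(a = 1, b = 0.001, c = -5),
                    form = "exponential")
  expect_error(detrend(rec, "x", neg, mode = "dff"), "<= 0")
})

test_that("rename changes only names; custom hook transforms the table", {
  rec <- make_rec(x = c(1, 2), rate = 1)
  rn <- rename_channel(rec, "x", "y")
  expect_equal(rn$channels$y, c(1, 2))
  back <- rename_channel(rn, "y", "x")
  expect_equal(back$channels, rec$channels)
  expect_error(rename_channel(rec, "zz", "y"), "unknown")
  expect_error(rename_channel(make_rec(x = 1, y = 1, rate = 1), "x", "y"),
               "exists")
  expect_equal(rename_recording(rec, "new")$name, "new")

  doubled <- apply_custom(rec, function(df) { df$x <- df$x * 2; df })
  expect_equal(doubled$channels$x, c(2, 4))
  expect_error(apply_custom(rec, function(df) df[1, ]), "number of samples")
  expect_error(apply_custom(rec, function(df) df$x), "data.frame")
})
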