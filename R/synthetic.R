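#' Scenario configuration for synthetic recordings
#'
#' Describes a synthetic fiber-photometry session: an exponentially bleaching
#' baseline `B(t) = a * exp(-b * t) + c`, fractional transient responses
#' locked to scheduled event onsets, proportional Gaussian noise, and a TTL
#' channel marking the schedule. The generated fluorescence is
#' `F(t) = B(t) * (1 + r(t) + e(t))` where `r(t)` sums amplitude-scaled
#' transient kernels and `e(t) ~ N(0, noise_sd^2)`; modelling the response and
#' the noise as fractions of the instantaneous baseline keeps the
#' delta-F-over-F of the signal stationary across the bleaching decay.
#'
#' @param duration recording length, seconds; `duration * rate` must be whole.
#' @param rate sampling rate, Hz.
#' @param bleach named numeric `c(a=, b=, c=)` of the baseline model.
#' @param kernel named numeric `c(amplitude=, tau_rise=, tau_decay=)`;
#'   amplitude is the peak fractional response (0.2 = 20% dF/F).
#' @param events data.frame with columns `onset` and `length` (seconds).
#' @param noise_sd fractional noise standard deviation (>= 0).
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param spectral optional list describing a spectrally resolved variant, see
#'   [simulate_spectral()].
#' @return a list of class `fp_scenario`.
#' @export
scenario_config <- function(duration, rate,
                            bleach = c(a = 2, b = 0.001, c = 1),
                            kernel = c(amplitude = 0.2, tau_rise = 0.5,
                                       tau_decay = 2),
                            events = data.frame(onset = numeric(),
                                                length = numeric()),
                            noise_sd = 0.01, seed = 1L, spectral = NULL) {
  n <- duration * rate
  if (abs(n - round(n)) > 1e-9)
    stop("duration * rate must be a whole number of samples (got ", n, ")")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(all(c("a", "b", "c") %in% names(bleach)),
            all(c("amplitude", "tau_rise", "tau_decay") %in% names(kernel)),
            all(c("onset", "length") %in% names(events)))
  structure(list(duration = duration, rate = rate, bleach = bleach,
                 kernel = kernel, events = events, noise_sd = noise_sd,
                 seed = as.integer(seed), spectral = spectral),
            class = "fp_scenario")
}

#' Default tone-presentation scenario
#'
#' A 900-second session at 20 Hz with five 10-second tone presentations
#' (onsets 120, 270, 420, 570 and 720 s) marked on a TTL channel, the typical
#' layout of an experimenter-triggered auditory protocol. Peri-event analyses
#' of this scenario conventionally use a 3-second baseline before tone onset
#' and follow the signal until 5 seconds after tone offset.
#'
#' @param ... overrides passed to [scenario_config()].
#' @return an `fp_scenario`.
#' @export
tone_protocol <- function(...) {
  args <- list(
    duration = 900, rate = 20,
    events = data.frame(onset = c(120, 270, 420, 570, 720), length = 10),
    noise_sd = 0.01, seed = 20L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}

#' Transient response kernel
#'
#' Difference-of-exponentials `(1 - exp(-t / tau_rise)) * exp(-t / tau_decay)`
#' for `t >= 0`, normalized so its maximum is exactly 1 (the analytic peak is
#' at `t* = tau_rise * log(1 + tau_decay / tau_rise)`). This is the standard
#' calcium-sensor impulse shape: fast rise, slow decay.
#'
#' @param t times since event onset, seconds (values < 0 give 0).
#' @param tau_rise,tau_decay time constants, seconds.
#' @export
transient_kernel <- function(t, tau_rise, tau_decay) {
  raw <- function(x) (1 - exp(-x / tau_rise)) * exp(-x / tau_decay)
  t_peak <- tau_rise * log(1 + tau_decay / tau_rise)
  out <- ifelse(t >= 0, raw(t) / raw(t_peak), 0)
  out
}

bleach_curve <- function(t, p) p[["a"]] * exp(-p[["b"]] * t) + p[["c"]]

response_trace <- function(cfg, tt) {
  r <- numeric(length(tt))
  amp <- cfg$kernel[["amplitude"]]
  for (i in seq_len(nrow(cfg$events))) {
    r <- r + amp * transient_kernel(tt - cfg$events$onset[i],
                                    cfg$kernel[["tau_rise"]],
                                    cfg$kernel[["tau_decay"]])
  }
  r
}

ttl_trace <- function(cfg, tt) {
  on <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(cfg$events))) {
    s <- cfg$events$onset[i]
    on <- on | (tt >= s & tt < s + cfg$events$length[i])
  }
  as.double(on)
}

#' Simulate a recording from a scenario
#'
#' @param cfg an `fp_scenario`.
#' @return an `fp_recording` with channels `fluorescence` and `ttl`.
#'   Deterministic for a fixed `cfg$seed`.
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "fp_scenario"))
  n <- round(cfg$duration * cfg$rate)
  tt <- (seq_len(n) - 1L) / cfg$rate
  set.seed(cfg$seed)
  eps <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else numeric(n)
  f <- bleach_curve(tt, cfg$bleach) * (1 + response_trace(cfg, tt) + eps)
  fp_recording(list(fluorescence = f, ttl = ttl_trace(cfg, tt)),
               rate = cfg$rate, start_offset = 0, name = "synthetic",
               provenance = sprintf("simulated from scenario (seed %d)", cfg$seed))
}

#' Simulate a spectrally resolved recording
#'
#' Each time frame's emission spectrum is a non-negative mixture of Gaussian
#' reference spectra, `frames[, t] = R %*% coef[, t] + noise`. By default the
#' first fluorophore's coefficient trace is the scenario's fluorescence
#' (baseline times transients) and any further fluorophores carry the bleach
#' baseline only, mimicking an activity sensor recorded alongside a
#' calcium-insensitive control fluorophore.
#'
#' @param cfg an `fp_scenario` whose `spectral` component is a list with
#'   `wavelengths` (nm grid), `means`, `widths` (per-fluorophore Gaussian
#'   emission peak and SD, nm), optional `names`, optional `coefficients`
#'   (K x T matrix of true traces) and optional `noise_sd` (spectral counts).
#' @return list with `spectra` (an [fp_spectra] frame set), `coefficients`
#'   (the true K x T traces) and `recording` (the scalar simulation).
#' @export
simulate_spectral <- function(cfg) {
  stopifnot(inherits(cfg, "fp_scenario"))
  sp <- cfg$spectral
  if (is.null(sp)) stop("scenario has no `spectral` configuration")
  rec <- simulate_recording(cfg)
  n <- n_samples(rec)
  k <- length(sp$means)
  wl <- sp$wavelengths
  nms <- sp$names %||% paste0("fluor", seq_len(k))
  refs <- vapply(seq_len(k),
                 function(j) exp(-(wl - sp$means[j])^2 / (2 * sp$widths[j]^2)),
                 numeric(length(wl)))
  refs <- apply(refs, 2L, function(col) col / max(col))
  coefs <- sp$coefficients
  if (is.null(coefs)) {
    tt <- time_axis(rec)
    coefs <- rbind(rec$channels$fluorescence,
                   matrix(rep(bleach_curve(tt, cfg$bleach), max(k - 1L, 0L)),
                          nrow = max(k - 1L, 0L), byrow = TRUE))
  }
  stopifnot(nrow(coefs) == k, ncol(coefs) == n)
  frames <- refs %*% coefs
  sd_sp <- sp$noise_sd %||% 0
  if (sd_sp > 0) {
    set.seed(cfg$seed + 1L)
    frames <- frames + matrix(stats::rnorm(length(frames), 0, sd_sp),
                              nrow = nrow(frames))
  }
  spectra <- fp_spectra(wavelengths = wl, frames = frames, rate = cfg$rate,
                        references = refs, fluorophores = nms,
                        name = paste0(rec$name, "_spectra"))
  list(spectra = spectra, coefficients = coefs, recording = rec)
}

#' Simulate a behavioral stream at a different rate
#'
#' Emulates a tracking system that records the same event schedule on its own
#' clock: a binary behavior channel at `rate2`, with every event shifted by
#' `latency` seconds. Used to test nearest-neighbor stream alignment.
#'
#' @param cfg an `fp_scenario`.
#' @param rate2 behavioral sampling rate, Hz.
#' @param latency constant delay added to every event, seconds.
#' @return an `fp_recording` with a single `behavior` channel.
#' @export
behavior_stream <- function(cfg, rate2, latency = 0) {
  stopifnot(inherits(cfg, "fp_scenario"), rate2 > 0)
  n2 <- floor(cfg$duration * rate2)
  tt <- (seq_len(n2) - 1L) / rate2
  shifted <- cfg
  shifted$events$onset <- cfg$events$onset + latency
  fp_recording(list(behavior = ttl_trace(shifted, tt)), rate = rate2,
               start_offset = 0, name = "behavior")
}

#' Inject single-sample glitches into a binary channel
#'
#' Flips `n_glitches` isolated zero samples to one, at seeded positions chosen
#' strictly outside (and not adjacent to) existing high periods or each other,
#' so each glitch forms its own one-sample spurious event. Emulates the
#' spurious pulses video-derived behavior scoring produces.
#'
#' @param rec an `fp_recording`.
#' @param channel binary channel name.
#' @param n_glitches number of glitches to inject.
#' @param seed integer seed.
#' @return the modified recording.
#' @export
inject_glitches <- function(rec, channel, n_glitches, seed = 1L) {
  x <- get_channel(rec, channel)
  n <- length(x)
  pad <- c(0, x, 0)
  # candidate i: x[i] and both neighbours are zero
  ok <- which(pad[2:(n + 1)] == 0 & pad[1:n] == 0 & pad[3:(n + 2)] == 0)
  set.seed(seed)
  chosen <- integer(0)
  for (i in sample(ok)) {
    if (length(chosen) == n_glitches) break
    if (all(abs(chosen - i) > 1L)) chosen <- c(chosen, i)
  }
  if (length(chosen) < n_glitches)
    stop("could not place ", n_glitches, " isolated glitches")
  x[chosen] <- 1
  rec$channels[[channel]] <- x
  add_provenance(rec, sprintf("injected %d single-sample glitches into '%s' (seed %d)",
                              n_glitches, channel, seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
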