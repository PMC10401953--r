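#' @name pipeline
#' @title Batch pipeline configuration
#' @description
#' A single YAML document drives the whole batch workflow:
#' import (or simulate) -> transform -> detect events -> normalize ->
#' analyze -> export. Top-level keys:
#' \describe{
#'   \item{seed}{integer; seeds every stochastic stage.}
#'   \item{simulate}{optional scenario: `scenario: tone` or explicit
#'     [scenario_config()] fields, plus optional
#'     `glitches: {channel, count}`.}
#'   \item{imports}{optional list of [read_tabular()] argument sets.}
#'   \item{transforms}{ordered list of steps, each
#'     `{op, dataset, ...args}` where `op` names a transform
#'     (`lowpass_downsample`, `ratio_channel`, `linear_scale`,
#'     `fit_detrend`, `rename_channel`, `align_join`, `append_rows`).}
#'   \item{events}{list of event-series definitions: `name`, `dataset`,
#'     `channel`, `detector` (`{type, ...}`), optional `condition`
#'     (`{expression, mode}`), `filters` (list of `{kind, ...}`),
#'     `intervals` (list of [interval_spec()] fields) and `normalizations`
#'     (list of [norm_spec()] fields).}
#'   \item{analysis}{list of products: `{series, product, ...}` with product
#'     one of `mean_trace`, `heatmap`, `interval_summaries`.}
#'   \item{export}{`{event_tables: {layout, align_by, value}, session:
#'     <file>}`.}
#' }
NULL

config_error <- function(msg, field) {
  stop(structure(class = c("fp_config_error", "error", "condition"),
                 list(message = paste0(msg, " [at ", field, "]"),
                      call = NULL, field = field)))
}

req <- function(x, name, field) {
  if (is.null(x[[name]])) config_error(paste0("missing required key '", name, "'"), field)
  x[[name]]
}

#' Validate a pipeline configuration
#'
#' Structural checks run before anything executes; violations raise an
#' `fp_config_error` (CLI exit code 2) naming the offending field path.
#'
#' @param cfg parsed configuration list.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$simulate) && is.null(cfg$imports))
    config_error("need `simulate` and/or `imports`", "(top level)")
  known <- character()
  if (!is.null(cfg$simulate)) known <- c(known, cfg$simulate$name %||% "synthetic")
  for (i in seq_along(cfg$imports)) {
    im <- cfg$imports[[i]]
    p <- req(im, "path", sprintf("imports[%d]", i))
    known <- c(known, im$name %||% tools::file_path_sans_ext(basename(p)))
  }
  for (i in seq_along(cfg$transforms)) {
    tr <- cfg$transforms[[i]]
    f <- sprintf("transforms[%d]", i)
    req(tr, "op", f)
    ds <- req(tr, "dataset", f)
    if (!ds %in% known)
      config_error(paste0("unknown dataset '", ds, "'"), paste0(f, ".dataset"))
  }
  for (i in seq_along(cfg$events)) {
    ed <- cfg$events[[i]]
    f <- sprintf("events[%d]", i)
    req(ed, "name", f)
    ds <- req(ed, "dataset", f)
    if (!ds %in% known)
      config_error(paste0("unknown dataset '", ds, "'"), paste0(f, ".dataset"))
    det <- req(ed, "detector", f)
    req(det, "type", paste0(f, ".detector"))
  }
  series_names <- vapply(cfg$events, function(e) e$name, character(1))
  for (i in seq_along(cfg$analysis)) {
    an <- cfg$analysis[[i]]
    f <- sprintf("analysis[%d]", i)
    sr <- req(an, "series", f)
    req(an, "product", f)
    if (length(series_names) && !sr %in% series_names)
      config_error(paste0("unknown event series '", sr, "'"), paste0(f, ".series"))
  }
  invisible(cfg)
}

scenario_from_config <- function(sim, seed) {
  if (identical(sim$scenario, "tone")) {
    extra <- sim[intersect(names(sim), c("duration", "rate", "noise_sd", "seed"))]
    do.call(tone_protocol, c(extra, if (is.null(sim$seed)) list(seed = seed)))
  } else {
    ev <- sim$events
    ev <- data.frame(onset = vapply(ev, `[[`, numeric(1), "onset"),
                     length = vapply(ev, `[[`, numeric(1), "length"))
    scenario_config(duration = sim$duration, rate = sim$rate,
                    bleach = unlist(sim$bleach %||% c(a = 2, b = 0.001, c = 1)),
                    kernel = unlist(sim$kernel %||%
                                      c(amplitude = 0.2, tau_rise = 0.5, tau_decay = 2)),
                    events = ev, noise_sd = sim$noise_sd %||% 0.01,
                    seed = sim$seed %||% seed)
  }
}

run_transform <- function(recs, tr) {
  rec <- recs[[tr$dataset]]
  recs[[tr$dataset]] <- switch(tr$op,
    lowpass_downsample = lowpass_downsample(rec, tr$cutoff, tr$factor %||% 1L),
    ratio_channel = ratio_channel(rec, tr$num, tr$den),
    linear_scale = linear_scale(rec, tr$channel, tr$gain %||% 1,
                                tr$offset %||% 0, tr$match_to),
    rename_channel = rename_channel(rec, tr$old, tr$new),
    fit_detrend = {
      model <- fit_bleach(rec, tr$channel, tr$form %||% "exponential")
      detrend(rec, tr$channel, model, tr$mode %||% "dff")
    },
    align_join = align_join(rec, recs[[tr$other]], tr$channels %||%
                              names(recs[[tr$other]]$channels)),
    append_rows = append_rows(rec, recs[[tr$other]]),
    stop("unknown transform op '", tr$op, "'"))
  recs
}

run_detector <- function(rec, det, field) {
  type <- det$type
  if (type %in% c("binary", "inverted", "peak") ) {
    v <- det$variable %||% config_error("detector needs `variable`", field)
    if (!v %in% names(rec$channels))
      config_error(paste0("channel '", v, "' not found in dataset '",
                          rec$name, "'"), paste0(field, ".variable"))
  }
  switch(type,
    binary = detect_binary(rec, det$variable),
    inverted = detect_binary(rec, det$variable, inverted = TRUE),
    binned = detect_binned(rec, det$t %||% rec$start_offset, det$L),
    peak = detect_peaks(rec, det$variable, det$L, det$k),
    timestamped = detect_timestamped(rec, data.frame(
      start = vapply(det$stamps, `[[`, numeric(1), "start"),
      end = vapply(det$stamps, `[[`, numeric(1), "end"))),
    config_error(paste0("unknown detector type '", type, "'"),
                 paste0(field, ".type")))
}

build_event_table <- function(rec, ed, field) {
  series <- run_detector(rec, ed$detector, paste0(field, ".detector"))
  if (!is.null(ed$condition))
    series <- apply_condition(series, rec, ed$condition$expression,
                              ed$condition$mode %||% "entire")
  if (length(ed$filters)) {
    steps <- lapply(ed$filters, function(fl) do.call(filter_step, fl))
    series <- apply_filters(series, steps)
  }
  ivs <- lapply(ed$intervals %||% list(list(name = "signal",
                                            reference = "event_signal")),
                function(iv) do.call(interval_spec, iv))
  channel <- ed$channel %||% config_error("event definition needs `channel`", field)
  if (!channel %in% names(rec$channels))
    config_error(paste0("channel '", channel, "' not found in dataset '",
                        rec$name, "'"), paste0(field, ".channel"))
  tbl <- resolve_intervals(series, ivs, rec, channel)
  if (length(ed$normalizations) && nrow(tbl)) {
    specs <- lapply(ed$normalizations, function(ns) do.call(norm_spec, ns))
    names(specs) <- vapply(ed$normalizations,
                           function(ns) ns$name %||% ns$scheme, character(1))
    tbl <- normalize_events(tbl, specs)
  }
  list(series = series, table = tbl, intervals = ivs)
}

write_stable_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, na = "")
  path
}

#' Run the batch pipeline from a configuration file
#'
#' Executes import/simulate -> transforms -> event detection + normalization
#' -> analysis products -> export, writing all artifacts plus a
#' machine-readable `run_log.json` (inputs, seed, per-stage counts) under
#' `out_dir`. Fully deterministic for a fixed config + seed.
#'
#' @param config path to a YAML configuration, or an already-parsed list
#'   (see [pipeline]).
#' @param out_dir output directory, created if needed.
#' @param seed optional integer overriding the config seed.
#' @return invisibly, a list with `recordings`, `series`, `tables`,
#'   `artifacts` (written paths) and `log`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(config = if (is.character(config)) basename(config) else "(inline)",
              seed = seed, package_version = as.character(utils::packageVersion("fpeta")),
              stages = list())
  note <- function(stage, ...) {
    log$stages[[length(log$stages) + 1L]] <<- c(list(stage = stage), list(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "fp_config_error")) stop(e)      # keep class: exit 2
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  artifacts <- character()
  set.seed(seed)

  recs <- list()
  stage("import", {
    if (!is.null(cfg$simulate)) {
      sc <- scenario_from_config(cfg$simulate, seed)
      rec <- simulate_recording(sc)
      rec$name <- cfg$simulate$name %||% rec$name
      if (!is.null(cfg$simulate$glitches)) {
        g <- cfg$simulate$glitches
        rec <- inject_glitches(rec, g$channel, g$count, seed = g$seed %||% seed)
      }
      recs[[rec$name]] <- rec
      note("simulate", dataset = rec$name, samples = n_samples(rec))
    }
    for (im in cfg$imports) {
      rec <- do.call(read_tabular, im)
      recs[[rec$name]] <- rec
      note("import", dataset = rec$name, samples = n_samples(rec))
    }
  })
  stage("transform", for (tr in cfg$transforms) {
    recs <- run_transform(recs, tr)
    note("transform", op = tr$op, dataset = tr$dataset)
  })
  series <- list(); tables <- list(); intervals <- list()
  stage("events", for (i in seq_along(cfg$events)) {
    ed <- cfg$events[[i]]
    res <- build_event_table(recs[[ed$dataset]], ed, sprintf("events[%d]", i))
    series[[ed$name]] <- res$series
    tables[[ed$name]] <- res$table
    intervals[[ed$name]] <- res$intervals
    note("events", series = ed$name, events = n_events(res$series),
         rows = nrow(res$table))
    p <- write_stable_csv(as.data.frame(res$table),
                          file.path(out_dir, paste0("events_", ed$name, ".csv")))
    artifacts <- c(artifacts, p)
  })
  stage("analyze", for (i in seq_along(cfg$analysis)) {
    an <- cfg$analysis[[i]]
    tbl <- tables[[an$series]]
    rate <- recs[[cfg$events[[which(vapply(cfg$events, `[[`, character(1), "name")
                                    == an$series)]]$dataset]]$rate
    out <- switch(an$product,
      mean_trace = {
        al <- event_traces(tbl, value = an$value %||% "value", rate = rate)
        mean_trace(al, band = an$band %||% "sd", multiplier = an$multiplier %||% 1)
      },
      heatmap = {
        al <- event_traces(tbl, value = an$value %||% "value", rate = rate)
        hm <- heatmap_matrix(al, sort = an$sort %||% "order",
                             auc_window = unlist(an$auc_window))
        cbind(data.frame(event = hm$order),
              stats::setNames(as.data.frame(hm$matrix),
                              sprintf("t%.6g", hm$t_event)))
      },
      interval_summaries = interval_summaries(tbl, stat = an$stat %||% "mean",
                                              value = an$value %||% "value",
                                              auc_window = unlist(an$auc_window)),
      stop("unknown analysis product '", an$product, "'"))
    p <- write_stable_csv(out, file.path(out_dir,
           sprintf("%s_%s_%d.csv", an$series, an$product, i)))
    artifacts <- c(artifacts, p)
    note("analyze", series = an$series, product = an$product, rows = nrow(out))
  })
  stage("export", {
    if (!is.null(cfg$export$event_tables)) {
      ex <- cfg$export$event_tables
      for (nm in names(tables)) {
        if (!nrow(tables[[nm]])) next
        ps <- export_event_table(tables[[nm]], dir = out_dir,
                                 layout = ex$layout %||% "long",
                                 align_by = ex$align_by %||% "time",
                                 value = ex$value %||% "value",
                                 rate = recs[[1L]]$rate,
                                 human_readable = isTRUE(ex$human_readable))
        artifacts <- c(artifacts, ps)
      }
    }
    sess_file <- cfg$export$session %||% "session.json"
    sess <- fp_session(recordings = recs, event_series = series,
                       interval_tables = intervals,
                       settings = list(seed = seed))
    p <- save_session(sess, file.path(out_dir, sess_file))
    artifacts <- c(artifacts, p)
    note("export", artifacts = length(artifacts))
  })
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, log_path)
  invisible(list(recordings = recs, series = series, tables = tables,
                 artifacts = artifacts, log = log))
}

#' Command-line entry point
#'
#' Thin argument parser over [run_pipeline()] and the session tools, used by
#' the `inst/cli/fpeta.R` script. Subcommands:
#' `run --config <yaml> --out-dir <dir> [--seed <int>]`;
#' `simulate --scenario tone --out-dir <dir> [--seed <int>]`;
#' `session info <file>`; every subcommand accepts `--help`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 on success, 1 on a stage failure, 2 on a
#'   configuration/usage error.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fpeta <subcommand> [options]",
    "  run       --config <yaml> --out-dir <dir> [--seed <int>]",
    "  simulate  --scenario tone --out-dir <dir> [--seed <int>]",
    "  session   info <file.json>", sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0L) return(default)
    if (i[1L] == length(args)) return(default)
    args[i[1L] + 1L]
  }
  if (length(args) == 0L || args[1L] %in% c("--help", "-h", "help")) {
    cat(usage, "\n"); return(0L)
  }
  sub <- args[1L]
  if ("--help" %in% args) { cat(usage, "\n"); return(0L) }
  res <- tryCatch({
    if (sub == "run") {
      config <- opt("--config"); out <- opt("--out-dir")
      if (is.null(config) || is.null(out))
        config_error("run needs --config and --out-dir", "(cli)")
      run_pipeline(config, out, seed = opt("--seed"))
      0L
    } else if (sub == "simulate") {
      out <- opt("--out-dir")
      if (is.null(out)) config_error("simulate needs --out-dir", "(cli)")
      if (!identical(opt("--scenario", "tone"), "tone"))
        config_error("only the 'tone' scenario ships built in", "(cli)")
      seed <- as.integer(opt("--seed", "20"))
      rec <- simulate_recording(tone_protocol(seed = seed))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_tabular(rec, file.path(out, "recording.csv"))
      save_session(fp_session(recordings = list(rec),
                              settings = list(seed = seed)),
                   file.path(out, "session.json"))
      0L
    } else if (sub == "session") {
      if (length(args) < 3L || args[2L] != "info")
        config_error("usage: session info <file>", "(cli)")
      s <- load_session(args[3L])
      cat(sprintf("session: %d recording(s), %d event series\n",
                  length(s$recordings), length(s$event_series)))
      0L
    } else {
      config_error(paste0("unknown subcommand '", sub, "'"), "(cli)")
    }
  },
  fp_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  res
}
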