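#' Read a tabular recording from a delimited text file
#'
#' Handles the layout acquisition software typically emits: an arbitrary
#' preamble, a header row, then data rows. Time comes either from a stated
#' sampling rate (plus offset) or from a time column; an explicit time column
#' with jitter is resampled by nearest neighbor onto a uniform grid at the
#' stated (or median-spacing-derived) rate, and the resampling is logged in
#' provenance. Non-numeric cells become missing values.
#'
#' @param path file path (`.csv`, `.tsv`, `.txt`; decimal separator `.`).
#' @param delimiter field delimiter (default inferred from the extension:
#'   `","` except `"\t"` for `.tsv`).
#' @param header_row 1-based line number of the header row.
#' @param data_row 1-based line number of the first data row
#'   (`> header_row`); intervening lines are ignored.
#' @param channels character vector of channel columns to import (default:
#'   every numeric column except the time column), optionally named to
#'   rename (`c(file_col = "new_name")` is given as `c(new_name = "file_col")`).
#' @param time_col name of an explicit time column (seconds), mutually
#'   exclusive with `rate`.
#' @param rate stated sampling rate, Hz (with `start_offset`).
#' @param start_offset clock time of the first sample when `rate` is given.
#' @param name dataset name (default: file base name).
#' @return an `fp_recording`.
#' @export
read_tabular <- function(path, delimiter = NULL, header_row = 1L,
                         data_row = header_row + 1L, channels = NULL,
                         time_col = NULL, rate = NULL, start_offset = 0,
                         name = NULL) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE))
    stop("workbook (.xlsx) import is not supported; export the sheet as CSV")
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(time_col) == is.null(rate))
    stop("give exactly one time source: `time_col` or `rate`")
  if (data_row <= header_row) stop("`data_row` must be below `header_row`")
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < data_row) stop("empty data region in ", path)
  split1 <- function(s) strsplit(s, delimiter, fixed = TRUE)[[1L]]
  header <- trimws(split1(lines[header_row]))
  cells <- lapply(lines[data_row:length(lines)], split1)
  cells <- cells[vapply(cells, length, integer(1)) > 0L]
  if (length(cells) == 0L) stop("empty data region in ", path)
  mat <- do.call(rbind, lapply(cells, function(r) {
    length(r) <- length(header)
    suppressWarnings(as.numeric(trimws(r)))
  }))
  colnames(mat) <- header
  pick <- channels %||% setdiff(header, time_col)
  missing_cols <- setdiff(unname(pick), header)
  if (length(missing_cols))
    stop("column(s) not in file: ", paste(missing_cols, collapse = ", "))
  out_names <- if (is.null(names(pick))) unname(pick) else
    ifelse(nzchar(names(pick)), names(pick), unname(pick))
  chans <- stats::setNames(lapply(unname(pick), function(cn) mat[, cn]), out_names)
  prov <- sprintf("imported %d rows from %s (header row %d, data row %d)",
                  nrow(mat), basename(path), header_row, data_row)
  if (!is.null(time_col)) {
    if (!time_col %in% header) stop("column(s) not in file: ", time_col)
    tt <- mat[, time_col]
    if (anyNA(tt)) stop("time column '", time_col, "' has non-numeric entries")
    dt <- stats::median(diff(tt))
    if (!is.finite(dt) || dt <= 0) stop("time column is not increasing")
    rate <- 1 / dt
    start_offset <- tt[1L]
    grid <- start_offset + (seq_along(tt) - 1L) / rate
    jitter <- max(abs(tt - grid))
    if (jitter > 1e-6 / rate) {
      nn <- vapply(grid, function(g) which.min(abs(tt - g)), integer(1))
      chans <- lapply(chans, `[`, nn)
      prov <- c(prov, sprintf(
        "jittery time column resampled (nearest neighbor) to %g Hz; max jitter %g s",
        rate, jitter))
    }
  }
  fp_recording(chans, rate = rate, start_offset = start_offset,
               name = name %||% tools::file_path_sans_ext(basename(path)),
               provenance = prov)
}

#' Write a recording as a delimited text file
#'
#' One `time` column plus one column per channel; full double precision.
#'
#' @param rec an `fp_recording`.
#' @param path output path.
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(rec, path, delimiter = ",") {
  df <- as.data.frame(c(list(time = time_axis(rec)), rec$channels),
                      check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrometer matrix with reference spectra
#'
#' The data file carries the wavelength grid in one row (`wavelength_row`)
#' and one time frame per row from `data_row` on. The reference file holds
#' the standard emission spectrograms of the fluorophores: either a shared
#' wavelength grid (first column wavelength, one column per fluorophore) or
#' wavelength/intensity column pairs per fluorophore (`layout = "paired"`).
#' References are linearly interpolated onto the data grid with endpoints
#' clamped; non-overlapping wavelength ranges are an error.
#'
#' @param path spectrometer data file (delimited text).
#' @param reference_path reference spectra file.
#' @param rate collection frequency, Hz (> 0).
#' @param wavelength_row 1-based line holding the wavelength grid.
#' @param data_row 1-based line of the first frame.
#' @param delimiter field delimiter.
#' @param layout reference file layout, `"shared"` or `"paired"`.
#' @param name dataset name.
#' @return an [fp_spectra].
#' @export
read_spectral <- function(path, reference_path, rate, wavelength_row = 1L,
                          data_row = 2L, delimiter = ",",
                          layout = c("shared", "paired"), name = NULL) {
  layout <- match.arg(layout)
  if (rate <= 0) stop("collection frequency must be > 0")
  lines <- readLines(path, warn = FALSE)
  split1 <- function(s) suppressWarnings(as.numeric(strsplit(s, delimiter, fixed = TRUE)[[1L]]))
  wl <- split1(lines[wavelength_row])
  wl <- wl[!is.na(wl)]
  if (anyDuplicated(wl) || any(diff(wl) <= 0))
    stop("wavelength row must be strictly increasing with no duplicates")
  frames <- t(do.call(rbind, lapply(lines[data_row:length(lines)], split1)))
  if (nrow(frames) != length(wl))
    stop("frame rows have ", nrow(frames), " values but the wavelength row has ",
         length(wl))
  ref_tab <- utils::read.table(reference_path, sep = delimiter, header = TRUE,
                               check.names = FALSE)
  interp <- function(w, v) {
    if (max(w) < min(wl) || min(w) > max(wl))
      stop("reference wavelength range [", min(w), ", ", max(w),
           "] nm does not overlap the data grid")
    stats::approx(w, v, xout = wl, rule = 2)$y
  }
  if (layout == "shared") {
    w <- ref_tab[[1L]]
    refs <- vapply(ref_tab[-1L], function(v) interp(w, v), numeric(length(wl)))
    fl <- names(ref_tab)[-1L]
  } else {
    if (ncol(ref_tab) %% 2L != 0L)
      stop("paired layout needs an even number of columns")
    ks <- seq(1L, ncol(ref_tab), by = 2L)
    refs <- vapply(ks, function(j) interp(ref_tab[[j]], ref_tab[[j + 1L]]),
                   numeric(length(wl)))
    fl <- names(ref_tab)[ks + 1L]
  }
  fp_spectra(wavelengths = wl, frames = frames, rate = rate, references = refs,
             fluorophores = fl,
             name = name %||% tools::file_path_sans_ext(basename(path)))
}

# ---- event-table export ------------------------------------------------

#' Pivot an event table to wide layout
#'
#' One value column per event. With `align_by = "time"` rows are keyed by
#' `t_event`, so equal peri-event times line up across events and shorter
#' events leave blanks; with `align_by = "interval"` each interval type
#' starts on a common row and rows within an interval are aligned by sample
#' position, so like intervals can be compared even when events are ragged.
#'
#' @param tbl an `fp_event_table`.
#' @param value value column to spread.
#' @param align_by `"time"` or `"interval"`.
#' @param rate sampling rate, Hz (grid for the `t_event` key).
#' @return data.frame with key columns and one `event_<i>` column per event.
#' @export
event_table_wide <- function(tbl, value = "value", align_by = c("time", "interval"),
                             rate) {
  align_by <- match.arg(align_by)
  evs <- sort(unique(tbl$event))
  if (align_by == "time") {
    key <- grid_key(tbl$t_event, rate)
    all_keys <- sort(unique(key))
    out <- data.frame(t_event = all_keys / rate)
    for (ev in evs) {
      sel <- tbl$event == ev
      col <- rep(NA_real_, length(all_keys))
      col[match(key[sel], all_keys)] <- tbl[[value]][sel]
      out[[paste0("event_", ev)]] <- col
    }
    out
  } else {
    ivs <- unique(tbl$interval)
    blocks <- lapply(ivs, function(iv) {
      sub <- tbl[tbl$interval == iv, , drop = FALSE]
      depth <- max(tapply(seq_len(nrow(sub)), sub$event, length))
      out <- data.frame(interval = rep(iv, depth), row = seq_len(depth))
      for (ev in evs) {
        v <- sub[[value]][sub$event == ev]
        out[[paste0("event_", ev)]] <- c(v, rep(NA_real_, depth - length(v)))
      }
      out
    })
    do.call(rbind, blocks)
  }
}

#' Melt a time-aligned wide table back to long rows
#'
#' Inverse of [event_table_wide()] for `align_by = "time"`: blank cells are
#' dropped, so the row set matches the original samples.
#'
#' @param wide output of `event_table_wide(..., align_by = "time")`.
#' @return data.frame with `event`, `t_event`, `value`.
#' @export
event_table_long <- function(wide) {
  cols <- setdiff(names(wide), "t_event")
  rows <- lapply(cols, function(cn) {
    ok <- !is.na(wide[[cn]])
    data.frame(event = as.integer(sub("^event_", "", cn)),
               t_event = wide$t_event[ok], value = wide[[cn]][ok])
  })
  out <- do.call(rbind, rows)
  out[order(out$event, out$t_event), , drop = FALSE]
}

#' Export an event table to CSV files
#'
#' Writes one CSV per dataset (the diff-friendly stand-in for workbook tabs).
#' The default long layout is machine-readable: one row per sample. The wide
#' layout gives one column per event, aligned across events by time or by
#' interval type. `human_readable` adds the interval label and all three
#' timestamp columns (raw dataset time, time within the interval, and time
#' relative to the event-signal start) to wide output; long output always
#' carries them.
#'
#' @param tbl an `fp_event_table` (optionally normalized).
#' @param dir output directory (created if needed).
#' @param layout `"long"` or `"wide"`.
#' @param align_by `"time"` or `"interval"` (wide layout).
#' @param value value column for the wide layout.
#' @param rate sampling rate, Hz (required for wide/time alignment).
#' @param human_readable add labels and timestamps to wide output.
#' @return character vector of written file paths, invisibly.
#' @export
export_event_table <- function(tbl, dir, layout = c("long", "wide"),
                               align_by = c("time", "interval"),
                               value = "value", rate = NULL,
                               human_readable = FALSE) {
  layout <- match.arg(layout)
  align_by <- match.arg(align_by)
  if (nrow(tbl) == 0L) stop("cannot export an empty event table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (ds in unique(tbl$dataset)) {
    sub <- tbl[tbl$dataset == ds, , drop = FALSE]
    out <- if (layout == "long") {
      as.data.frame(sub)
    } else {
      if (align_by == "time" && is.null(rate))
        stop("wide/time export needs `rate`")
      w <- event_table_wide(sub, value = value, align_by = align_by, rate = rate)
      if (human_readable && align_by == "time") {
        lab <- sub[!duplicated(grid_key(sub$t_event, rate)), ]
        i <- match(grid_key(w$t_event, rate), grid_key(lab$t_event, rate))
        cbind(data.frame(interval = lab$interval[i],
                         t_dataset = lab$t_dataset[i],
                         t_interval = lab$t_interval[i]), w)
      } else w
    }
    p <- file.path(dir, paste0(make.names(ds), "_", layout, ".csv"))
    utils::write.csv(out, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

# ---- sessions ----------------------------------------------------------

SESSION_VERSION <- "1"

#' Bundle pipeline state into a session
#'
#' @param recordings list of `fp_recording`s.
#' @param event_series list of `fp_events`.
#' @param interval_tables list of lists of [interval_spec()]s.
#' @param settings arbitrary named list (seeds, parameters).
#' @return a list of class `fp_session`.
#' @export
fp_session <- function(recordings = list(), event_series = list(),
                       interval_tables = list(), settings = list()) {
  structure(list(recordings = recordings, event_series = event_series,
                 interval_tables = interval_tables, settings = settings),
            class = "fp_session")
}

#' Save an analysis session
#'
#' Serializes recordings, event series, interval tables and settings into a
#' single schema-versioned JSON container. Doubles are written at full
#' precision, so a load reproduces every sample and event time exactly.
#'
#' @param session an `fp_session`.
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "fp_session"))
  payload <- list(
    container = "fpeta-session", version = SESSION_VERSION,
    recordings = lapply(session$recordings, unclass),
    event_series = lapply(session$event_series, function(s) {
      s <- unclass(s); s$events <- as.list(s$events); s
    }),
    interval_tables = lapply(session$interval_tables,
                             function(tab) lapply(tab, unclass)),
    settings = session$settings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Load an analysis session
#'
#' @param path a file written by [save_session()].
#' @return the restored `fp_session`.
#' @export
load_session <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE),
                      error = function(e)
                        stop("cannot read session file ", path, ": ",
                             conditionMessage(e)))
  if (!identical(payload$container, "fpeta-session"))
    stop("not a session container: ", path)
  if (!identical(as.character(payload$version), SESSION_VERSION))
    stop("session version mismatch: file has '", payload$version,
         "', this package reads '", SESSION_VERSION, "'")
  recs <- lapply(payload$recordings, function(r)
    fp_recording(as.list(r$channels), rate = r$rate,
                 start_offset = r$start_offset, name = r$name,
                 provenance = unlist(r$provenance) %||% character()))
  series <- lapply(payload$event_series, function(s) {
    ev <- data.frame(start = as.double(s$events$start %||% numeric()),
                     end = as.double(s$events$end %||% numeric()))
    fp_events(ev, definition = s$definition, dataset = s$dataset,
              span = unlist(s$span))
  })
  tabs <- lapply(payload$interval_tables, function(tab) {
    lapply(tab, function(iv)
      interval_spec(iv$name, iv$reference, iv$start_off, iv$end_off))
  })
  fp_session(recordings = recs, event_series = series,
             interval_tables = tabs, settings = payload$settings %||% list())
}
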