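#' Spectrally resolved frame set
#'
#' Holds a wavelength-by-frame intensity matrix together with the reference
#' emission spectra needed for linear unmixing. Reference columns are
#' max-normalized to 1 at construction (unmixed coefficients are then in the
#' units of the recorded intensities at each fluorophore's emission peak).
#'
#' @param wavelengths strictly increasing wavelength grid, nm (length W).
#' @param frames W x T intensity matrix, one column per time frame.
#' @param rate frame rate, Hz.
#' @param references W x K matrix of non-negative reference spectra.
#' @param fluorophores length-K character vector of fluorophore names.
#' @param name dataset name.
#' @return an object of class `fp_spectra`.
#' @export
fp_spectra <- function(wavelengths, frames, rate, references, fluorophores,
                       name = "spectra") {
  wavelengths <- as.double(wavelengths)
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  frames <- as.matrix(frames)
  references <- as.matrix(references)
  if (nrow(frames) != length(wavelengths))
    stop("`frames` must have one row per wavelength")
  if (nrow(references) != length(wavelengths))
    stop("`references` must share the wavelength grid of `frames`")
  if (ncol(references) != length(fluorophores))
    stop("need one fluorophore name per reference column")
  if (any(references < 0)) stop("reference spectra must be non-negative")
  peaks <- apply(references, 2L, max)
  if (any(peaks <= 0)) stop("reference spectra must not be all-zero")
  references <- sweep(references, 2L, peaks, "/")
  colnames(references) <- fluorophores
  structure(list(wavelengths = wavelengths, frames = frames,
                 rate = as.double(rate), references = references,
                 fluorophores = as.character(fluorophores),
                 name = as.character(name)),
            class = "fp_spectra")
}

#' @export
print.fp_spectra <- function(x, ...) {
  cat(sprintf("<fp_spectra> %s: %d wavelengths (%g-%g nm) x %d frames @ %g Hz\n",
              x$name, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), ncol(x$frames), x$rate))
  cat("  fluorophores:", paste(x$fluorophores, collapse = ", "), "\n")
  invisible(x)
}

#' Linear unmixing of spectral frames
#'
#' Decomposes each frame's observed spectrum into per-fluorophore
#' contributions by least squares against the reference spectra: for frame
#' `t`, the coefficients minimize `|| frames[, t] - R %*% c ||_2`, subject to
#' `c >= 0` when `nonneg = TRUE` (fluorescence contributions are physically
#' non-negative). Frames whose unconstrained solution is already non-negative
#' take it directly; only the remainder are solved by non-negative least
#' squares, which keeps long recordings fast without changing the result.
#'
#' @param fs an `fp_spectra`.
#' @param nonneg constrain coefficients to be non-negative (default TRUE).
#' @return an `fp_recording` at the frame rate with one channel per
#'   fluorophore.
#' @export
unmix <- function(fs, nonneg = TRUE) {
  stopifnot(inherits(fs, "fp_spectra"))
  R <- fs$references
  k <- ncol(R)
  if (k > nrow(R)) stop("more fluorophores than wavelengths: underdetermined")
  qrR <- qr(R)
  if (qrR$rank < k) {
    dropped <- fs$fluorophores[qrR$pivot[(qrR$rank + 1):k]]
    stop("reference spectra are collinear; offending fluorophore(s): ",
         paste(dropped, collapse = ", "))
  }
  coef <- qr.coef(qrR, fs$frames)              # K x T unconstrained solution
  if (nonneg) {
    bad <- which(apply(coef < -1e-12, 2L, any))
    for (t in bad) {
      coef[, t] <- pracma::lsqnonneg(R, fs$frames[, t])$x
    }
    coef[coef < 0] <- 0
  }
  chans <- stats::setNames(lapply(seq_len(k), function(j) coef[j, ]),
                           fs$fluorophores)
  fp_recording(chans, rate = fs$rate, start_offset = 0, name = fs$name,
               provenance = sprintf("linear unmixing (%s) of %d frames against %d references",
                                    if (nonneg) "non-negative" else "unconstrained",
                                    ncol(fs$frames), k))
}

range_idx <- function(wavelengths, range, what) {
  idx <- which(wavelengths >= range[1] & wavelengths <= range[2])
  if (length(idx) == 0L)
    stop(what, " range [", range[1], ", ", range[2],
         "] nm contains no recorded wavelengths")
  idx
}

summary_stat <- function(frames, wl, idx, stat) {
  sub <- frames[idx, , drop = FALSE]
  switch(stat,
         mean = colMeans(sub),
         median = apply(sub, 2L, stats::median),
         auc = {
           if (length(idx) < 2L)
             stop("stat = 'auc' needs at least 2 wavelengths in the range")
           apply(sub, 2L, function(v) trapezoid_auc(wl[idx], v))
         },
         stop("unknown stat '", stat, "'"))
}

#' Wavelength-range summary ratio signal
#'
#' The alternative to full unmixing when emission spectra overlap: summarize
#' each frame over two user-chosen wavelength bands (closed intervals on the
#' recorded grid) with a summary statistic, take the ratio
#' numerator / denominator, and optionally detrend the ratio trace by a
#' fitted exponential bleaching model (divisive: trace / fit - 1; a
#' subtractive variant is available).
#'
#' @param fs an `fp_spectra`.
#' @param range_num,range_den numeric length-2 wavelength bounds, nm.
#' @param stat one of `"auc"`, `"mean"`, `"median"`.
#' @param detrend detrend the ratio trace (default TRUE).
#' @param detrend_mode `"divisive"` (`x / fit - 1`) or `"subtractive"`
#'   (`x - fit`).
#' @return an `fp_recording` with a single `ratio` channel.
#' @export
summary_signal <- function(fs, range_num, range_den, stat = c("auc", "mean", "median"),
                           detrend = TRUE,
                           detrend_mode = c("divisive", "subtractive")) {
  stopifnot(inherits(fs, "fp_spectra"))
  stat <- match.arg(stat)
  detrend_mode <- match.arg(detrend_mode)
  wl <- fs$wavelengths
  num <- summary_stat(fs$frames, wl, range_idx(wl, range_num, "numerator"), stat)
  den <- summary_stat(fs$frames, wl, range_idx(wl, range_den, "denominator"), stat)
  zero <- which(den == 0)
  if (length(zero))
    stop("denominator summary is exactly 0 at frame(s) ",
         paste(utils::head(zero, 5L), collapse = ", "))
  ratio <- num / den
  rec <- fp_recording(list(ratio = ratio), rate = fs$rate, start_offset = 0,
                      name = fs$name,
                      provenance = sprintf("summary ratio (%s) of [%g,%g]/[%g,%g] nm",
                                           stat, range_num[1], range_num[2],
                                           range_den[1], range_den[2]))
  if (detrend) {
    model <- fit_bleach(rec, "ratio", form = "exponential")
    rec <- detrend(rec, "ratio", model,
                   mode = if (detrend_mode == "divisive") "dff" else "residual")
  }
  rec
}
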