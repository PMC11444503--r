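# Ciliary beat frequency by Fourier power-spectral analysis of small
# subregions, ranked by peak sharpness.

# Hann-windowed periodogram, zero-padded to the next power of two.
# Returns freqs (Hz, 0..fps/2) and power.
periodogram_hann <- function(x, fps) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xs <- (x - mean(x)) * w
  N <- 2^ceiling(log2(n))
  P <- Mod(stats::fft(c(xs, numeric(N - n))))^2
  half <- seq_len(N %/% 2 + 1L)
  list(freqs = fps * (half - 1L) / N, power = P[half], n_native = n)
}

# characterise one tile spectrum: peak, sharpness, secondary peaks
spectrum_stats <- function(sp, fps, hp_cutoff, reject_frac) {
  f <- sp$freqs; P <- sp$power
  band <- f > hp_cutoff & f <= 0.45 * fps
  if (!any(band)) stop("empty peak-search band; check hp cutoff vs fps")
  ib <- which(band)
  peak_i <- ib[which.max(P[ib])]
  peak_hz <- f[peak_i]
  bw <- 2 * fps / sp$n_native              # half-width: two native bins
  region <- abs(f - peak_hz) <= bw & f > 0
  total <- sum(P[f > 0])
  sharp <- if (total > 0) sum(P[region]) / total else 0
  out <- band & !region
  second <- if (any(out)) max(P[out]) else 0
  io <- which(out)
  locmax <- io[io > 1 & io < length(P) &
               P[io] > P[io - 1L] & P[io] >= P[io + 1L] &
               P[io] >= reject_frac * P[peak_i]]
  list(peak_hz = peak_hz, sharpness = sharp,
       n_peaks = 1L + length(locmax),
       multi_peak = second >= reject_frac * P[peak_i])
}

#' Power spectra of 3x3 pixel subregions
#'
#' Tiles the ROI with non-overlapping 3x3 pixel tiles and, for every tile
#' containing at least one oscillatory pixel, computes the Hann-windowed
#' power spectrum (zero-padded to the next power of two) of the tile-mean
#' time series.  Each tile is characterised by its peak frequency within
#' the search band `(hp_cutoff, 0.45*fps)`, its peak sharpness (power
#' within two native frequency bins of the peak divided by total power),
#' and whether a secondary local maximum exceeds `reject_frac` of the
#' primary peak (a spurious, multi-peaked spectrum).
#'
#' @param stack A high-pass-filtered [video_stack()].
#' @param map A [detect_oscillatory_pixels()] result.
#' @param roi The [roi_config()] (supplies `hp_cutoff_hz`, `reject_frac`).
#' @return An object of class `"subregion_spectra"`: `table` (data.frame
#'   with tile centre `y`, `x`, `peak_hz`, `sharpness`, `n_peaks`,
#'   `multi_peak`), `power` (matrix, one column per tile), `freqs`, `fps`.
#' @export
subregion_spectra <- function(stack, map, roi) {
  stopifnot(inherits(stack, "video_stack"), inherits(map, "cilia_map"))
  d <- dim(stack$frames)
  if (d[1] < 64L)
    stop("need at least 64 frames for adequate frequency resolution")
  fps <- stack$calibration$fps
  ny <- length(map$y_rows); nx <- length(map$x_cols)
  sub <- stack$frames[, map$y_rows, map$x_cols, drop = FALSE]
  dim(sub) <- c(d[1], ny * nx)
  rows <- list(); powers <- list()
  for (iy in seq_len(ny %/% 3L)) {
    yy <- (3L * iy - 2L):(3L * iy)
    for (ix in seq_len(nx %/% 3L)) {
      xx <- (3L * ix - 2L):(3L * ix)
      if (!any(map$active[yy, xx])) next
      cols <- rep(yy, times = 3L) + (rep(xx, each = 3L) - 1L) * ny
      series <- rowMeans(sub[, cols, drop = FALSE])
      sp <- periodogram_hann(series, fps)
      st <- spectrum_stats(sp, fps, roi$hp_cutoff_hz, roi$reject_frac)
      rows[[length(rows) + 1L]] <- data.frame(
        y = map$y_rows[yy[2L]], x = map$x_cols[xx[2L]],
        peak_hz = st$peak_hz, sharpness = st$sharpness,
        n_peaks = st$n_peaks, multi_peak = st$multi_peak)
      powers[[length(powers) + 1L]] <- sp$power
      if (length(powers) == 1L) freqs <- sp$freqs
    }
  }
  if (!length(rows)) {
    return(structure(list(table = data.frame(), power = NULL,
                          freqs = NULL, fps = fps),
                     class = "subregion_spectra"))
  }
  structure(list(table = do.call(rbind, rows),
                 power = do.call(cbind, powers),
                 freqs = freqs, fps = fps),
            class = "subregion_spectra")
}

#' @export
print.subregion_spectra <- function(x, ...) {
  cat(sprintf("subregion_spectra: %d tiles", nrow(x$table)))
  if (nrow(x$table))
    cat(sprintf(", peak range %.2f-%.2f Hz", min(x$table$peak_hz),
                max(x$table$peak_hz)))
  cat("\n"); invisible(x)
}

#' Aggregate subregion spectra into the ROI ciliary beat frequency
#'
#' Subregions are ranked by descending peak sharpness and screened for
#' spurious spectra in two automated steps standing in for manual review:
#' spectra with a secondary peak exceeding `reject_frac` of the primary
#' (multi-peaked) are rejected, and spectra whose peak lies more than half
#' an octave from the ROI consensus (the median candidate peak) are
#' rejected as harmonics or outliers — a pixel that a cilium sweeps twice
#' per beat oscillates at twice the beat frequency with a perfectly sharp
#' spectrum, so sharpness alone cannot screen it.  The peak frequencies of
#' the top `max_subregions` survivors are averaged into the ROI CBF.  When
#' every subregion is rejected the result is a flagged null (CBF `NA`),
#' not an error.
#'
#' @param spectra A [subregion_spectra()] result.
#' @param max_subregions Maximum number of subregions aggregated.
#' @return An object of class `"cbf_result"`: `cbf_hz` (`NA` when null),
#'   `table` (all tiles with `accepted` flag and rejection `reason`),
#'   `null` (logical).
#' @export
estimate_cbf_roi <- function(spectra, max_subregions = 10) {
  stopifnot(inherits(spectra, "subregion_spectra"))
  tb <- spectra$table
  if (!nrow(tb)) {
    return(structure(list(cbf_hz = NA_real_, table = tb, null = TRUE),
                     class = "cbf_result"))
  }
  tb <- tb[order(-tb$sharpness, tb$x, tb$y), ]
  tb$reason <- ifelse(tb$multi_peak, "multi-peak spectrum", "")
  ok <- which(!tb$multi_peak)
  if (length(ok)) {
    consensus <- stats::median(tb$peak_hz[ok])
    octave_off <- abs(log2(tb$peak_hz[ok] / consensus)) > 0.5
    tb$reason[ok[octave_off]] <- "inconsistent with ROI consensus"
    ok <- ok[!octave_off]
  }
  keep <- ok[seq_len(min(length(ok), max_subregions))]
  tb$accepted <- FALSE
  tb$accepted[keep] <- TRUE
  tb$reason[setdiff(ok, keep)] <- "rank below sharpness cutoff"
  if (!length(keep)) {
    return(structure(list(cbf_hz = NA_real_, table = tb, null = TRUE),
                     class = "cbf_result"))
  }
  structure(list(cbf_hz = mean(tb$peak_hz[keep]), table = tb, null = FALSE),
            class = "cbf_result")
}

#' @export
print.cbf_result <- function(x, ...) {
  if (x$null) cat("CBF: null result (no acceptable subregion spectra)\n")
  else cat(sprintf("CBF: %.2f Hz from %d accepted subregions\n",
                   x$cbf_hz, sum(x$table$accepted)))
  invisible(x)
}

#' Select the reference cilium for phase analysis
#'
#' The reference is the accepted subregion with the sharpest spectral peak
#' (ties broken by smaller x, then smaller y).  When a cilia map is given,
#' the returned pixel is snapped to the active pixel nearest the winning
#' tile's centre, guaranteeing a valid phase reference.
#'
#' @param cbf A [estimate_cbf_roi()] result.
#' @param map Optional [detect_oscillatory_pixels()] result for snapping.
#' @return `c(y, x)` pixel coordinates, or `NULL` for a null CBF result.
#' @export
select_reference <- function(cbf, map = NULL) {
  stopifnot(inherits(cbf, "cbf_result"))
  if (cbf$null) return(NULL)
  acc <- cbf$table[cbf$table$accepted, ]
  acc <- acc[order(-acc$sharpness, acc$x, acc$y), ]
  ref <- c(y = acc$y[1L], x = acc$x[1L])
  if (!is.null(map)) {
    iy <- match(ref["y"], map$y_rows); ix <- match(ref["x"], map$x_cols)
    if (is.na(iy) || is.na(ix) || !map$active[iy, ix]) {
      act <- which(map$active, arr.ind = TRUE)
      if (!nrow(act)) return(NULL)
      d2 <- (map$y_rows[act[, 1]] - ref["y"])^2 +
            (map$x_cols[act[, 2]] - ref["x"])^2
      k <- which.min(d2)
      ref <- c(y = map$y_rows[act[k, 1]], x = map$x_cols[act[k, 2]])
    }
  }
  ref
}
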