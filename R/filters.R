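# Zero-phase temporal high-pass filtering, vectorised over pixels.
#
# A recording carries slow bulk drifts (stage vibration, tissue settling)
# that must be removed before any per-pixel spectral analysis, without
# distorting the phase relationships the metachrony modules depend on.
# Hence a forward-backward (zero-phase) order-2 Butterworth high-pass,
# applied along time to every pixel series at once.

# Run one pass of an order-2 IIR filter along the columns of an N x T
# matrix (one row per pixel series, time along columns, so each time step
# touches one contiguous column).  `backward = TRUE` runs the recursion
# from the last column to the first, which together with a forward pass
# gives a zero-phase filter without materialising reversed copies.
iir_filter_mat <- function(b, a, x, backward = FALSE) {
  nT <- ncol(x)
  y <- matrix(0, nrow(x), nT)
  idx <- if (backward) nT:1L else seq_len(nT)
  ## step-response initial state (direct form II transposed) scaled by the
  ## first processed sample, so edges start in filter steady state
  M <- matrix(c(1 + a[2], a[3], -1, 1), 2L, 2L)
  zi <- solve(M, c(b[2] - a[2] * b[1], b[3] - a[3] * b[1]))
  x0 <- x[, idx[1L]]
  z1 <- zi[1] * x0; z2 <- zi[2] * x0
  for (n in idx) {
    xn <- x[, n]
    yn <- b[1] * xn + z1
    z1 <- b[2] * xn - a[2] * yn + z2
    z2 <- b[3] * xn - a[3] * yn
    y[, n] <- yn
  }
  y
}

# Zero-phase application with odd-reflection end padding (N x T layout).
# The pad length is generous because at 0.6 Hz / 100 fps the filter's
# transient is long relative to typical recordings.
filtfilt_mat <- function(b, a, x) {
  nT <- ncol(x)
  P <- min(nT - 1L, 200L)
  xp <- matrix(0, nrow(x), nT + 2L * P)
  xp[, (P + 1L):(P + nT)] <- x
  xp[, seq_len(P)] <- 2 * x[, 1L] - x[, (P + 1L):2L, drop = FALSE]
  xp[, (P + nT + 1L):(nT + 2L * P)] <-
    2 * x[, nT] - x[, (nT - 1L):(nT - P), drop = FALSE]
  y <- iir_filter_mat(b, a, xp)
  y <- iir_filter_mat(b, a, y, backward = TRUE)
  y[, (P + 1L):(P + nT), drop = FALSE]
}

#' Temporally high-pass filter a video stack
#'
#' Removes low-frequency intensity drift (default cutoff 0.6 Hz) from every
#' pixel's time series with a zero-phase order-2 Butterworth filter (applied
#' forward and backward, so effectively 4th order with no phase distortion).
#' Each series is mean-centred first; output intensities are therefore
#' signed fluctuations around zero.
#'
#' @param stack A [video_stack()].
#' @param cutoff_hz High-pass cutoff in Hz (must be below Nyquist).
#' @return A `"video_stack"`-classed object with filtered (signed) frames;
#'   calibration and id are preserved.
#' @export
highpass_video <- function(stack, cutoff_hz = 0.6) {
  stopifnot(inherits(stack, "video_stack"))
  fps <- stack$calibration$fps
  if (cutoff_hz <= 0 || cutoff_hz >= fps / 2)
    stop("cutoff_hz must lie in (0, fps/2)")
  d <- dim(stack$frames)
  if (d[1] < 16L) stop("too few frames for the high-pass filter (need >= 16)")
  flt <- signal::butter(2, cutoff_hz / (fps / 2), type = "high")
  x <- stack$frames
  dim(x) <- c(d[1], d[2] * d[3])
  x <- t(x)
  x <- x - rowMeans(x)
  y <- t(filtfilt_mat(flt$b, flt$a, x))
  dim(y) <- d
  structure(list(frames = y, calibration = stack$calibration,
                 id = stack$id, highpassed = cutoff_hz),
            class = "video_stack")
}
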