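# Phase mapping relative to a reference cilium, synchrony-band detection,
# temporal alternation testing, and the metachrony call.

#' Complex phase map of ciliary beating relative to a reference cilium
#'
#' For every oscillatory pixel p, the complex Fourier coefficients of its
#' (high-pass filtered) time series at the bin nearest the ROI beat
#' frequency and its two neighbours form a vector `z_p`; the pixel's
#' correlation with the reference pixel is
#' `corr(p) = <z_p, z_ref> / (||z_p|| * ||z_ref||)`.
#' Its argument is the beat-phase shift relative to the reference and its
#' magnitude the confidence of that estimate.  Phase shifts are reduced to
#' a binary colour: green for wrapped phase in (-90, +90] degrees (beating
#' with the reference), red otherwise (opposed); pixels without detected
#' ciliary motion carry no colour.
#'
#' @param stack A high-pass-filtered [video_stack()].
#' @param map A [detect_oscillatory_pixels()] result.
#' @param cbf_hz The ROI beat frequency (from [estimate_cbf_roi()]).
#' @param ref `c(y, x)` reference pixel (absolute indices); must be active.
#' @return An object of class `"phase_map"`: complex matrix `corr`,
#'   `magnitude`, integer `color` (0 none / 1 green / 2 red), `phase_deg`,
#'   `ref`, `cbf_hz` and the `y_rows` / `x_cols` covered.
#' @export
phase_map <- function(stack, map, cbf_hz, ref) {
  stopifnot(inherits(stack, "video_stack"), inherits(map, "cilia_map"))
  if (!is.finite(cbf_hz) || cbf_hz <= 0) stop("cbf_hz must be positive")
  d <- dim(stack$frames)
  fps <- stack$calibration$fps
  ny <- length(map$y_rows); nx <- length(map$x_cols)
  iy <- match(ref[1], map$y_rows); ix <- match(ref[2], map$x_cols)
  if (is.na(iy) || is.na(ix) || !map$active[iy, ix])
    stop("reference pixel is not an active pixel of the cilia map")
  k <- round(cbf_hz * d[1] / fps)          # 0-based frequency bin
  k <- max(2L, min(k, d[1] %/% 2L - 1L))
  sub <- stack$frames[, map$y_rows, map$x_cols, drop = FALSE]
  dim(sub) <- c(d[1], ny * nx)
  act <- which(map$active)
  Z <- stats::mvfft(sub[, act, drop = FALSE])[(k):(k + 2L), , drop = FALSE]
  ref_flat <- match(iy + (ix - 1L) * ny, act)
  zr <- Z[, ref_flat]
  num <- colSums(Z * Conj(matrix(zr, nrow = 3L, ncol = ncol(Z))))
  den <- sqrt(colSums(Mod(Z)^2)) * sqrt(sum(Mod(zr)^2))
  corr_v <- num / den
  corr <- matrix(complex(real = NA_real_), ny, nx)
  corr[act] <- corr_v
  phase <- matrix(NA_real_, ny, nx)
  phase[act] <- Arg(corr_v) * 180 / pi
  color <- matrix(0L, ny, nx)
  color[act] <- ifelse(phase[act] > -90 & phase[act] <= 90, 1L, 2L)
  mag <- matrix(0, ny, nx)
  mag[act] <- Mod(corr_v)
  weight <- matrix(0, ny, nx)
  weight[act] <- sqrt(colSums(Mod(Z)^2))   # beat-frequency amplitude
  structure(list(corr = corr, magnitude = mag, color = color,
                 weight = weight,
                 phase_deg = phase, ref = c(y = map$y_rows[iy],
                                            x = map$x_cols[ix]),
                 cbf_hz = cbf_hz, y_rows = map$y_rows, x_cols = map$x_cols),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  n <- sum(x$color > 0)
  cat(sprintf(
    "phase_map @ %.2f Hz, ref (y=%d, x=%d): %d coloured px (%.0f%% green)\n",
    x$cbf_hz, x$ref["y"], x$ref["x"], n,
    if (n) 100 * sum(x$color == 1L) / n else 0))
  invisible(x)
}

#' Per-frame binary stroke phase from tip positions
#'
#' In each frame and each ciliated column, the cilium tip is located as the
#' topmost high-intensity scatter above the epithelial surface; a tip at or
#' above `stroke_cutoff_um` (default 5 um) marks the extended power stroke
#' (green), below it the recovery/rest phase (red).  Columns with no
#' detectable tip in a frame carry no colour there.  Uses the raw
#' (unfiltered) stack, since tip detection needs absolute brightness.
#'
#' @param stack The raw [video_stack()].
#' @param map A [detect_oscillatory_pixels()] result (defines the search
#'   band and the ciliated columns).
#' @param surface_y Per-column row index of the epithelial surface (scalar
#'   or one value per ROI column), e.g. from [segment_layers()].
#' @param stroke_cutoff_um Power/recovery height cutoff (um).
#' @param tip_thresh Absolute intensity threshold for the tip scatter;
#'   `NULL` (default) uses the midpoint between the band's median and
#'   maximum intensity.
#' @return An object of class `"stroke_field"`: integer matrix `color`
#'   (`T x n_columns`, 0 none / 1 green / 2 red), `height_um`, `x_cols`.
#' @export
stroke_phase_binary <- function(stack, map, surface_y,
                                stroke_cutoff_um = 5, tip_thresh = NULL) {
  stopifnot(inherits(stack, "video_stack"), inherits(map, "cilia_map"))
  d <- dim(stack$frames)
  um_y <- stack$calibration$um_per_px_y
  ny <- length(map$y_rows); nx <- length(map$x_cols)
  surface_y <- rep_len(surface_y, nx)
  sub <- stack$frames[, map$y_rows, map$x_cols, drop = FALSE]
  if (is.null(tip_thresh)) {
    med <- stats::median(sub); tip_thresh <- med + 0.5 * (max(sub) - med)
  }
  ## topmost above-threshold row per (frame, column): weight rows so the
  ## top row wins, then one max.col call over all frame-column pairs
  m <- aperm(sub > tip_thresh, c(2L, 1L, 3L))       # ny x T x nx
  dim(m) <- c(ny, d[1] * nx)
  w <- m * (ny:1L)
  found <- colSums(m) > 0
  top_iy <- max.col(t(w), ties.method = "first")    # band row of topmost tip
  height <- matrix(NA_real_, d[1], nx)
  hvals <- (rep(surface_y, each = d[1]) - map$y_rows[top_iy]) * um_y
  height[found] <- hvals[found]
  height[, !map$ciliated_columns] <- NA_real_
  color <- matrix(0L, d[1], nx)
  sel <- !is.na(height)
  color[sel] <- ifelse(height[sel] >= stroke_cutoff_um, 1L, 2L)
  structure(list(color = color, height_um = height, x_cols = map$x_cols,
                 stroke_cutoff_um = stroke_cutoff_um),
            class = "stroke_field")
}

#' Ribbon diagram rendering
#'
#' Encodes a phase map (or one frame of a stroke field) as an RGB image:
#' a green pixel renders as `[0, m, 0]` and a red pixel as `[m, 0, 0]`,
#' where `m` is the correlation magnitude (1 for stroke fields); pixels
#' without ciliary motion are black.
#'
#' @param x A [phase_map()] or [stroke_phase_binary()] result.
#' @param frame For stroke fields, which frame to render.
#' @return Numeric array `height x width x 3` (RGB in `[0, 1]`).
#' @export
ribbon_diagram <- function(x, frame = 1L) {
  if (inherits(x, "phase_map")) {
    col <- x$color; mag <- x$magnitude
  } else if (inherits(x, "stroke_field")) {
    col <- matrix(x$color[frame, ], 1L)
    mag <- matrix(1, 1L, ncol(col))
  } else stop("x must be a phase_map or stroke_field")
  rgb <- array(0, dim = c(nrow(col), ncol(col), 3L))
  rgb[, , 1][col == 2L] <- mag[col == 2L]
  rgb[, , 2][col == 1L] <- mag[col == 1L]
  rgb
}

#' Detect synchrony bands in a phase map
#'
#' Each ROI column is assigned the majority colour of its active pixels;
#' maximal runs of consecutive columns sharing a dominant colour, with run
#' purity at least `purity_min` and physical length at least `min_band_um`,
#' become synchrony bands.  Columns with no active pixels terminate runs.
#'
#' Column votes are weighted by each pixel's spectral amplitude at the
#' beat frequency, so pixels with little beat-frequency content (whose
#' colour is noise) carry little weight.  When a surface trace is
#' supplied, only active pixels at power-stroke heights (at least
#' `roi$stroke_cutoff_um` above the surface) vote for the column colour:
#' a moving point scatter necessarily oscillates in antiphase at the lower
#' versus upper end of its excursion (its fundamental Fourier component
#' changes sign across the mean tip height), so pooling all heights mixes
#' the two lobes and speckles the columns; the extended-stroke lobe
#' carries the beat phase coherently.
#'
#' @param pm A [phase_map()].
#' @param roi The [roi_config()] (supplies `purity_min`, `min_band_um`,
#'   `stroke_cutoff_um`).
#' @param calibration The stack's [calibration()].
#' @param surface_y Optional per-column epithelial surface row (scalar or
#'   one value per ROI column), e.g. from [segment_layers()].
#' @return data.frame with one row per band: `x_start`, `x_end` (absolute
#'   columns, inclusive), `length_um`, `dominant_color`, `purity`.
#' @export
detect_bands <- function(pm, roi, calibration, surface_y = NULL) {
  stopifnot(inherits(pm, "phase_map"))
  um_x <- calibration$um_per_px_x
  col_px <- pm$color
  if (!is.null(surface_y)) {
    um_y <- calibration$um_per_px_y
    surface_y <- rep_len(surface_y, ncol(col_px))
    height <- outer(-pm$y_rows, surface_y, "+") * um_y
    col_px[height < roi$stroke_cutoff_um] <- 0L
    empty <- colSums(col_px > 0L) == 0L   # fall back where the lobe is empty
    col_px[, empty] <- pm$color[, empty]
  }
  w <- pm$weight
  ng <- colSums((col_px == 1L) * w); nr <- colSums((col_px == 2L) * w)
  dom <- ifelse(ng + nr == 0, 0L, ifelse(ng >= nr, 1L, 2L))
  r <- rle(dom)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i] == 0L) next
    cols <- starts[i]:ends[i]
    len_um <- length(cols) * um_x
    if (len_um < roi$min_band_um) next
    match_w <- sum(w[, cols][col_px[, cols] == r$values[i]])
    tot_w <- sum(w[, cols][col_px[, cols] > 0L])
    purity <- if (tot_w > 0) match_w / tot_w else 0
    if (purity < roi$purity_min) next
    out[[length(out) + 1L]] <- data.frame(
      x_start = pm$x_cols[starts[i]], x_end = pm$x_cols[ends[i]],
      length_um = len_um,
      dominant_color = c("green", "red")[r$values[i]],
      purity = purity)
  }
  if (!length(out)) {
    return(data.frame(x_start = integer(0), x_end = integer(0),
                      length_um = numeric(0), dominant_color = character(0),
                      purity = numeric(0)))
  }
  do.call(rbind, out)
}

#' Test whether a synchrony band alternates between phases over time
#'
#' A genuine line of synchrony flips colour every half beat period and
#' returns every full period.  For `n_window_pairs` windows spread over the
#' recording, each band column's stroke colour is required to FLIP after
#' `round(fps / (2 * cbf_hz))` frames and RETURN after twice that lag; the
#' band passes when the mean flip-and-return fraction reaches
#' `alternation_min`.  Incoherent regions that happen to form a band (e.g.
#' patches beating at unrelated frequencies) fail the periodic-return
#' requirement.
#'
#' @param stroke A [stroke_phase_binary()] result.
#' @param band One row of the [detect_bands()] data.frame.
#' @param cbf_hz ROI beat frequency.
#' @param fps Frame rate.
#' @param alternation_min Pass threshold on the mean flip-and-return
#'   fraction.
#' @param n_window_pairs Number of tested window pairs (reduced with a
#'   warning when the recording is too short; fewer than 2 usable pairs
#'   gives an indeterminate `FALSE`).
#' @return Logical with attributes `score` (mean flip-and-return fraction),
#'   `n_pairs` and `lag_frames`.
#' @export
check_alternation <- function(stroke, band, cbf_hz, fps,
                              alternation_min = 0.7, n_window_pairs = 8) {
  stopifnot(inherits(stroke, "stroke_field"))
  if (!is.finite(cbf_hz) || cbf_hz <= 0) return(structure(FALSE, score = NA_real_,
                                                          n_pairs = 0L,
                                                          lag_frames = NA_integer_))
  lag <- max(1L, round(fps / (2 * cbf_hz)))
  nT <- nrow(stroke$color)
  t_max <- nT - 2L * lag
  K <- n_window_pairs
  if (t_max < K) {
    K <- max(t_max, 0L)
    if (K < n_window_pairs)
      warning("recording too short; testing ", K, " window pairs")
  }
  if (K < 2L)
    return(structure(FALSE, score = NA_real_, n_pairs = K, lag_frames = lag))
  cols <- which(stroke$x_cols >= band$x_start & stroke$x_cols <= band$x_end)
  starts <- unique(round(seq(1L, t_max, length.out = K)))
  fracs <- vapply(starts, function(t0) {
    c0 <- stroke$color[t0, cols]
    c1 <- stroke$color[t0 + lag, cols]
    c2 <- stroke$color[t0 + 2L * lag, cols]
    valid <- c0 > 0L & c1 > 0L & c2 > 0L
    if (!any(valid)) return(NA_real_)
    mean(c1[valid] != c0[valid] & c2[valid] == c0[valid])
  }, numeric(1))
  n_ok <- sum(!is.na(fracs))
  score <- if (n_ok) mean(fracs, na.rm = TRUE) else NA_real_
  ok <- n_ok >= 2L && !is.na(score) && score >= alternation_min
  structure(ok, score = score, n_pairs = n_ok, lag_frames = lag)
}

#' Classify metachrony from synchrony bands and their alternation
#'
#' Metachrony is called when the epithelium shows lines of synchronous
#' beating that alternate between phases over time and these cover at least
#' `min_proportion` (default 25%) of the epithelial surface.  The
#' proportion counts only alternation-passing bands, the stricter reading
#' of the two-factor definition.
#'
#' @param bands [detect_bands()] data.frame.
#' @param alternation_ok Logical vector, one element per band.
#' @param surface_um Epithelial surface length of the ROI in um.
#' @param min_proportion Metachrony-call threshold on the proportion.
#' @return An object of class `"metachrony_result"`: `metachronous`,
#'   `proportion`, `bands` (with `alternation_ok` column), `n_bands`,
#'   `surface_um`.
#' @export
classify_metachrony <- function(bands, alternation_ok, surface_um,
                                min_proportion = 0.25) {
  stopifnot(nrow(bands) == length(alternation_ok))
  bands$alternation_ok <- as.logical(alternation_ok)
  prop <- if (nrow(bands)) sum(bands$length_um[bands$alternation_ok]) /
            surface_um else 0
  prop <- min(prop, 1)
  structure(list(metachronous = prop >= min_proportion,
                 proportion = prop, bands = bands,
                 n_bands = sum(bands$alternation_ok),
                 surface_um = surface_um),
            class = "metachrony_result")
}

#' @export
print.metachrony_result <- function(x, ...) {
  cat(sprintf("metachrony: %s (proportion %.2f, %d alternating band%s over %g um)\n",
              if (x$metachronous) "PRESENT" else "absent", x$proportion,
              x$n_bands, if (x$n_bands == 1L) "" else "s", x$surface_um))
  invisible(x)
}
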