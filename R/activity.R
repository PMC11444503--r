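#' Analysis configuration for one region of interest
#'
#' The user-drawn box around the beating cilia plus every tunable threshold
#' of the analysis, with the standard defaults: 0.6 Hz high-pass reference,
#' activity threshold of 4 times the median per-pixel temporal SD, up to 10
#' spectral subregions, rejection of subregions whose secondary spectral
#' peak exceeds 50% of the primary, synchrony bands of at least 10 um with
#' at least 80% colour purity, a 5-um power/recovery stroke cutoff, and an
#' alternation requirement of 0.7 over 8 window pairs.
#'
#' @param surface_band Integer `c(y_top, y_bottom)`: rows (inclusive)
#'   containing the cilia immediately above the epithelial surface.  `NULL`
#'   lets [analyze_roi()] derive it from the layer segmentation.
#' @param x_range Integer `c(x_left, x_right)` column interval (inclusive);
#'   `NULL` means the full width.
#' @param hp_cutoff_hz Temporal high-pass cutoff (Hz).
#' @param activity_k Multiplier of the median temporal SD above which a
#'   pixel counts as oscillating.
#' @param max_subregions Maximum number of spectral subregions aggregated
#'   into the ROI CBF.
#' @param reject_frac A subregion is rejected as spurious when a secondary
#'   spectral peak exceeds this fraction of the primary peak's power.
#' @param purity_min Minimum fraction of a band's coloured pixels matching
#'   its dominant colour.
#' @param min_band_um Minimum synchrony-band length (um).
#' @param alternation_min Minimum mean flip-and-return fraction for a band
#'   to count as temporally alternating.
#' @param n_window_pairs Number of window pairs tested for alternation.
#' @param stroke_cutoff_um Tip height above the surface separating power
#'   stroke (green) from recovery/rest (red).
#' @param max_disp_px Particle linking gate (px per frame).
#' @param min_track_len Minimum particle track length (frames).
#' @param r2_min Minimum R-squared of a track's displacement-time fit.
#' @param particle_margin_um Mucus margin above the mucus-PCL boundary
#'   excluded from particle detection (beating cilium tips penetrate it).
#' @return An object of class `"roi_config"`.
#' @export
roi_config <- function(surface_band = NULL, x_range = NULL,
                       hp_cutoff_hz = 0.6, activity_k = 4,
                       max_subregions = 10, reject_frac = 0.5,
                       purity_min = 0.8, min_band_um = 10,
                       alternation_min = 0.7, n_window_pairs = 8,
                       stroke_cutoff_um = 5,
                       max_disp_px = 5, min_track_len = 10, r2_min = 0.8,
                       particle_margin_um = 5) {
  if (!is.null(surface_band)) {
    surface_band <- as.integer(surface_band)
    if (length(surface_band) != 2L || surface_band[1] >= surface_band[2])
      stop("surface_band must be c(y_top, y_bottom) with y_top < y_bottom")
  }
  if (!is.null(x_range)) {
    x_range <- as.integer(x_range)
    if (length(x_range) != 2L || x_range[1] > x_range[2])
      stop("x_range must be c(x_left, x_right) with x_left <= x_right")
  }
  structure(list(surface_band = surface_band, x_range = x_range,
                 hp_cutoff_hz = hp_cutoff_hz, activity_k = activity_k,
                 max_subregions = max_subregions, reject_frac = reject_frac,
                 purity_min = purity_min, min_band_um = min_band_um,
                 alternation_min = alternation_min,
                 n_window_pairs = n_window_pairs,
                 stroke_cutoff_um = stroke_cutoff_um,
                 max_disp_px = max_disp_px, min_track_len = min_track_len,
                 r2_min = r2_min, particle_margin_um = particle_margin_um),
            class = "roi_config")
}

resolve_x_range <- function(roi, stack) {
  if (is.null(roi$x_range)) c(1L, dim(stack$frames)[3]) else roi$x_range
}

#' Detect pixels with genuine oscillatory ciliary activity
#'
#' A pixel within the surface band is scored by its temporal standard
#' deviation relative to the image's noise floor, taken as the median
#' temporal SD across all pixels of the image (the image is dominated by
#' static structure — epithelium, lamina propria, air — so its median SD
#' is the random-variation floor).  Pixels whose SD exceeds `activity_k`
#' (default 4) times that median are flagged active; isolated single
#' active pixels (no active 8-neighbour) are removed as salt noise.  The
#' input must already be high-pass filtered ([highpass_video()]) so that
#' slow drifts do not masquerade as activity.
#'
#' @param stack A high-pass-filtered [video_stack()].
#' @param roi A [roi_config()] with a non-`NULL` `surface_band`.
#' @return An object of class `"cilia_map"`: logical matrix `active`
#'   (band rows x ROI columns), numeric `score` (SD / median SD, the cilia
#'   probability score), logical `ciliated_columns`, and the absolute
#'   `y_rows` / `x_cols` indices the map covers.
#' @export
detect_oscillatory_pixels <- function(stack, roi) {
  stopifnot(inherits(stack, "video_stack"), inherits(roi, "roi_config"))
  if (is.null(roi$surface_band))
    stop("roi$surface_band is required (rows containing the cilia)")
  d <- dim(stack$frames)
  xr <- resolve_x_range(roi, stack)
  y_rows <- roi$surface_band[1]:roi$surface_band[2]
  x_cols <- xr[1]:xr[2]
  if (min(y_rows) < 1L || max(y_rows) > d[2] ||
      min(x_cols) < 1L || max(x_cols) > d[3])
    stop("ROI exceeds stack dimensions")
  nT <- d[1]
  all_px <- stack$frames
  dim(all_px) <- c(nT, d[2] * d[3])
  mu_all <- colMeans(all_px)
  sds_all <- sqrt(pmax(colMeans(all_px^2) - mu_all^2, 0) * nT / (nT - 1))
  med <- stats::median(sds_all)
  if (med <= 0) med <- .Machine$double.eps  # noiseless degenerate floor
  sds <- matrix(sds_all, d[2], d[3])[y_rows, x_cols, drop = FALSE]
  score <- matrix(sds / med, length(y_rows), length(x_cols))
  active <- score > roi$activity_k
  active <- prune_isolated(active)
  structure(list(active = active, score = score,
                 ciliated_columns = apply(active, 2L, any),
                 y_rows = y_rows, x_cols = x_cols),
            class = "cilia_map")
}

# drop active pixels with no active 8-neighbour
prune_isolated <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  nb <- matrix(0L, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- nb + pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx]
  }
  m & nb >= 1L
}

#' @export
print.cilia_map <- function(x, ...) {
  cat(sprintf("cilia_map: %d/%d active pixels, %d/%d ciliated columns\n",
              sum(x$active), length(x$active),
              sum(x$ciliated_columns), length(x$ciliated_columns)))
  invisible(x)
}

#' Percentage of the epithelial surface with detectable motile cilia
#'
#' @param map A [detect_oscillatory_pixels()] result.
#' @param roi The [roi_config()] the map was computed with.
#' @param calibration The stack's [calibration()] (columns are converted to
#'   um of surface length; with uniform pixel pitch this equals the column
#'   fraction).
#' @return Percentage in `[0, 100]`.
#' @export
ciliation_fraction <- function(map, roi, calibration) {
  stopifnot(inherits(map, "cilia_map"))
  100 * mean(map$ciliated_columns)
}
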