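# Airway surface liquid / periciliary layer segmentation from the
# temporal-median frame.  The median over time suppresses moving cilia and
# advected particles, leaving the static layer structure: air (dark) over
# the mucus (ASL) band, a darker periciliary gap, then the bright
# epithelial band.

#' Segment ASL and PCL layers and trace the epithelial surface
#'
#' On each column of the temporal-median frame: the apical epithelial
#' surface is the strongest positive axial intensity edge; above it the
#' air-mucus interface is the strongest positive edge and the mucus-PCL
#' boundary the strongest negative edge between the two (both must exceed
#' a fraction of the surface edge strength, making the segmentation
#' invariant to global intensity scaling).  Column traces are smoothed with
#' a 5-column running median; columns with no detectable surface are
#' interpolated from neighbours across gaps up to 10 um, otherwise excluded
#' from the depth means.  PCL depth is the mucus-PCL boundary to surface
#' distance, ASL depth the air-mucus to mucus-PCL distance, both in um.
#'
#' @param stack The raw [video_stack()].
#' @param roi A [roi_config()] (only `x_range` is used).
#' @return An object of class `"layer_depths"`: `asl_um`, `pcl_um`
#'   (ROI means), per-column traces `surface_y`, `air_mucus_y`,
#'   `mucus_pcl_y`, logical `valid`, `x_cols`, and `null` (`TRUE` with a
#'   warning when more than half the columns have no detectable surface).
#' @export
segment_layers <- function(stack, roi = roi_config()) {
  stopifnot(inherits(stack, "video_stack"))
  d <- dim(stack$frames)
  um_y <- stack$calibration$um_per_px_y
  um_x <- stack$calibration$um_per_px_x
  xr <- resolve_x_range(roi, stack)
  x_cols <- xr[1]:xr[2]
  m <- stack$frames
  dim(m) <- c(d[1], d[2] * d[3])
  med <- matrix(apply(m, 2L, stats::median), d[2], d[3])[, x_cols, drop = FALSE]
  nx <- ncol(med); ny <- nrow(med)
  grad <- med[-1L, , drop = FALSE] - med[-ny, , drop = FALSE]  # d[y] at row y+1
  ## surface score: contrast of a 5-row band below each candidate row
  ## against the 3 rows above it (the epithelium is a thick bright band,
  ## which a stray bright line above the surface cannot mimic)
  below_w <- 5L; above_w <- 3L
  cs <- rbind(0, apply(med, 2L, cumsum))
  band_mean <- function(from, to) {          # rows from..to inclusive, per col
    (cs[pmin(to, ny) + 1L, , drop = FALSE] -
       cs[pmax(from, 1L), , drop = FALSE]) /
      (pmin(to, ny) - pmax(from, 1L) + 1L)
  }
  surf <- air <- pcl <- rep(NA_real_, nx)
  cand <- (above_w + 1L):(ny - below_w + 1L)
  score <- matrix(-Inf, ny, nx)
  for (y in cand)
    score[y, ] <- band_mean(y, y + below_w - 1L) - band_mean(y - above_w, y - 1L)
  ## a surface is detectable when its band contrast is an appreciable
  ## fraction of the median frame's dynamic range (scale invariant; a
  ## structureless image has only noise-level contrasts)
  min_strength <- 0.25 * diff(range(med))
  for (j in seq_len(nx)) {
    s <- which.max(score[, j])                     # first epithelium row
    strength <- score[s, j]
    if (strength < min_strength) next              # no detectable surface
    surf[j] <- s
    if (s <= 3L) { air[j] <- pcl[j] <- s; next }
    g <- grad[, j]
    above <- seq_len(s - 2L)                       # gradient rows above surface
    ga <- g[above]
    pos <- which(ga >= 0.15 * strength)
    if (!length(pos)) { air[j] <- pcl[j] <- s; next }
    a_i <- pos[1L]                                 # topmost qualifying edge
    a <- a_i + 1L                                  # first mucus row
    between <- seq_along(ga) > a_i
    if (any(between) && min(ga[between]) <= -0.1 * strength) {
      p <- which(between)[which.min(ga[between])] + 1L   # first PCL row
    } else p <- a                                  # zero-thickness ASL
    air[j] <- a; pcl[j] <- p
  }
  valid <- !is.na(surf)
  if (mean(valid) < 0.5) {
    warning("no detectable epithelial surface in more than half the columns")
    return(structure(list(asl_um = NA_real_, pcl_um = NA_real_,
                          surface_y = surf, air_mucus_y = air,
                          mucus_pcl_y = pcl, valid = valid, x_cols = x_cols,
                          null = TRUE), class = "layer_depths"))
  }
  gap_px <- ceiling(10 / um_x)
  smooth_trace <- function(v) {
    v <- fill_gaps(v, gap_px)
    if (sum(!is.na(v)) >= 5L) {
      ok <- !is.na(v)
      v[ok] <- stats::runmed(v[ok], k = 5L, endrule = "median")
    }
    v
  }
  surf <- smooth_trace(surf); air <- smooth_trace(air); pcl <- smooth_trace(pcl)
  use <- !is.na(surf) & !is.na(air) & !is.na(pcl)
  structure(list(asl_um = mean((pcl - air)[use]) * um_y,
                 pcl_um = mean((surf - pcl)[use]) * um_y,
                 surface_y = surf, air_mucus_y = air, mucus_pcl_y = pcl,
                 valid = valid, x_cols = x_cols, null = FALSE),
            class = "layer_depths")
}

# linearly interpolate NA runs no longer than gap_px columns
fill_gaps <- function(v, gap_px) {
  if (!anyNA(v) || all(is.na(v))) return(v)
  idx <- which(!is.na(v))
  filled <- stats::approx(idx, v[idx], xout = seq_along(v), rule = 1)$y
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] <= gap_px)
      v[starts[i]:ends[i]] <- filled[starts[i]:ends[i]]
  }
  v
}

#' @export
print.layer_depths <- function(x, ...) {
  if (x$null) cat("layer_depths: null result (surface not detectable)\n")
  else cat(sprintf("layer_depths: ASL %.1f um, PCL %.1f um (%d/%d columns)\n",
                   x$asl_um, x$pcl_um, sum(x$valid), length(x$valid)))
  invisible(x)
}
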