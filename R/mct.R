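# Mucociliary transport rate by particle tracking velocimetry: detect
# bright particulates in the mucus (ASL) layer, link them into tracks, and
# convert the average lateral displacement slope to mm/min.

#' Detect particulates in the ASL layer, frame by frame
#'
#' In every frame, local intensity maxima inside the mucus band (between
#' the air-mucus and mucus-PCL boundary traces, excluding a
#' `particle_margin_um` margin above the mucus-PCL boundary that beating
#' cilium tips can reach) exceeding the mucus background mean plus three
#' SDs are kept and refined to sub-pixel centroids over a 3x3
#' background-subtracted neighbourhood.
#'
#' @param stack The raw [video_stack()].
#' @param layers A [segment_layers()] result (or ground-truth equivalent
#'   with `air_mucus_y` / `mucus_pcl_y` / `x_cols`).
#' @param roi A [roi_config()] (supplies `particle_margin_um`).
#' @return List with one `data.frame(frame, x_px, y_px)` per frame.
#' @export
detect_particles <- function(stack, layers, roi = roi_config()) {
  stopifnot(inherits(stack, "video_stack"))
  d <- dim(stack$frames)
  um_y <- stack$calibration$um_per_px_y
  margin_px <- round(roi$particle_margin_um / um_y)
  x_cols <- layers$x_cols
  a <- round(layers$air_mucus_y); p <- round(layers$mucus_pcl_y)
  ok <- !is.na(a) & !is.na(p)
  empty <- data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0))
  if (!any(ok)) return(rep(list(empty), d[1]))
  y_lo <- max(min(a[ok]) + 1L, 1L)
  y_hi <- min(max(p[ok]) - 1L - margin_px, d[2])
  if (y_hi < y_lo) return(rep(list(empty), d[1]))
  rows <- y_lo:y_hi
  lapply(seq_len(d[1]), function(t) {
    R <- stack$frames[t, rows, x_cols, drop = TRUE]
    if (is.null(dim(R))) R <- matrix(R, length(rows), length(x_cols))
    bg_mu <- mean(R); bg_sd <- stats::sd(R)
    thr <- bg_mu + 3 * bg_sd
    ny <- nrow(R); nx <- ncol(R)
    if (ny < 3L || nx < 3L) return(empty)
    core <- R[2:(ny - 1L), 2:(nx - 1L)]
    ismax <- core > thr
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ismax <- ismax & core >= R[2:(ny - 1L) + dy, 2:(nx - 1L) + dx]
    }
    idx <- which(ismax, arr.ind = TRUE)
    if (!nrow(idx)) return(empty)
    cy <- idx[, 1] + 1L; cx <- idx[, 2] + 1L
    xs <- ys <- numeric(nrow(idx))
    for (k in seq_len(nrow(idx))) {
      w <- pmax(R[(cy[k] - 1L):(cy[k] + 1L), (cx[k] - 1L):(cx[k] + 1L)] -
                  bg_mu, 0)
      sw <- sum(w)
      ys[k] <- rows[1] - 1L + cy[k] + sum(w * (-1:1)) / sw
      xs[k] <- x_cols[1] - 1L + cx[k] +
        sum(t(w) * (-1:1)) / sw
    }
    data.frame(frame = t, x_px = xs, y_px = ys)
  })
}

#' Link per-frame detections into particle tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking within a displacement
#' gate.  Tracks shorter than `min_track_len` frames are discarded; each
#' surviving track's lateral speed is the least-squares slope of x versus
#' frame, and tracks with fit R-squared below `r2_min` are discarded
#' (near-stationary tracks with negligible residual variance count as
#' perfect fits).
#'
#' @param points Per-frame detection list from [detect_particles()].
#' @param max_disp_px Linking gate in pixels per frame.
#' @param min_track_len Minimum number of points per track.
#' @param r2_min Minimum R-squared of the x-vs-frame fit.
#' @return List of tracks; each is a list with `points` (data.frame),
#'   `slope_px_per_frame`, `r2`.
#' @export
link_tracks <- function(points, max_disp_px = 5, min_track_len = 10,
                        r2_min = 0.8) {
  ## pool all detections; assign a track id to each by greedy NN linking
  all_pts <- do.call(rbind, lapply(points, function(d)
    cbind(frame = d$frame, x = d$x_px, y = d$y_px)))
  if (is.null(all_pts) || !nrow(all_pts)) return(list())
  track_id <- integer(nrow(all_pts))
  next_id <- 0L
  prev_idx <- integer(0)          # row indices of previous frame's points
  frames <- all_pts[, "frame"]
  for (t in seq_along(points)) {
    cur_idx <- which(frames == t)
    assigned <- rep(FALSE, length(cur_idx))
    if (length(prev_idx) && length(cur_idx)) {
      D <- sqrt(outer(all_pts[prev_idx, "x"], all_pts[cur_idx, "x"], "-")^2 +
                outer(all_pts[prev_idx, "y"], all_pts[cur_idx, "y"], "-")^2)
      taken_prev <- rep(FALSE, length(prev_idx))
      repeat {
        k <- which.min(D)
        if (!length(k) || D[k] > max_disp_px) break
        i <- (k - 1L) %% nrow(D) + 1L; j <- (k - 1L) %/% nrow(D) + 1L
        track_id[cur_idx[j]] <- track_id[prev_idx[i]]
        assigned[j] <- TRUE; taken_prev[i] <- TRUE
        D[i, ] <- Inf; D[, j] <- Inf
      }
    }
    for (j in which(!assigned)) {
      next_id <- next_id + 1L
      track_id[cur_idx[j]] <- next_id
    }
    prev_idx <- cur_idx
  }
  out <- list()
  for (id in seq_len(next_id)) {
    sel <- which(track_id == id)
    if (length(sel) < min_track_len) next
    fr <- all_pts[sel, "frame"]; xx <- all_pts[sel, "x"]
    fit <- stats::lm.fit(cbind(1, fr), xx)
    slope <- unname(fit$coefficients[2])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((xx - mean(xx))^2)
    r2 <- if (ss_tot < 1e-12) 1 else 1 - ss_res / ss_tot
    if (r2 < r2_min) next
    out[[length(out) + 1L]] <- list(
      points = data.frame(frame = fr, x_px = xx, y_px = all_pts[sel, "y"]),
      slope_px_per_frame = slope, r2 = r2)
  }
  out
}

#' Mucociliary transport rate from particle tracks
#'
#' Averages the per-track lateral speeds and converts pixels/frame to
#' mm/min: `mean(slope) * um_per_px_x * fps * 60 / 1000`.  Positive values
#' are transport in the +x (cranial) direction.
#'
#' @param tracks [link_tracks()] output.
#' @param calibration The stack's [calibration()].
#' @return An object of class `"mct_result"`: `mct_mm_min` (`NA` with a
#'   warning when no track was accepted), `n_tracks`, `per_track`.
#' @export
mct_rate <- function(tracks, calibration) {
  calibration <- as_calibration(calibration)
  if (!length(tracks)) {
    warning("no accepted particle tracks; MCT is a null result")
    return(structure(list(mct_mm_min = NA_real_, n_tracks = 0L,
                          per_track = list(), null = TRUE),
                     class = "mct_result"))
  }
  slopes <- vapply(tracks, `[[`, 0, "slope_px_per_frame")
  structure(list(
    mct_mm_min = mean(slopes) * calibration$um_per_px_x *
      calibration$fps * 60 / 1000,
    n_tracks = length(tracks), per_track = tracks, null = FALSE),
    class = "mct_result")
}

#' @export
print.mct_result <- function(x, ...) {
  if (x$null) cat("MCT: null result (no accepted tracks)\n")
  else cat(sprintf("MCT: %.2f mm/min from %d tracks\n",
                   x$mct_mm_min, x$n_tracks))
  invisible(x)
}
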