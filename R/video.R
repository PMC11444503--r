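#' Calibrated micro-OCT video stack
#'
#' The container used by every analysis stage: a `T x Y x X` array of
#' non-negative grey-level intensities plus its acquisition [calibration()].
#' Axis 1 is time (frames), axis 2 is depth into the tissue (y, increasing
#' downward), axis 3 is lateral position along the epithelium (x), matching
#' the cross-sectional presentation of micro-OCT B-scans.
#'
#' @param frames Numeric `T x Y x X` array, `T >= 2`, `Y, X >= 3`, all values
#'   finite and non-negative.
#' @param calibration A [calibration()] object.
#' @param id Character label for the recording.
#' @return An object of class `"video_stack"` with elements `frames`,
#'   `calibration`, `id`.
#' @export
video_stack <- function(frames, calibration = metawave::calibration(),
                        id = "roi") {
  calibration <- as_calibration(calibration)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a 3-d array (T x Y x X)")
  d <- dim(frames)
  if (d[1] < 2L) stop("a video stack needs at least 2 frames")
  if (d[2] < 3L || d[3] < 3L) stop("frames must be at least 3 x 3 pixels")
  if (!all(is.finite(frames))) stop("intensities must be finite")
  if (min(frames) < 0) stop("intensities must be non-negative")
  structure(list(frames = frames, calibration = calibration,
                 id = as.character(id)[1]),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("video_stack '%s': %d frames of %d x %d px (%.3g s, %g x %g um)\n",
              x$id, d[1], d[2], d[3], d[1] / x$calibration$fps,
              d[2] * x$calibration$um_per_px_y,
              d[3] * x$calibration$um_per_px_x))
  invisible(x)
}

#' @export
dim.video_stack <- function(x) dim(x$frames)

sidecar_path <- function(path) {
  sub("\\.[A-Za-z0-9]+$", "", path) |> paste0(".calib.json")
}

#' Write a video stack to multi-page TIFF with a calibration sidecar
#'
#' Integer-valued stacks in `[0, 65535]` are stored losslessly as 16-bit
#' grey; other stacks are min-max scaled to 16 bits (quantisation error at
#' most 1/65535 of the dynamic range) with the offset/scale recorded in the
#' sidecar so that [read_video()] restores physical intensities.  The
#' calibration is persisted as JSON in `<name>.calib.json` next to the TIFF.
#'
#' @param stack A [video_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_video <- function(stack, path) {
  stopifnot(inherits(stack, "video_stack"))
  fr <- stack$frames
  integral <- all(fr == round(fr)) && max(fr) <= 65535
  if (integral) {
    offset <- 0; scale <- 65535
  } else {
    offset <- min(fr)
    scale <- max(fr) - offset
    if (scale <= 0) scale <- 1   # constant float stack
  }
  pages <- lapply(seq_len(dim(fr)[1]),
                  function(t) (fr[t, , ] - offset) / scale)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                 compression = "none"),
                 error = function(e) stop("failed to write TIFF: ",
                                          conditionMessage(e)))
  meta <- list(fps = stack$calibration$fps,
               um_per_px_x = stack$calibration$um_per_px_x,
               um_per_px_y = stack$calibration$um_per_px_y,
               id = stack$id,
               encoding = list(type = if (integral) "uint16" else "scaled16",
                               offset = offset, scale = scale))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibrated video stack from multi-page TIFF
#'
#' Reads grayscale frames in time order and attaches the calibration, taken
#' from the `<name>.calib.json` sidecar written by [write_video()] when
#' present, otherwise from the `calibration` argument.  AVI containers are
#' not supported; convert recordings to multi-page TIFF first.
#'
#' @param path Path to a multi-page TIFF.
#' @param calibration Optional [calibration()] used when no sidecar exists.
#' @return A [video_stack()].
#' @export
read_video <- function(path, calibration = NULL) {
  if (grepl("\\.avi$", path, ignore.case = TRUE))
    stop("AVI input is not supported; convert to multi-page TIFF")
  if (!file.exists(path)) stop("cannot read video: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable TIFF: ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("video must contain at least 2 frames")
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # collapse grey-written-as-RGB
    p
  })
  d <- dim(pages[[1]])
  fr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (t in seq_along(pages)) fr[t, , ] <- pages[[t]]
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!is.null(meta)) {
    cal <- calibration(meta$fps, meta$um_per_px_x, meta$um_per_px_y)
    enc <- meta$encoding
    if (identical(enc$type, "uint16")) {
      fr <- round(fr * 65535)
    } else {
      fr <- fr * enc$scale + enc$offset
    }
    id <- if (!is.null(meta$id)) meta$id else basename(path)
  } else {
    if (is.null(calibration))
      stop("no calibration sidecar found; pass `calibration` explicitly")
    cal <- as_calibration(calibration)
    fr <- round(fr * 65535)   # raw 16-bit TIFF, integer grey levels
    id <- basename(path)
  }
  video_stack(pmax(fr, 0), cal, id)
}
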