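#' Acquisition calibration for a micro-OCT recording
#'
#' Bundles the three scale factors needed to convert pixel/frame coordinates
#' into physical units: the frame rate and the lateral (x) and axial (y)
#' pixel pitches.  The defaults correspond to a typical micro-OCT acquisition
#' of the airway surface: 100 frames per second and a 240-pixel-wide,
#' 240 um-wide field (1 um per pixel in both directions).
#'
#' @param fps Frame rate in frames per second.
#' @param um_per_px_x Lateral pixel pitch in micrometres per pixel.
#' @param um_per_px_y Axial (depth) pixel pitch in micrometres per pixel.
#' @return An object of class `"calibration"`: a list with elements `fps`,
#'   `um_per_px_x` and `um_per_px_y`.
#' @examples
#' cal <- calibration()        # 100 fps, 1 um/px
#' cal$fps
#' @export
calibration <- function(fps = 100, um_per_px_x = 1, um_per_px_y = 1) {
  for (v in list(fps, um_per_px_x, um_per_px_y)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("calibration values must be single, finite, strictly positive numbers")
  }
  structure(list(fps = as.numeric(fps),
                 um_per_px_x = as.numeric(um_per_px_x),
                 um_per_px_y = as.numeric(um_per_px_y)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("micro-OCT calibration: %g fps, %g um/px lateral, %g um/px axial\n",
              x$fps, x$um_per_px_x, x$um_per_px_y))
  invisible(x)
}

as_calibration <- function(x) {
  if (inherits(x, "calibration")) return(x)
  if (is.list(x) && all(c("fps", "um_per_px_x", "um_per_px_y") %in% names(x)))
    return(calibration(x$fps, x$um_per_px_x, x$um_per_px_y))
  stop("cannot interpret object as a calibration")
}
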