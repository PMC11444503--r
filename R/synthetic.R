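#' Parameters of the synthetic micro-OCT epithelium simulator
#'
#' Collects every knob of the simulated recording.  Defaults describe a
#' human-scale airway ROI: 2 s at 100 fps, a 240-um-wide field at 1 um/px,
#' fully ciliated surface beating at 8 Hz in a 60-um metachronal wave, a
#' 17-um mucus (ASL) layer over a 4-um periciliary layer, and particulates
#' advected at 1.6 mm/min.
#'
#' Phase structure along the epithelium (`phase_mode`):
#' * `"metachronal"` — a travelling wave, phase ramp `2*pi*x/wavelength_um`;
#' * `"synchronous"` — all cilia in phase;
#' * `"chaotic"` — independent uniform phases per `patch_um`-wide patch
#'   (one multiciliated cell) and, reflecting the multi-peaked frequency
#'   content of uncoordinated epithelium, an independent per-patch beat
#'   frequency drawn uniformly from `cbf_hz * (1 +/- freq_spread)`.
#'
#' @param T_frames,Y,X Stack dimensions (frames, rows, columns).
#' @param calibration A [calibration()].
#' @param cbf_hz True ciliary beat frequency (must be below Nyquist).
#' @param phase_mode One of `"metachronal"`, `"synchronous"`, `"chaotic"`.
#' @param wavelength_um Metachronal wavelength (metachronal mode only).
#' @param tip_excursion_um Peak-to-peak vertical travel of the cilium tip.
#' @param tip_base_um Mean tip height above the epithelial surface, so the
#'   tip oscillates `tip_base_um +/- tip_excursion_um/2`.  The default (5)
#'   centres the oscillation on the 5-um power/recovery stroke cutoff.
#' @param ciliation_frac Fraction of the surface carrying motile cilia.
#' @param patch_um Width of one independently phased ciliary patch.
#' @param freq_spread Relative half-width of the per-patch beat-frequency
#'   band; `NULL` selects the mode default (0.7 chaotic, 0 otherwise).
#' @param asl_um,pcl_um True airway-surface-liquid and periciliary depths.
#' @param mct_mm_min True lateral particle advection speed.
#' @param n_particles Number of bright particulates in the mucus.
#' @param noise_sd Additive Gaussian noise SD, relative to the epithelial
#'   band intensity (1.0); cilium tips are rendered at `tip_intensity`.
#' @param tip_intensity Grey level of the cilium tip scatter (default 3,
#'   i.e. 3x the epithelial band — a specular point scatter).
#' @param speckle If `TRUE`, noise is multiplicative
#'   (`I * (1 + noise)`) instead of additive.
#' @param seed RNG seed; identical parameters give a bit-identical stack.
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(T_frames = 200, Y = 100, X = 240,
                       calibration = metawave::calibration(),
                       cbf_hz = 8,
                       phase_mode = c("metachronal", "synchronous", "chaotic"),
                       wavelength_um = 60,
                       tip_excursion_um = 7, tip_base_um = 5,
                       ciliation_frac = 1, patch_um = 5,
                       freq_spread = NULL,
                       asl_um = 17, pcl_um = 4,
                       mct_mm_min = 1.6, n_particles = 8,
                       noise_sd = 0.1, tip_intensity = 3,
                       speckle = FALSE, seed = 1) {
  phase_mode <- match.arg(phase_mode)
  calibration <- as_calibration(calibration)
  if (cbf_hz >= calibration$fps / 2)
    stop("cbf_hz must be below the Nyquist frequency fps/2")
  if (phase_mode == "metachronal" &&
      (is.null(wavelength_um) || !is.finite(wavelength_um) || wavelength_um <= 0))
    stop("metachronal mode requires a positive wavelength_um")
  if (ciliation_frac < 0 || ciliation_frac > 1)
    stop("ciliation_frac must be in [0, 1]")
  if (is.null(freq_spread))
    freq_spread <- if (phase_mode == "chaotic") 0.7 else 0
  p <- list(T_frames = as.integer(T_frames), Y = as.integer(Y),
            X = as.integer(X), calibration = calibration, cbf_hz = cbf_hz,
            phase_mode = phase_mode, wavelength_um = wavelength_um,
            tip_excursion_um = tip_excursion_um, tip_base_um = tip_base_um,
            ciliation_frac = ciliation_frac, patch_um = patch_um,
            freq_spread = freq_spread, asl_um = asl_um, pcl_um = pcl_um,
            mct_mm_min = mct_mm_min, n_particles = as.integer(n_particles),
            noise_sd = noise_sd, tip_intensity = tip_intensity,
            speckle = isTRUE(speckle), seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

# run expr with a private, seeded RNG stream; caller's stream untouched
with_sim_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Per-column ciliary phase offsets
#'
#' The spatial phase structure of the beat along the epithelium.
#' Metachronal mode is a wrapped linear ramp `2*pi*x/wavelength_um`;
#' synchronous mode is identically zero; chaotic mode draws one
#' Uniform(0, 2*pi) phase per `patch_um`-wide patch (adjacent positions in
#' a patch share the phase).
#'
#' @param mode `"metachronal"`, `"synchronous"` or `"chaotic"`.
#' @param wavelength_um Metachronal wavelength in um.
#' @param x_um Numeric vector of lateral positions in um.
#' @param patch_um Patch width for chaotic mode.
#' @param seed RNG seed used in chaotic mode.
#' @return Numeric vector of phase offsets in `[0, 2*pi)`, one per position.
#' @examples
#' phase_profile("metachronal", 60, x_um = c(0, 30)) # 0 and pi
#' @export
phase_profile <- function(mode = c("metachronal", "synchronous", "chaotic"),
                          wavelength_um = 60, x_um, patch_um = 5, seed = 1) {
  mode <- match.arg(mode)
  switch(mode,
    synchronous = rep(0, length(x_um)),
    metachronal = {
      if (is.null(wavelength_um) || !is.finite(wavelength_um) ||
          wavelength_um <= 0)
        stop("metachronal mode requires a positive wavelength_um")
      (2 * pi * x_um / wavelength_um) %% (2 * pi)
    },
    chaotic = {
      patch <- floor(x_um / patch_um)
      ids <- sort(unique(patch))
      ph <- with_sim_rng(seed, stats::runif(length(ids), 0, 2 * pi))
      ph[match(patch, ids)]
    })
}

# integer row layout of the simulated scene (1-based, y increases downward)
sim_geometry <- function(p) {
  um_y <- p$calibration$um_per_px_y
  ep_px  <- max(3L, round(15 / um_y))
  lp_px  <- max(3L, round(20 / um_y))
  pcl_px <- round(p$pcl_um / um_y)
  asl_px <- round(p$asl_um / um_y)
  surface_row <- p$Y - lp_px - ep_px + 1L        # first epithelium row
  pcl_top <- surface_row - pcl_px                # first PCL row
  mucus_top <- pcl_top - asl_px                  # first mucus row (air-mucus)
  tip_reach <- ceiling((p$tip_base_um + p$tip_excursion_um / 2) / um_y)
  if (mucus_top < 4L)
    stop("geometry exceeds frame height: increase Y or reduce layer depths")
  if (surface_row - tip_reach < 1L)
    stop("cilium tips exceed frame height")
  list(surface_row = surface_row, pcl_top = pcl_top, mucus_top = mucus_top,
       ep_px = ep_px, lp_px = lp_px, pcl_px = pcl_px, asl_px = asl_px)
}

#' Simulate a micro-OCT recording of beating ciliated epithelium
#'
#' Renders, frame by frame, a cross-sectional scene: a bright epithelial
#' band over lamina propria, a periciliary gap and a mucus (ASL) band below
#' an air interface; cilium tips as bright point scatters whose height above
#' the surface oscillates as
#' `tip_base_um + (tip_excursion_um/2) * sin(2*pi*f*t + phi(x))`;
#' bright particulates advected laterally through the mucus at the true MCT
#' rate (wrapping at the field edges so the particle count is stationary);
#' and additive Gaussian noise.  The paired ground truth carries every
#' quantity the analysis modules estimate.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `stack` (a [video_stack()]) and `truth`
#'   (class `"sim_truth"`): true phases/frequencies per column, CBF, MCT,
#'   layer depths, the ciliated-column mask, the metachrony flag and true
#'   coherent-wave proportion, plus the rendered row indices of the surface
#'   and layer boundaries.
#' @export
simulate_epithelium <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  cal <- p$calibration
  um_x <- cal$um_per_px_x; um_y <- cal$um_per_px_y
  g <- sim_geometry(p)
  with_sim_rng(p$seed, {
    ## background scene (static)
    bg <- matrix(0, p$Y, p$X)
    if (g$asl_px > 0) bg[g$mucus_top:(g$pcl_top - 1L), ] <- 0.25
    if (g$pcl_px > 0) bg[g$pcl_top:(g$surface_row - 1L), ] <- 0.05
    bg[g$surface_row:(g$surface_row + g$ep_px - 1L), ] <- 1.0
    bg[(g$surface_row + g$ep_px):p$Y, ] <- 0.35

    ## ciliated patches, phases, frequencies
    x_px <- seq_len(p$X)
    x_um <- (x_px - 1L) * um_x
    patch_w <- max(1L, round(p$patch_um / um_x))
    patch_id <- (x_px - 1L) %/% patch_w
    n_patch <- max(patch_id) + 1L
    n_cil <- round(p$ciliation_frac * n_patch)
    cil_patches <- if (n_cil >= n_patch) seq_len(n_patch) - 1L
                   else sort(sample.int(n_patch, n_cil) - 1L)
    ciliated <- patch_id %in% cil_patches
    phase <- phase_profile(p$phase_mode, p$wavelength_um, x_um,
                           p$patch_um, seed = p$seed)
    freq <- rep(p$cbf_hz, p$X)
    if (p$freq_spread > 0) {
      fpatch <- p$cbf_hz * stats::runif(n_patch, 1 - p$freq_spread,
                                        1 + p$freq_spread)
      freq <- fpatch[patch_id + 1L]
    }

    ## particle initial state: sub-pixel positions in the upper half of the
    ## mucus, clear of the cilium-tip excursion range near the PCL boundary
    dx_px <- p$mct_mm_min * (1000 / 60) / cal$fps / um_x
    margin_px <- round(5 / um_y)
    py_lo <- g$mucus_top + 1L
    py_hi <- min(g$mucus_top + g$asl_px %/% 2L,
                 g$pcl_top - 1L - margin_px)
    n_part <- p$n_particles
    if (n_part > 0 && py_hi < py_lo) {
      warning("mucus layer too thin for particles; simulating none")
      n_part <- 0L
    }
    part_x0 <- stats::runif(n_part, 0, p$X)
    part_y <- if (n_part > 0) stats::runif(n_part, py_lo, py_hi) else numeric(0)

    fr <- array(0, dim = c(p$T_frames, p$Y, p$X))
    tvec <- (seq_len(p$T_frames) - 1L) / cal$fps
    half_exc <- p$tip_excursion_um / 2
    cil_idx <- which(ciliated)
    for (t in seq_len(p$T_frames)) {
      frame <- bg
      if (length(cil_idx)) {
        h_um <- p$tip_base_um +
          half_exc * sin(2 * pi * freq[cil_idx] * tvec[t] + phase[cil_idx])
        rows <- g$surface_row - pmax(1L, pmin(round(h_um / um_y),
                                              g$surface_row - 1L))
        frame[cbind(rows, cil_idx)] <- p$tip_intensity
      }
      if (n_part > 0) {
        xc <- (part_x0 + (t - 1L) * dx_px) %% p$X + 1
        for (k in seq_len(n_part)) {
          xs <- (round(xc[k]) - 2L):(round(xc[k]) + 2L)
          ys <- (round(part_y[k]) - 2L):(round(part_y[k]) + 2L)
          keep_y <- ys >= py_lo - 1L & ys <= py_hi + 1L
          xs_w <- (xs - 1L) %% p$X + 1L
          w <- outer(exp(-(ys - part_y[k])^2 / 2),
                     exp(-(xs - xc[k])^2 / 2))
          frame[ys[keep_y], xs_w] <- frame[ys[keep_y], xs_w] +
            0.9 * w[keep_y, , drop = FALSE]
        }
      }
      fr[t, , ] <- frame
    }
    if (p$noise_sd > 0) {
      eps <- stats::rnorm(length(fr), 0, p$noise_sd)
      fr <- if (p$speckle) fr * (1 + eps) else fr + eps
      fr <- pmax(fr, 0)
    }

    truth <- structure(list(
      phase_at_x = phase, freq_at_x = freq, cbf_hz = p$cbf_hz,
      mct_mm_min = p$mct_mm_min, dx_px_per_frame = dx_px,
      asl_um = g$asl_px * um_y, pcl_um = g$pcl_px * um_y,
      ciliated_columns = ciliated,
      metachronous = p$phase_mode %in% c("metachronal", "synchronous"),
      metachrony_proportion_true =
        if (p$phase_mode == "chaotic") 0 else mean(ciliated),
      surface_row = g$surface_row, pcl_top_row = g$pcl_top,
      mucus_top_row = g$mucus_top, n_particles = n_part,
      params = p), class = "sim_truth")
    list(stack = video_stack(fr, cal, id = sprintf("sim-%s-seed%d",
                                                   p$phase_mode, p$seed)),
         truth = truth)
  })
}

#' Default analysis configuration for a simulated stack
#'
#' Builds a [roi_config()] whose surface band covers the cilium excursion
#' range of the simulated scene (the rows the user would draw around the
#' beating cilia), using the simulator's ground-truth surface row.
#'
#' @param truth A `"sim_truth"` object from [simulate_epithelium()].
#' @param band_um Height of the surface band above the epithelium (um).
#' @param ... Passed on to [roi_config()].
#' @return A [roi_config()].
#' @export
sim_roi_config <- function(truth, band_um = 12, ...) {
  um_y <- truth$params$calibration$um_per_px_y
  roi_config(surface_band = c(truth$surface_row - ceiling(band_um / um_y),
                              truth$surface_row - 1L),
             x_range = c(1L, truth$params$X), ...)
}
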