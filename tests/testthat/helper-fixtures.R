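# Shared fixtures: small simulated recordings and reference oracles.

# quick simulated ROI with human-scale defaults
quick_sim <- function(seed = 1, ...) {
  simulate_epithelium(sim_params(seed = seed, ...))
}

# run the metachrony branch of the pipeline on a simulated ROI, using the
# ground-truth surface row (cheaper than analyze_roi when layers/MCT are
# not under test)
metachrony_call <- function(sim, roi = sim_roi_config(sim$truth)) {
  hp <- highpass_video(sim$stack, roi$hp_cutoff_hz)
  cmap <- detect_oscillatory_pixels(hp, roi)
  if (!any(cmap$active)) return(NULL)
  cbf <- estimate_cbf_roi(subregion_spectra(hp, cmap, roi),
                          roi$max_subregions)
  if (cbf$null) return(NULL)
  ref <- select_reference(cbf, cmap)
  pm <- phase_map(hp, cmap, cbf$cbf_hz, ref)
  surf <- sim$truth$surface_row
  bands <- detect_bands(pm, roi, sim$stack$calibration, surf)
  stroke <- stroke_phase_binary(sim$stack, cmap, surf, roi$stroke_cutoff_um)
  alt <- if (nrow(bands)) vapply(seq_len(nrow(bands)), function(i) {
    as.logical(check_alternation(stroke, bands[i, ], cbf$cbf_hz,
                                 sim$stack$calibration$fps,
                                 roi$alternation_min, roi$n_window_pairs))
  }, logical(1)) else logical(0)
  surface_um <- ncol(pm$color) * sim$stack$calibration$um_per_px_x
  classify_metachrony(bands, alt, surface_um)
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings
rank_sum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(N, n)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * (N - n) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Fourier amplitude of a series at frequency f (cycles per sample unit t)
fourier_amp <- function(v, f, t) 2 * Mod(mean(v * exp(-2i * pi * f * t)))
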