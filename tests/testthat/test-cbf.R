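# helper: build a stack whose 3x3 tiles carry prescribed time series
tile_stack <- function(series_list, fps = 100) {
  T_len <- length(series_list[[1]])
  nx <- 3L * length(series_list)
  fr <- array(0, c(T_len, 3L, nx))
  for (i in seq_along(series_list))
    for (dx in 1:3) fr[, , 3L * (i - 1L) + dx] <- series_list[[i]]
  video_stack(fr - min(fr), calibration(fps = fps))
}

# cilia map marking every pixel active over the whole tile grid
full_map <- function(stack) {
  d <- dim(stack$frames)
  structure(list(active = matrix(TRUE, d[2], d[3]),
                 score = matrix(10, d[2], d[3]),
                 ciliated_columns = rep(TRUE, d[3]),
                 y_rows = seq_len(d[2]), x_cols = seq_len(d[3])),
            class = "cilia_map")
}

test_that("subregion spectra localise pure tones and score them sharp", {
  t <- (0:255) / 100
  st <- tile_stack(list(sin(2 * pi * 8 * t), sin(2 * pi * 13.5 * t)))
  hp <- highpass_video(st, 0.6)
  ss <- subregion_spectra(hp, full_map(st), roi_config(surface_band = c(1, 3)))
  expect_identical(nrow(ss$table), 2L)
  expect_lt(abs(ss$table$peak_hz[1] - 8), 100 / 256)
  expect_lt(abs(ss$table$peak_hz[2] - 13.5), 100 / 256)
  expect_true(all(ss$table$sharpness >= 0.9))   # near-total power in one peak
  expect_false(any(ss$table$multi_peak))
  short <- video_stack(st$frames[1:32, , , drop = FALSE], st$calibration)
  expect_error(subregion_spectra(short, full_map(short),
                                 roi_config(surface_band = c(1, 3))), "64")
})

test_that("white-noise tiles are flat-spectrum and flagged multi-peak", {
  set.seed(9)
  reps <- vapply(1:30, function(i) {
    t_len <- 256
    st <- tile_stack(list(rnorm(t_len)))
    hp <- highpass_video(st, 0.6)
    ss <- subregion_spectra(hp, full_map(st),
                            roi_config(surface_band = c(1, 3)))
    c(sharp = ss$table$sharpness, multi = ss$table$multi_peak)
  }, numeric(2))
  ## flat-spectrum sharpness expectation: peak region width / band width
  n_bins <- 256 / 2
  region_frac <- (4 * 2 + 1) / n_bins    # +/- 2 native bins on the 2x grid
  expect_lt(mean(reps["sharp", ]), 3 * region_frac)
  expect_gt(mean(reps["multi", ]), 0.9)  # ragged spectra get rejected
})

test_that("ROI CBF averages the sharpest tiles and rejects multi-peak ones", {
  t <- (0:255) / 100
  clean <- sin(2 * pi * 8 * t)
  broad <- 0.8 * (sin(2 * pi * 2.2 * t) + sin(2 * pi * 3.1 * t + 1) +
                    sin(2 * pi * 4 * t + 2))
  st <- tile_stack(c(replicate(4, clean, simplify = FALSE),
                     replicate(4, broad, simplify = FALSE)))
  hp <- highpass_video(st, 0.6)
  ss <- subregion_spectra(hp, full_map(st), roi_config(surface_band = c(1, 3)))
  cbf <- estimate_cbf_roi(ss)
  expect_false(cbf$null)
  expect_lt(abs(cbf$cbf_hz - 8), 0.25)
  expect_true(all(cbf$table$reason[cbf$table$multi_peak] ==
                    "multi-peak spectrum"))
  ## permutation invariance: shuffling tile order leaves the estimate
  perm <- ss; idx <- c(5, 2, 7, 1, 8, 3, 6, 4)
  perm$table <- ss$table[idx, ]; perm$power <- ss$power[, idx]
  expect_identical(estimate_cbf_roi(perm)$cbf_hz, cbf$cbf_hz)
})

test_that("noise-only tiles never shift the CBF of sharp tiles", {
  set.seed(10)
  t <- (0:255) / 100
  clean <- replicate(3, sin(2 * pi * 8 * t), simplify = FALSE)
  noisy <- replicate(8, rnorm(256, 0, 1), simplify = FALSE)
  st1 <- tile_stack(clean)
  st2 <- tile_stack(c(clean, noisy))
  roi <- roi_config(surface_band = c(1, 3))
  c1 <- estimate_cbf_roi(subregion_spectra(highpass_video(st1, 0.6),
                                           full_map(st1), roi))
  c2 <- estimate_cbf_roi(subregion_spectra(highpass_video(st2, 0.6),
                                           full_map(st2), roi))
  expect_equal(c2$cbf_hz, c1$cbf_hz, tolerance = 1e-9)
})

test_that("noiseless synthetic CBF is recovered within one frequency bin", {
  sim <- quick_sim(seed = 12, T_frames = 256, cbf_hz = 9, noise_sd = 0,
                   n_particles = 0)
  roi <- sim_roi_config(sim$truth)
  hp <- highpass_video(sim$stack, 0.6)
  cm <- detect_oscillatory_pixels(hp, roi)
  ss <- subregion_spectra(hp, cm, roi)
  cbf <- estimate_cbf_roi(ss)
  ## every tile surviving the spurious-peak screens sits within one bin;
  ## pixels swept twice per beat peak at the 2nd harmonic and must have
  ## been screened out by the consensus rule
  expect_true(all(abs(cbf$table$peak_hz[cbf$table$accepted] - 9) <=
                    100 / 256 + 1e-9))
  expect_true(any(cbf$table$reason == "inconsistent with ROI consensus"))
  expect_lt(abs(cbf$cbf_hz - 9), 100 / 256)
})

test_that("empty or fully rejected spectra give a flagged null, not an error", {
  empty <- structure(list(table = data.frame(), power = NULL,
                          freqs = NULL, fps = 100),
                     class = "subregion_spectra")
  res <- estimate_cbf_roi(empty)
  expect_true(res$null)
  expect_identical(res$cbf_hz, NA_real_)
  expect_null(select_reference(res))
})

test_that("the reference cilium is the sharpest accepted tile, ties broken low", {
  tb <- data.frame(y = c(2, 2, 5), x = c(10, 4, 4),
                   peak_hz = c(8, 8, 8), sharpness = c(0.6, 0.6, 0.4),
                   n_peaks = 1L, multi_peak = FALSE)
  ss <- structure(list(table = tb, power = matrix(1, 4, 3),
                       freqs = 1:4, fps = 100), class = "subregion_spectra")
  ref <- select_reference(estimate_cbf_roi(ss))
  expect_identical(unname(ref), c(2, 4))   # smaller x wins the tie
})
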