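test_that("self-correlation of the reference pixel is 1 and green", {
  sim <- quick_sim(seed = 21, noise_sd = 0.05, n_particles = 0)
  roi <- sim_roi_config(sim$truth)
  hp <- highpass_video(sim$stack, 0.6)
  cm <- detect_oscillatory_pixels(hp, roi)
  cbf <- estimate_cbf_roi(subregion_spectra(hp, cm, roi))
  ref <- select_reference(cbf, cm)
  pm <- phase_map(hp, cm, cbf$cbf_hz, ref)
  iy <- match(ref["y"], pm$y_rows); ix <- match(ref["x"], pm$x_cols)
  expect_equal(Mod(pm$corr[iy, ix]), 1, tolerance = 1e-9)
  expect_equal(Arg(pm$corr[iy, ix]), 0, tolerance = 1e-9)
  expect_identical(pm$color[iy, ix], 1L)
  expect_true(all(pm$magnitude <= 1 + 1e-9))
  expect_error(phase_map(hp, cm, cbf$cbf_hz, c(1, 1)), "not an active")
})

test_that("a metachronal wave shows the half-wavelength phase opposition", {
  ## lambda = 60 um: columns 30 um apart beat in antiphase
  sim <- quick_sim(seed = 22, wavelength_um = 60, noise_sd = 0,
                   n_particles = 0)
  roi <- sim_roi_config(sim$truth)
  hp <- highpass_video(sim$stack, 0.6)
  cm <- detect_oscillatory_pixels(hp, roi)
  cbf <- estimate_cbf_roi(subregion_spectra(hp, cm, roi))
  ref <- select_reference(cbf, cm)
  pm <- phase_map(hp, cm, cbf$cbf_hz, ref)
  ## compare upper-lobe (power-stroke height) pixels, whose fundamental
  ## carries the column phase coherently
  surf <- sim$truth$surface_row
  height <- outer(-pm$y_rows, rep(surf, ncol(pm$color)), "+")
  ref_ix <- match(ref["x"], pm$x_cols)
  opp_ix <- ref_ix + ifelse(ref_ix + 30 <= ncol(pm$color), 30, -30)
  pick <- function(ix) {
    sel <- pm$color[, ix] > 0L & height[, ix] >= 6
    ph <- pm$phase_deg[sel, ix]
    ph[which.max(pm$weight[sel, ix])]
  }
  d <- abs(pick(opp_ix) - pick(ref_ix))
  expect_lt(abs(pmin(d, 360 - d) - 180), 25)
})

test_that("chaotic epithelium colours split near evenly", {
  set.seed(1)
  fracs <- vapply(1:8, function(s) {
    sim <- quick_sim(seed = 100 + s, phase_mode = "chaotic", noise_sd = 0.1,
                     T_frames = 128, n_particles = 0)
    roi <- sim_roi_config(sim$truth)
    hp <- highpass_video(sim$stack, 0.6)
    cm <- detect_oscillatory_pixels(hp, roi)
    cbf <- estimate_cbf_roi(subregion_spectra(hp, cm, roi))
    pm <- phase_map(hp, cm, cbf$cbf_hz, select_reference(cbf, cm))
    sum(pm$color == 1L) / sum(pm$color > 0L)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.12)
})

test_that("stroke colours follow the 5-um cutoff and beat at the CBF", {
  sim <- quick_sim(seed = 23, cbf_hz = 8, noise_sd = 0, n_particles = 0)
  roi <- sim_roi_config(sim$truth)
  hp <- highpass_video(sim$stack, 0.6)
  cm <- detect_oscillatory_pixels(hp, roi)
  stroke <- stroke_phase_binary(sim$stack, cm, sim$truth$surface_row)
  ## cutoff rule on the recovered heights
  sel <- !is.na(stroke$height_um)
  expect_true(all((stroke$color == 1L)[sel] ==
                    (stroke$height_um >= 5)[sel]))
  ## a fixed column alternates with period fps/cbf = 12.5 frames:
  ## 2 * cbf * duration transitions
  cc <- stroke$color[, 50]
  n_trans <- sum(diff(cc[cc > 0]) != 0)
  expect_lt(abs(n_trans - 2 * 8 * 2), 3)
})

test_that("ribbon encoding follows the [r, g, b] colour contract", {
  pm <- structure(list(color = matrix(c(1L, 2L, 0L), 1L),
                       magnitude = matrix(c(0.6257, 0.5628, 0.9), 1L),
                       y_rows = 1L, x_cols = 1:3),
                  class = "phase_map")
  rgb <- ribbon_diagram(pm)
  expect_equal(rgb[1, 1, ], c(0, 0.6257, 0))   # power stroke: pure green
  expect_equal(rgb[1, 2, ], c(0.5628, 0, 0))   # recovery: pure red
  expect_equal(rgb[1, 3, ], c(0, 0, 0))        # no ciliary motion
  stroke <- structure(list(color = matrix(c(1L, 2L), 2, 1),
                           x_cols = 1L), class = "stroke_field")
  expect_equal(ribbon_diagram(stroke, frame = 2)[1, 1, ], c(1, 0, 0))
})

test_that("band structure matches the programmed phase mode", {
  ## synchronous: one band spanning the ciliated surface
  simS <- quick_sim(seed = 24, phase_mode = "synchronous", noise_sd = 0,
                    n_particles = 0)
  metS <- metachrony_call(simS)
  expect_identical(nrow(metS$bands), 1L)
  expect_gt(metS$bands$length_um[1], 0.95 * 240)
  ## metachronal lambda = 120 um over 240 um: alternating ~60 um bands
  simM <- quick_sim(seed = 25, wavelength_um = 120, noise_sd = 0,
                    n_particles = 0)
  metM <- metachrony_call(simM)
  expect_gte(nrow(metM$bands), 3L)
  inner <- metM$bands[-c(1, nrow(metM$bands)), ]
  expect_true(all(abs(inner$length_um - 60) <= 12))
  expect_true(all(inner$dominant_color[-1] != head(inner$dominant_color, -1)))
  expect_true(all(metM$bands$purity >= 0.8))
})

test_that("chaotic surfaces rarely accumulate qualifying band coverage", {
  set.seed(2)
  cov <- vapply(1:10, function(s) {
    sim <- quick_sim(seed = 300 + s, phase_mode = "chaotic", noise_sd = 0.2,
                     n_particles = 0)
    met <- metachrony_call(sim)
    if (is.null(met)) 0 else met$proportion
  }, numeric(1))
  expect_gte(mean(cov < 0.25), 0.9)
})

test_that("alternation requires a periodic flip-and-return, not a static stripe", {
  sim <- quick_sim(seed = 26, noise_sd = 0, n_particles = 0)
  roi <- sim_roi_config(sim$truth)
  hp <- highpass_video(sim$stack, 0.6)
  cm <- detect_oscillatory_pixels(hp, roi)
  cbf <- estimate_cbf_roi(subregion_spectra(hp, cm, roi))
  pm <- phase_map(hp, cm, cbf$cbf_hz, select_reference(cbf, cm))
  bands <- detect_bands(pm, roi, sim$stack$calibration,
                        sim$truth$surface_row)
  stroke <- stroke_phase_binary(sim$stack, cm, sim$truth$surface_row)
  ok <- check_alternation(stroke, bands[1, ], cbf$cbf_hz, 100)
  expect_true(as.logical(ok))
  expect_gt(attr(ok, "score"), 0.7)
  ## a painted static stripe never flips
  static <- stroke
  static$color[] <- rep(rep(c(1L, 2L), each = 30),
                        length.out = ncol(static$color))[col(static$color)]
  bad <- check_alternation(static, data.frame(x_start = 1, x_end = 30),
                           cbf$cbf_hz, 100)
  expect_false(as.logical(bad))
  expect_lt(attr(bad, "score"), 0.05)
  ## too short a recording is indeterminate (FALSE), with a warning
  shorty <- stroke; shorty$color <- stroke$color[1:15, , drop = FALSE]
  expect_warning(res <- check_alternation(shorty, bands[1, ], 8, 100,
                                          n_window_pairs = 8))
  expect_length(attr(res, "n_pairs"), 1L)
})

test_that("the metachrony call applies the 25% two-factor rule", {
  bands <- data.frame(x_start = c(1, 101), x_end = c(72, 130),
                      length_um = c(72, 30),
                      dominant_color = c("green", "red"),
                      purity = c(0.95, 0.9))
  ## one alternating band covering 30% -> metachronous, proportion 0.30
  m1 <- classify_metachrony(bands, c(FALSE, TRUE), surface_um = 100)
  expect_true(m1$metachronous)
  expect_equal(m1$proportion, 0.30)
  ## only 72/240 = 0.30 when the other band alternates instead
  expect_true(classify_metachrony(bands, c(TRUE, FALSE), 240)$metachronous)
  ## non-alternating coverage never counts
  expect_false(classify_metachrony(bands, c(FALSE, FALSE), 240)$metachronous)
  ## no bands -> proportion 0
  m0 <- classify_metachrony(bands[0, ], logical(0), 240)
  expect_false(m0$metachronous)
  expect_identical(m0$proportion, 0)
})

test_that("the metachrony call is invariant to reference choice and global phase", {
  sim <- quick_sim(seed = 27, noise_sd = 0, n_particles = 0)
  roi <- sim_roi_config(sim$truth)
  hp <- highpass_video(sim$stack, 0.6)
  cm <- detect_oscillatory_pixels(hp, roi)
  cbf <- estimate_cbf_roi(subregion_spectra(hp, cm, roi))
  surf <- sim$truth$surface_row
  stroke <- stroke_phase_binary(sim$stack, cm, surf)
  call_with_ref <- function(ref) {
    pm <- phase_map(hp, cm, cbf$cbf_hz, ref)
    bands <- detect_bands(pm, roi, sim$stack$calibration, surf)
    alt <- vapply(seq_len(nrow(bands)), function(i)
      as.logical(check_alternation(stroke, bands[i, ], cbf$cbf_hz, 100)),
      logical(1))
    classify_metachrony(bands, alt, 240)
  }
  ref1 <- select_reference(cbf, cm)
  act <- which(cm$active, arr.ind = TRUE)
  ## a reference in a different column, half a wavelength away
  ix2 <- which(cm$x_cols[act[, 2]] == cm$x_cols[match(ref1["x"], cm$x_cols)] + 30)[1]
  ref2 <- c(y = cm$y_rows[act[ix2, 1]], x = cm$x_cols[act[ix2, 2]])
  m1 <- call_with_ref(ref1); m2 <- call_with_ref(ref2)
  expect_identical(m1$metachronous, m2$metachronous)
  expect_lt(abs(m1$proportion - m2$proportion), 0.15)
  ## half-wavelength shift: same band boundaries, colours swapped
  pm1 <- phase_map(hp, cm, cbf$cbf_hz, ref1)
  pm2 <- phase_map(hp, cm, cbf$cbf_hz, ref2)
  b1 <- detect_bands(pm1, roi, sim$stack$calibration, surf)
  b2 <- detect_bands(pm2, roi, sim$stack$calibration, surf)
  shared <- intersect(b1$x_start, b2$x_start)
  expect_gt(length(shared), 0)
  for (s in shared) {
    expect_false(b1$dominant_color[b1$x_start == s] ==
                   b2$dominant_color[b2$x_start == s])
  }
  ## a global time shift (same phase offset in all columns) leaves the call
  shifted <- sim
  shifted$stack$frames <- sim$stack$frames[c(7:200, 1:6), , ]
  m3 <- metachrony_call(shifted)
  expect_identical(m3$metachronous, m1$metachronous)
})
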