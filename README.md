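# metawave

Quantifying the functional microanatomy of ciliated airway epithelium from
cross-sectional micro-optical coherence tomography (µOCT) video.

Airway health depends on mucociliary transport: cilia beating in
coordinated, slightly phase-shifted waves (*metachrony*) propel the mucus
layer along the epithelium. µOCT films this machinery in situ at ~1–3 µm
resolution and ~100 frames/s, capturing — in a single recording — the
airway surface liquid (ASL) and periciliary liquid (PCL) depths, the
ciliary beat frequency (CBF), the mucociliary transport (MCT) rate, and
the spatial phase structure of ciliary beating. `metawave` is an R
toolkit for turning such recordings into per-ROI records of these five
quantities, aimed at airway physiologists analysing ex vivo tracheal or
bronchial preparations.

## What it computes

For a calibrated `T × Y × X` intensity stack (time × depth × lateral
position):

* **Ciliary activity** — after zero-phase temporal high-pass filtering
  (0.6 Hz cutoff), a pixel is oscillatory when its temporal SD exceeds
  4× the median per-pixel SD of the image (the noise floor); the ratio is
  its cilia probability score. Ciliation is the percentage of surface
  columns with active pixels.
* **CBF** — Hann-windowed power spectra of the mean series of 3×3-pixel
  subregions; subregions ranked by *peak sharpness* (peak power density ÷
  total power density), screened for multi-peaked spectra and for peaks
  inconsistent with the ROI consensus; the top ≤ 10 survivors' peak
  frequencies are averaged.
* **Phase map & metachrony** — each active pixel's complex Fourier
  coefficients at the beat frequency are correlated with a reference
  cilium (the sharpest subregion):
  `corr(p) = ⟨z_p, z_ref⟩ / (‖z_p‖‖z_ref‖)`. Phase shifts in (−90°, 90°]
  render green (beating with the reference), others red; colour intensity
  is |corr|. Runs of same-coloured columns ≥ 10 µm with ≥ 80% purity are
  synchrony bands. A band is *alternating* when its stroke colours flip
  after half a beat period and return after a full one. Metachrony is
  called when alternating bands cover ≥ 25% of the epithelial surface;
  the covered fraction is the metachrony proportion.
* **Stroke phase** — per frame, the cilium tip (topmost high-intensity
  scatter above the surface) at ≥ 5 µm marks the extended power stroke
  (green), below it recovery/rest (red); ribbon diagrams render these
  fields as RGB (`[0, m, 0]` green / `[m, 0, 0]` red).
* **ASL/PCL depths** — per-column edge analysis of the temporal-median
  frame: the epithelial surface (strongest band-contrast edge), the
  air–mucus interface (topmost qualifying edge) and the mucus–PCL
  boundary (strongest negative edge between them).
* **MCT** — particulates in the mucus detected per frame (local maxima
  above mean + 3 SD of the mucus background), linked into tracks by
  nearest-neighbour gating; the mean least-squares slope of x vs t,
  converted to mm/min.
* **Statistics** — the percent-change statistic
  `100·(reference − comparator)/reference`, exact/approximate
  Mann–Whitney comparisons, and backward stepwise OLS of MCT on ASL, PCL,
  CBF, ciliation, metachrony, metachrony proportion and the
  metachrony×CBF interaction (removal threshold p ≥ 0.10).

A bundled simulator (`simulate_epithelium()`) renders ground-truth
synthetic µOCT recordings — layered scene, oscillating tip scatters with
metachronal / synchronous / chaotic phase structure, advected mucus
particulates, Gaussian noise — against which every estimator is
validated.

## Worked example

```r
library(metawave)

sim <- simulate_epithelium(sim_params(phase_mode = "metachronal",
                                      cbf_hz = 8, mct_mm_min = 1.6,
                                      asl_um = 17, pcl_um = 4,
                                      noise_sd = 0.1, seed = 7))
rec <- analyze_roi(sim$stack, roi_config())
print(rec)
#> ROI 'sim-metachronal-seed7' functional microanatomy
#>   ASL 17.0 um | PCL 4.0 um | CBF 7.81 Hz | MCT 1.59 mm/min
#>   ciliation 100.0% | metachrony present (proportion 0.97)
```

The record recovers the programmed scene: a 17 µm mucus layer over a 4 µm
periciliary layer, an 8 Hz beat (7.81 Hz is the nearest spectral bin at
this recording length), transport at 1.6 mm/min, and a metachronal wave
covering nearly the whole surface. Group-level reporting follows the
convention of percent change relative to the reference group:

```r
pct_change(1.6, 0.83)   # MCT with vs without metachrony
#> [1] 48.1
```

Recordings on disk are handled as multi-page TIFF plus a JSON calibration
sidecar (`read_video()` / `write_video()`); `inst/cli/metawave.R`
provides `simulate`, `analyze` and `stats` subcommands for shell use.

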