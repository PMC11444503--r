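---
title: "Methods: quantifying airway functional microanatomy from µOCT video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying airway functional microanatomy from µOCT video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metawave)
```

# The measurement problem

Cross-sectional µOCT video of the airway surface shows, from top to
bottom, air, the mucus (airway surface liquid, ASL) layer, the thin
periciliary liquid (PCL) layer in which cilia beat, the bright epithelial
band, and the lamina propria. Beating cilium tips appear as
high-intensity point scatters whose height above the epithelial surface
oscillates with the beat; mucus particulates drift laterally with
mucociliary transport. From one recording `metawave` estimates ASL and
PCL depths, ciliation, ciliary beat frequency (CBF), mucociliary
transport (MCT) rate, and whether — and over what fraction of the
surface — the cilia beat in a metachronal wave.

All analyses run on a `T × Y × X` array with a calibration (default
100 frames/s, 1 µm/px laterally and axially, 240 µm wide ROIs). Indices
are R-native (1-based, inclusive); y increases downward into the tissue.

# Stage by stage

## Temporal high-pass filter

Slow bulk intensity drifts would otherwise dominate per-pixel variance
and spectra, so every pixel series is mean-centred and filtered with an
order-2 Butterworth high-pass at 0.6 Hz, applied forward and backward
(zero phase, so downstream phase relationships are undistorted). Ends
are odd-reflection padded (up to 200 samples) and the recursion starts
from its step-response steady state, keeping edge transients small at
this very low normalised cutoff. Passband amplitude at 8 Hz is preserved
to better than 1%; a 0.2 Hz drift is attenuated to below 2% mid-series.

## Oscillatory-pixel detection and ciliation

A pixel is called active when its temporal SD exceeds `activity_k = 4`
times the noise floor, taken as the median per-pixel temporal SD over
the whole image — the image is dominated by static structure
(epithelium, lamina propria, air), so its median SD estimates the random
variation level without being contaminated by cilia, even on a fully
ciliated surface. The ratio SD/median-SD is the pixel's cilia
probability score; isolated single active pixels are pruned as salt
noise. Both the mask and the score are invariant to global intensity
scaling, and raising `activity_k` can only shrink the mask. Ciliation is
the percentage of ROI columns containing at least one active pixel.

In a noiseless synthetic scene the median SD degenerates to zero; the
floor is then machine epsilon, making "any oscillation" active, which is
the correct degenerate limit.

## CBF by ranked subregion spectra

The ROI band is tiled with non-overlapping 3×3 pixel tiles (a sliding
window would duplicate essentially identical spectra at 9× cost); each
tile containing an active pixel contributes the Hann-windowed
periodogram of its mean series, zero-padded to the next power of two.
Peaks are searched in (0.6 Hz, 0.45·fps) — the upper margin avoids
Nyquist-edge artifacts. *Peak sharpness* is the power within ±2 native
frequency bins of the peak divided by total power; a pure tone scores
above 0.99, white noise near the bin-count ratio.

Two automated screens stand in for manual rejection of spurious spectra:

* **multi-peak** — a secondary local maximum exceeding `reject_frac =
  0.5` of the primary peak's power (outside the primary's ±2-bin
  neighbourhood) rejects the tile;
* **octave consistency** — tiles whose peak lies more than half an
  octave from the median candidate peak are rejected. This screen is
  necessary because a pixel that the cilium sweeps twice per beat
  oscillates at exactly twice the beat frequency with a perfectly sharp
  single-peak spectrum; sharpness cannot distinguish it.

The top `max_subregions = 10` survivors by sharpness are averaged. If
nothing survives, the ROI's CBF is a flagged null, never an exception.
On noiseless synthetic input the estimate lands within one native
frequency bin (fps/T) of the truth.

## Phase map, synchrony bands, alternation, metachrony

The reference cilium is the accepted subregion with the sharpest peak
(ties to smaller x, then y), snapped to the nearest active pixel. For
each active pixel the complex DFT coefficients at the bin nearest the
ROI CBF ±1 bin form `z_p`, and

`corr(p) = ⟨z_p, z_ref⟩ / (‖z_p‖ ‖z_ref‖)`

gives the pixel's phase shift (argument) and its confidence (modulus).
The continuous phase is reduced to the two colours of the field's ribbon
convention by half-plane binning: green for (−90°, +90°], red otherwise
— the only consistent two-colour reduction of a continuous phase.

**Column colours.** A moving point scatter necessarily oscillates in
antiphase at the two ends of its excursion: the fundamental Fourier
component of the occupancy indicator changes sign across the mean tip
height. Pooling a column's pixels therefore speckles its majority
colour. Two measures make column colours well defined: votes are
weighted by each pixel's spectral amplitude at the beat frequency
(pixels with no beat-frequency content vote negligibly), and when a
surface trace is available only pixels at power-stroke heights (≥ the
5 µm stroke cutoff) vote — the extended-stroke lobe carries the beat
phase coherently.

**Bands.** Maximal runs of columns sharing a dominant colour, with
weighted purity ≥ `purity_min = 0.8` and length ≥ `min_band_um = 10`,
are synchrony bands; colourless columns terminate runs.

**Alternation.** A genuine line of synchrony flips colour every half
beat period *and returns every full period*. For `n_window_pairs = 8`
windows spread over the recording, each band column's stroke colour must
flip after `round(fps/(2·CBF))` frames and return after twice that lag;
the band passes when the mean flip-and-return fraction is ≥
`alternation_min = 0.7`. The return requirement is what rejects
incoherent regions: any oscillator within ±50% of the ROI CBF flips its
sign after roughly half a period, so a flip-only test cannot separate
chaos from coordination, while the flip-and-return comb scores ~0.9 for
a coherent band and ~0.35 for mixed-frequency patches.

**Call.** Metachrony is present when alternation-passing bands cover ≥
25% of the epithelial surface length; the covered fraction is the
metachrony proportion (the stricter reading that counts only
alternation-passing bands). Fully synchronous beating satisfies this
operational definition as a single whole-ROI band; the band count is
reported so callers can distinguish that degenerate case. Because the
phase-map colours are relative to an arbitrary reference, band
*boundaries* shift with the reference phase (a reference half a
wavelength away swaps all colours with identical boundaries); the call
and the proportion are reference-invariant up to band-edge effects.

## Stroke-phase binary field

Per frame and ciliated column, the tip is the topmost pixel above the
surface exceeding an adaptive threshold (midpoint of the band's median
and maximum intensity); tip height ≥ 5 µm renders green (power stroke),
below red (recovery/rest). Ribbon diagrams encode green pixels as
`[0, m, 0]` and red as `[m, 0, 0]` with `m` the correlation magnitude
(1 for stroke fields).

## ASL/PCL segmentation

On the temporal-median frame (the median suppresses anything moving —
cilia, particulates) each column is searched for three edges: the
epithelial surface maximises a band-contrast score (mean of the 5 rows
below minus mean of the 3 rows above a candidate row — a thick bright
band wins over any stray bright line); the air–mucus interface is the
*topmost* gradient above the surface exceeding 15% of the surface
strength; the mucus–PCL boundary is the most negative gradient between
the two (absent one, the ASL has zero thickness). Columns whose surface
contrast falls below 25% of the median frame's dynamic range are
undetectable; gaps ≤ 10 µm are interpolated, traces smoothed with a
5-column running median, and more than half undetectable columns yields
a flagged null. Depth recovery on synthetic scenes is within 1 px, and
all rules are ratios, hence scale-invariant.

## MCT by particle tracking

Particulates are local maxima inside the mucus band exceeding the mucus
background mean + 3 SD, refined to 3×3 background-subtracted centroids.
A margin of `particle_margin_um = 5` above the mucus–PCL boundary is
excluded: beating tips penetrate the lower mucus and would otherwise be
tracked as zero-velocity particles, biasing MCT low. Detections are
linked greedily frame-to-frame within `max_disp_px = 5` (comfortably
above the ~1.7 px/frame of fast ferret-scale transport); tracks need ≥
10 points and an x-vs-frame least-squares fit with R² ≥ 0.8 (a
zero-variance stationary track counts as a perfect fit). The MCT rate is
`mean(slope) · µm/px · fps · 60/1000` mm/min, positive toward +x. The
estimate is frame-rate invariant within a few percent and recovers
synthetic truth within ~2–5% relative error at noise 0.1.

## Statistics

* `pct_change(reference, comparator)` = `100·(ref − comp)/ref`, rounded
  to one decimal for reporting — the difference expressed relative to
  the larger/control group, the only formula consistent with the
  published worked examples.
* `compare_groups()` wraps the rank-sum test: exact distribution for
  combined n ≤ 20 without ties, otherwise the tie-corrected normal
  approximation.
* `backward_stepwise()` fits OLS on all predictors (including the
  metachrony×CBF interaction as its own non-hierarchical term) and
  repeatedly removes the largest p ≥ `alpha_remove = 0.10` (the common
  stepwise default) until all retained predictors fall below it, with
  aliased columns dropped under a warning and the elimination order
  reported. With ~5 uninformative covariates tested at α = 0.10, the
  probability that the final model is *exactly* the generating set is
  bounded near (1 − α)⁵ ≈ 0.6 — a property of stepwise selection itself,
  not of the implementation; the true effects are retained essentially
  always at the simulated effect sizes.

# The simulator: what it emulates, what it does not

`simulate_epithelium()` renders the layered scene (epithelium 15 µm,
lamina propria below; PCL and ASL at programmed depths; air above),
cilium tips as single bright point scatters at 3× the epithelial band
intensity — µOCT tips are specular aggregated scatters, and an
oscillation must exceed 4× the noise floor to be detectable at all —
with height `5 + 3.5·sin(2π·f·t + φ(x))` µm (defaults: 7 µm excursion
centred on the 5 µm stroke cutoff, so the binary colouring is
well-posed), Gaussian-profile particulates advected at the programmed
MCT with wraparound (stationary particle count), and additive Gaussian
noise relative to the epithelial intensity (optionally multiplicative
speckle).

Phase structure: metachronal `φ(x) = 2πx/λ` (default λ = 60 µm — a free
simulator parameter; tissue wavelengths are not prescribed),
synchronous `φ = 0`, chaotic i.i.d. uniform per 5-µm patch (one
multiciliated cell). Chaotic patches additionally draw independent beat
frequencies uniform in `cbf·(1 ± 0.7)`: uncoordinated epithelium shows
several spectral peaks rather than one shared frequency, and a
single-frequency "chaos" would be physically and statistically
indistinguishable from coordination at half-period lags. Particles are
seeded in the upper half of the mucus, clear of tip reach.

The simulator does **not** model cilia hydrodynamics, optical
point-spread or speckle statistics, mucus rheology, curved or moving
tissue surfaces, or partial-volume effects. Passing its truth tables
shows the estimators correctly invert the stated forward model — layered
geometry, sinusoidal tips, linear advection — not that they are robust
to every property of tissue recordings.

# Numerical choices and degenerate inputs

* Recording length: T ≥ 64 frames for spectra; alternation reduces its
  window count (with a warning) on short recordings and returns an
  indeterminate `FALSE` below 2 usable pairs.
* Ties: column colour ties break to green; reference ties to smaller x
  then y; all orderings are deterministic, so a record re-analysed from
  the same file is bit-identical (JSON included).
* Null paths: no acceptable spectra → null CBF; no surface → null
  depths; no accepted tracks → null MCT — each sets a QC flag on the
  record and never aborts the other stages.
* Validation problem sizes: per-ROI stacks of 200 frames × 100 × 240 px
  (400 frames for the noiseless CBF checks), 50 + 50 ROIs for the
  classifier operating characteristics, 20 seeds per MCT scale, 200
  replicates of n = 200 for regression recovery — sizes at which the
  Monte-Carlo bounds asserted in the tests are stable.

# Known limitations

* The ASL/PCL scheme is a reproducible gradient/contrast operationali-
  sation; the field's historical measurements were made with bespoke
  interactive procedures, so absolute agreement on tissue data is not
  implied.
* The greedy nearest-neighbour linker can swap identities of crossing
  particles; mean-slope MCT is insensitive to swaps among equal-velocity
  particles but per-track statistics are not.
* Metachronal wavelength, wave direction and wave speed are not
  estimated — the call is deliberately binary plus a proportion.
* AVI containers are not read; convert to multi-page TIFF.
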