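---
title: "Quantifying peripheral microtubule organization and sliding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peripheral microtubule organization and sliding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perimt)
```

## The problem

Secretory cells such as pancreatic beta cells maintain a *peripheral
microtubule (MT) array*: a bundle of MTs lying within roughly 1–2 µm of
the plasma membrane and co-aligned with it. Kinesin-1 slides intact MTs
relative to one another and to the cell, and this sliding both supplies
the periphery with MT mass and lays the filaments down along the border.
Experiments that perturb the motor therefore need quantitative answers
to four questions: how parallel are peripheral MTs to the border, how
much MT area slides into a photobleached zone, what fraction of
MT-lattice fiducial marks move, and how much tubulin intensity sits at
the periphery. `perimt` implements each readout and a simulator that
generates inputs with known ground truth for all of them.

## Directionality: model and estimator

### Border geometry

The cell footprint is a binary mask (supplied, or drawn by the
experimenter; automated segmentation is out of scope). Two fields derive
from it:

* **Distance to border.** The Euclidean distance transform, scaled to
  µm. Distances are measured from pixel centers to the sub-pixel border
  half a pixel beyond the outermost mask pixels; border pixels carry
  distance 0. Sub-pixel interpolation of the border position is not
  attempted — the error is bounded by half a pixel (0.05 µm at the
  default calibration), well below the 1 µm analysis bands.
* **Border tangent.** The gradient of the *signed* distance map
  (positive inside, negative outside), smoothed with a Gaussian of
  σ = 3 px and rotated by 90°, reported modulo 180°. The signed map is
  used because it is smooth across the border, so smoothing does not
  bias the gradient direction at boundary pixels. On a disk this
  construction is exact up to discretization; on irregular smooth masks
  the test suite compares it against an independent brute-force oracle
  (exhaustive nearest-boundary search plus total-least-squares line fit
  to the boundary within 0.5 µm) and requires 95% agreement within 5°
  in the outer 1 µm.

### Orientation

Per-pixel MT orientation uses the structure tensor: image gradients from
derivative-of-Gaussian filters (σ_g = 1 px), accumulated into the 2×2
gradient-covariance tensor with a Gaussian window (σ_w = 2 px). The
orientation of the minor eigenvector is the along-ridge direction;
coherence (λ₁ − λ₂)/(λ₁ + λ₂) measures anisotropy. A pixel is
*conclusive* when it is MT-positive under the threshold mask **and** its
coherence is at least `coherence_min` (default 0.2); all other pixels
are disregarded, which is the operational meaning we give to discarding
inconclusive pixels. The exact orientation operator used in the original
analyses of this kind is not fully specified anywhere we could follow,
so the structure tensor — the standard, testable choice — is a declared
substitute validated by simulation, not a re-implementation claim.

One non-obvious numerical choice: before gradients are taken, the image
is extended smoothly beyond the cell border (iterative neighbour
averaging of in-mask values). Without this, the intensity step at the
mask edge dominates the tensor in border-adjacent pixels and reads as
border-parallel structure; on isotropic synthetic renders this inflated
the parallel bin by 5–9 percentage points with a characteristic
monotone distortion of the whole histogram. With border extension, the
isotropic histogram is flat to within sampling error.

### Binning conventions

Angles to the border are acute differences modulo 180°, so α ∈ [0°, 90°]
with 0° parallel. Histograms use nine 10° bins, half-open
`[0,10), …, [80,90]` with the last bin closed; a value exactly on an
interior edge goes to the upper bin. The peripheral histogram uses the
half-open distance band `[0, 1)` µm. Population summaries are produced
with both pixel weighting (summing counts — cells with more detectable
MT pixels weigh more, matching reports of total pixel numbers) and
equal-cell weighting (mean of per-cell fractions), because published
summaries can be read either way.

### Conditioning chain

`directionality_analysis()` chains Richardson–Lucy deconvolution
(default on, 30 iterations, Gaussian PSF σ = 0.15 µm), thresholding, and
the estimator. RL is implemented with flux-preserving circular
convolution, so non-negativity and total intensity are conserved; the
iteration count is a declared default — the upstream workflow this
emulates does not state one. Two automatic thresholds are provided:
**standard** IsoData (iterative intermeans to convergence) over the
whole cell or pooled over a cell population, and the per-cell
**perfect** threshold, operationalized as IsoData restricted to the
outer peripheral band so that it is optimized for the peripheral array
(a manual override is accepted for parity with interactive use). On
clean synthetic renders the two variants give histograms agreeing within
5 percentage points per bin, which is the property the two-threshold
design is meant to have.

## FRAP sliding

`define_frap_rois()` splits the cell into a central unbleached belt
(default 5 µm wide) and two bleached zones; the three regions partition
the mask exactly. `displaced_mt_area()` thresholds each post-bleach
frame and reports the high-signal area inside the bleached zones,
subtracting the frame-0 residual (so area(0) = 0 by construction) and
flooring at zero; the headline readout is the area at the frame nearest
300 s. The default threshold is 50% of the mean intensity of MT-positive
belt pixels at frame 0, with MT-positive defined by IsoData within the
belt. We anchor to MT-positive pixels rather than the raw belt mean
because the raw mean scales with filament density (mostly dark
inter-filament space), which would make the cut-off fall into the PSF
halo on sparse cells; anchoring to filament brightness keeps the
"high-signal" semantics — masking out background and dim polymerizing
ends — across densities. IsoData, whole-belt-mean, and fixed-value modes
remain available, and on clean simulations the readout moves by less
than 15% when the threshold varies ±10%.

## Track motility

Track tables (CSV with track id, time, x, y; nm/ms units converted on
read) are resampled onto a common grid by nearest-sample selection
within half a grid step; gaps are left absent, never interpolated,
because the upstream tracker already performed its own gap closing.
Displacements are net Euclidean start-to-end distances over consecutive
non-overlapping 5 s windows (an overlapping mode exists behind a flag;
non-overlapping keeps observations independent). Windows missing either
endpoint are skipped; a gap-free track of duration D yields ⌊D/5⌋
windows. Classification is strict: stationary below 0.15 µm, motile
above 0.3 µm, values exactly at a threshold intermediate — 0.15 µm is a
resolution limit, so a displacement equal to it is not evidence of
immobility. Each window is one observation; published "N = … tracks"
counts are ambiguous between windows and tracks, so summaries report
both counts. Binned distributions use 0.05 µm half-open bins and report
per-cell percentages with population mean ± SEM.

## Intensity readouts and statistics

Peripheral intensity is the mean over the outer 2 µm band. Depletion
folds divide each marker-positive cell's mean intensity by the average
of the marker-negative cells in the same field of view; the readout is
exactly scale-invariant. Group comparisons implement the two tests that
accompany directionality histograms: per-bin unpaired t-tests (Welch by
default, since equal variances are not warranted) with per-cell bin
fractions as observations — the alternative reading, pooled pixels as
observations, would pseudo-replicate — and a two-sample
Kolmogorov–Smirnov test on the pooled per-pixel angle distributions. No
multiple-testing correction is applied across the nine bins, matching
the reporting convention of the source analyses; a clearly labeled
Bonferroni column is emitted alongside. Groups with a single cell get
the K-S test but refuse the t-tests.

## The synthetic generator

The generator exists to give every analysis a ground truth:

* **Masks**: smooth ellipses, superellipses, and low-order-Fourier
  blobs, on a default 0.1 µm grid. Real acquisitions rarely publish
  their pixel size in a reusable form, so 0.1 µm/px is a declared
  default, typical of a 100× / NA 1.49 system, not an inferred value.
* **Filaments**: anti-aliased polylines of 0.3 µm apparent thickness
  (a PSF-limited stained MT), traced along the border-tangent field
  (`parallel_to_border`), straight at a fixed angle to the local
  tangent, or straight with uniform orientation (`isotropic`); peak
  intensity 100 a.u. over a 5 a.u. background, Gaussian PSF σ = 0.15 µm,
  Poisson shot noise plus Gaussian read noise (σ = 2). 60 filaments per
  cell is the default density. Ground truth records each filament's
  analytic angle to the border tangent, the noiseless orientation map,
  and the noiseless pixel mask.
* **FRAP series**: frame 0 has signal only inside the belt; a stated
  number of filaments (0.5 µm thick — sliding bundles appear thicker
  than single MTs) slide lengthwise into the bleached zones at constant
  speed (default 0.02 µm/s, 10 s frames, 31 frames) and stop at the cell
  edge; bleached zones can retain a configurable residual (default 0).
  Ground truth is the noiseless rendered filament area inside the zones
  at every frame.
* **Tracks**: stationary marks are static points with Gaussian
  localization noise (σ = 0.02 µm per coordinate, so 5 s displacements
  are Rayleigh with scale σ√2); motile marks move straight at 0.1 µm/s.
  The motile count is `round(n · f_motile)` — deterministic, so
  fraction-recovery tests have exact targets.
* **Fields of view**: negative cells around a reference mean, positive
  cells around `fold` times it, multiplicative Gaussian noise.

Everything is bitwise reproducible for a fixed seed.

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate about real data: curved or bundled filaments,
3D PSFs, photobleaching and blinking during acquisition, uneven
illumination, organelle autofluorescence, segmentation error in the cell
outline, and tracker linking errors. The validation shows that the
estimators recover known geometry and kinetics through realistic blur
and noise; it cannot certify biological accuracy on real images.

## Validation problem sizes

The acceptance-level tests and `scripts/acceptance.R` run: 10 synthetic
cells per orientation model (mixed shapes, ~1.4–2k conclusive band
pixels per cell) for directionality recovery and group statistics; 5
masks (~1.7k query pixels each) for the tangent oracle; 1000 tracks per
pure population and 5 × 400 for mixtures (24 windows per track); ~10⁴
windows for the Rayleigh binning law; and FRAP series with 0–10
translocating filaments at 31 frames. These sizes give sampling error
comfortably below the tolerances being asserted while keeping a full
run in the minutes range on one CPU.

## Known limitations

* Analysis is strictly 2D, on single planes or maximum-intensity
  projections; no 3D orientation is attempted.
* Individual filaments are never segmented or traced; all directionality
  statistics are per-pixel, so a pixel where filaments cross is either
  disregarded (low coherence) or contributes a blended orientation.
* The FRAP readout cannot distinguish sliding from polymerization beyond
  its intensity threshold; dim growing ends are deliberately excluded.
* IsoData assumes a bimodal intensity distribution; a cell with
  essentially no MT signal yields a threshold driven by noise (constant
  regions raise an error instead).
* The absolute calibration of "displaced area" depends on the chosen
  threshold; comparisons should hold the threshold mode fixed across
  conditions.
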