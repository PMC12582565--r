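# perimt

Quantification of peripheral microtubule (MT) organization and
motor-driven MT sliding in single cells, from calibrated fluorescence
microscopy images and particle tracks.

In many secretory cells — pancreatic beta cells are the motivating case —
a bundle of MTs runs along the inside of the plasma membrane, co-aligned
with the cell border. Kinesin-driven *MT sliding* builds and remodels
this peripheral array, and perturbing the motor changes both how much
tubulin sits at the periphery and how parallel it lies to the edge.
`perimt` implements the image- and track-based readouts used to measure
these phenotypes, plus a synthetic-data generator with analytic ground
truth so that every stage can be validated without real microscopy data.

## The four readouts

**Border-relative directionality.** For every MT-positive pixel, the
local filament orientation is estimated from the image structure tensor
(Gaussian-derivative gradients, eigen-analysis of the smoothed gradient
covariance; pixels with coherence below a cut-off are *inconclusive* and
disregarded). The cell border geometry comes from the Euclidean distance
transform of the cell mask: distance to the border, and the border
tangent as the 90°-rotated gradient of the signed distance map. The
angle between MT orientation and local tangent, α ∈ [0°, 90°]
(α = min(|Δ|, 180° − |Δ|)), is histogrammed in nine 10° bins for pixels
within the outer 1 µm of the cell; the 0–10° bin is the "parallel" bin.
Upstream conditioning: Richardson–Lucy deconvolution, maximum-intensity
projection, and IsoData thresholding (whole-cell "standard" or
peripheral-band "perfect" variants).

**FRAP sliding.** Two regions of a fluorescent-tubulin cell are
photobleached, leaving a central "fluorescent belt". Fluorescent MTs
found inside the bleached zones afterwards can only have slid there; the
readout is the thresholded MT area in the bleached zones (µm², frame-0
residual subtracted) at 300 s (5 min) of recovery.

**Track motility.** Fiducial marks bound to the MT lattice are tracked;
tracks are resampled onto a common time grid, segmented into 5 s
windows, and the net displacement per window is binned at 0.05 µm.
Windows below 0.15 µm are *stationary* (under the resolution limit),
above 0.3 µm *motile*, in between *intermediate*.

**Intensity.** Mean tubulin intensity in the outer 2 µm of the cell, and
depletion folds of marker-positive cells normalized to the mean of
marker-negative cells in the same field of view.

## Worked example

```r
library(perimt)

# a synthetic cell whose sub-membrane MTs run parallel to the border
mask <- generate_cell_mask("ellipse", size_um = c(15, 10), seed = 1)
scene <- render_mt_image(mask, filament_spec(n_filaments = 60), seed = 2)
res <- directionality_analysis(scene$image, mask, threshold_mode = "perfect")
res$histogram
#> directionality histogram, band [0, 1) um, n = 1206 px
#>  bin_lo bin_hi count  fraction
#>       0     10  1144 0.9485904
#>      10     20    42 0.0348259
#>      20     30    12 0.0099502
#>      30     40     1 0.0008292
#>      40     50     1 0.0008292
#>      50     60     1 0.0008292
#>      60     70     1 0.0008292
#>      70     80     2 0.0016584
#>      80     90     2 0.0016584
```

95% of the conclusive MT pixels within 1 µm of the border lie within 10°
of the border tangent — the signature of an intact peripheral array (the
generator drew every filament along the border, so this is a parameter
recovery, not a discovery). The same call on an
`orientation_model = "isotropic"` render gives ≈ 1/9 per bin.

```r
# FRAP: five filaments slide out of the belt at 0.02 um/s
sim <- simulate_frap_series(mask, sliding = list(n_translocating = 5,
                                                 speed_um_s = 0.02), seed = 3)
displaced_mt_area(sim$series, sim$rois)
#> MT sliding: displaced area 12.69 um^2 at 300 s (threshold 43.3)
```

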