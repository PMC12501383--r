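---
title: "Surface-aligned dual-band projections for optoacoustic mesoscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-aligned dual-band projections for optoacoustic mesoscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emipr)
```

## The problem

Raster-scan optoacoustic mesoscopy (RSOM) images the skin microvasculature by
recording laser-excited ultrasound while a focused detector raster-scans a few
square millimetres of skin. Reconstruction yields a 3D intensity volume per
frequency band — a low-frequency band (LF, large vessels) and a high-frequency
band (HF, capillary-scale structures) — on a lattice of roughly
200 x 100 x 500 voxels at 20 x 20 x 4 um. Clinicians read these volumes as 2D
maximum intensity projections (MIPs). Two artefacts routinely degrade the
projections:

* the skin surface is tilted and often bowed relative to the scan axes, so a
  lateral MIP smears the epidermis, dermal plexus and subcutis into each other;
* a handful of very bright structures (hairs lying in the coupling gel,
  reflections, isolated strong absorbers) set the global contrast reference and
  push the vasculature into the dark end of the display range.

`emipr` implements the enhanced MIP (eMIP) pipeline addressing both: it detects
the skin surface as a low-degree bivariate polynomial, shifts every depth
column so the detected surface sits at a fixed *zero level* (depth index 100,
i.e. 400 um), and renders the corrected volumes with per-band, quantile-based
dynamic contrast. The conventional alpha-equalized MIP is implemented alongside
as the baseline, together with the rater-agreement statistics (mean opinion
scores, weighted Fleiss' kappa with jackknife variances) used to compare the
two renderings.

## Coordinate and quantile conventions

Volumes are indexed `V[i, j, k]` with `i` along the slow scan axis, `j` along
the fast axis, and `k` along depth, `k = 1` nearest the detector. R's native
1-based arrays match this convention, so every index formula in the code is
literal. "Above the surface" always means smaller `k`.

Every quantile in the package — tile thresholds, noise levels, dynamic
contrast thresholds, the finalization percentile — goes through one shared
routine, `intensity_quantile()`, which is the linear-interpolation
(type 7) convention. The inverse used by the adaptive quantile level is the
exact piecewise-linear inverse of the same convention.

## Surface detection

Detection iterates four building blocks over (by default) four outer
iterations:

1. **Find surface points.** The lateral field is split into a fixed 4 x 4
   raster of tiles with boundary fractions `(0, 0.15, 0.5, 0.85, 1)`; the
   narrow outer tiles guarantee surface points near edges and corners, where a
   polynomial fit is most easily destabilized. Per tile and per band the
   threshold is `tau/sensitivity` times the `alpha`-quantile of the
   depth-restricted z-MIP, floored globally at `0.15 * tau/sensitivity` times
   a relaxed quantile (`alpha_relaxed = alpha - (1 - alpha)/3`) of the whole
   restricted z-MIP so that empty tiles do not detect pure noise. The surface
   point of a column is the *first* voxel (smallest `k`) inside the current
   search range reaching its tile threshold; columns with no crossing
   contribute nothing. LF and HF points are pooled into one set.
2. **Fit.** Either RANSAC (planes only; 200 trials, sample size 10, inlier
   distance 30 voxels, least-squares refit on the consensus set) or penalized
   least squares: candidate degrees `1 <= n, m <= 4` are fitted on a seeded
   95% training split and scored on the held-out 5% by squared error times
   `1.01^((n-1)^2 + (m-1)^2)`, which makes higher degrees earn their keep; the
   winner is refitted on all included points. Cost ties resolve to the earlier
   candidate in row-major `(n, m)` order, favouring lower `n`. Fits are
   performed in lateral coordinates centred and scaled to `[-1, 1]` (a raw
   Vandermonde at degree 4 on a 200-wide lattice is numerically hopeless);
   coefficients are stored in that basis together with the affine transform.
3. **Exclude outliers.** Residuals `r = sfit - z` (positive = point above the
   surface). The acceptance band combines the global sample standard
   deviation `sigma` with tile-local root second moments `gamma_t` (tiles
   without residuals inherit `sigma`), capped above by an absolute distance
   `h_abs`: points survive iff `-h_bot < r < h_top` strictly, where
   `h_top = min(max(sigma_top*sigma, gamma_top*gamma), h_abs)` and
   `h_bot = max(sigma_bot*sigma, gamma_bot*gamma)`. When the band degenerates
   to zero width on an exact fit, exact-fit points are kept. Fit and
   exclusion alternate (at most 5 times) until no point is removed.
4. **Feasible range.** The next iteration may only search
   `[sfit - theta_top, sfit + theta_bot]` per column, clamped to the lattice.

After the last iteration the surface is finalized by adding
`offset = q80(r) + sd(r)/5 + 3` voxels to the constant term (population
standard deviation, per the convention locked in the tests), which places the
finalized surface on the offset side of at least 80% of the included points
and adds a 3-voxel guard against residual outliers.

### The default schedule and why it looks the way it does

The per-iteration hyperparameters are this package's own calibration — the
algorithm needs a schedule, and no canonical one is available — and every
value can be overridden from a YAML config (`load_config()`):

| k | fit | alpha | tau | multipliers | h_abs | theta (top/bot) |
|---|------------------|----------|-----|------|-----|---------|
| 1 | RANSAC plane | 0.99 | 1.0 | 4 | 200 | 150/150 |
| 2 | polyfit, fixed (1,1) | 0.98 | 0.9 | 3 | 80 | 80/100 |
| 3 | polyfit, fixed (1,1) | 0.97 | 0.8 | 2.5 | 40 | 40/60 |
| 4 | polyfit, dynamic | adaptive | 0.7 | 2 | 30 | 40/60 |

The shape follows three observations made while calibrating on phantoms:

* The first pass must be robust, not accurate: a high quantile finds only the
  most confident columns, and RANSAC ignores hairs outright.
* Dynamic degree selection must wait until the feasible range is narrow.
  Bright hairs can dominate *entire raster tiles* (a hair is a line, and a
  line crosses a tile with tens of columns); if a quartic is allowed while
  such tiles still contribute hair points, the fit bends into them and the
  subsequent range chases the bent fit. Keeping iterations 2-3 linear and
  letting only the final iteration pick its degree removes the failure mode.
* The absolute cap `h_abs` is the mechanism that removes reflections and
  hairs; the sigma/gamma band cannot do it, because the tile-local gamma term
  (whose purpose is to keep sparse tiles populated) is inflated by the very
  outliers it should reject. The final caps (40, 30) are of the order of the
  RANSAC inlier distance (30), below the clearance of hairs lying in gel and
  above any residual spread of true surface points.

In the fourth iteration the quantile level is chosen adaptively per band: the
95th percentile of the z-MIP restricted to a 41-voxel window centred on the
detector-side boundary of the surface range estimates the noise level just
above the skin; the threshold target is clamped between the
`alpha_min`/`alpha_max` quantiles of the full z-MIP, converted back to a
quantile level by inverting the empirical CDF, and un-relaxed via
`alpha = (3 * alpha_relaxed + 1)/4`.

One printed formula had to be disambiguated: the feasible-range limits are
printed as `rho_bot = sfit - theta_bot`, `rho_top = sfit + theta_top`, while
the noise window is described as lying *above* the estimated surface at
`rho_top`. With depth increasing downward these are inconsistent; the package
resolves the range as `(sfit - theta_top, sfit + theta_bot)` (detector side
first) and centres the noise window on the detector-side bound, which is the
only orientation in which the surface search starts above the skin and noise
is measured on the detector side.

## Surface correction

The finalized surface is rasterized to the nearest depth index per column
(exact halves resolve to the smaller index; out-of-lattice values clamp), and
every z-column of both bands is shifted by the one shared map so the surface
voxel lands at the zero level, `k = 100` by default. Content shifted out of
the lattice is cut; missing entries are zero-padded. Note the alignment level
is the *finalized* surface, which sits `offset` (>= 3) voxels below the
melanin sheet by construction; after flattening, the skin therefore begins a
few voxels above the zero line, and all anatomy lies in a fixed depth frame.

## Contrast and rendering

Conventional MIP: per axis, both bands are projected, the HF image is scaled
by the closed-form least-squares factor
`alpha* = <im_LF, im_HF> / <im_HF, im_HF>`, both are scaled jointly to [0, 1]
between their combined minimum and maximum, and a saturation window (defaults
0.06/0.35, linear in between) stretches the display. A single bright
structure therefore compresses everything else — the baseline's documented
failure mode.

eMIP: after flattening, each band gets its own upper threshold
`th+ = 1.25 * q0.95(z-MIP)` computed on the *corrected* volumes (flattening
only cuts voxels, so the z-MIP quantiles are nearly invariant; computing them
after correction keeps the whole rendering a function of one volume pair).
Channels are clipped at zero, capped at `th+` and divided by it — LF to red,
HF to green, blue empty. The saturation operator for the baseline is a linear
window on the jointly scaled image; the operator behind the published
0.06/0.35 convention is not formally defined anywhere, so the common
`imadjust`-style reading was chosen and is locked by tests.

Lateral renderings are displayed with depth increasing downward.

## The phantom generator

`phantom_spec()`/`generate_phantom()` emulate exactly the features the
pipeline must survive, with known ground truth:

* a melanin-like sheet, 2-4 voxels thick, starting at a polynomial depth map
  `z_true(x, y)` of degree <= 3 — the dominant signal, as the stratum corneum
  is in RSOM;
* capsule-shaped vessels below the sheet (radius 3-6 voxels in LF, 1-2 in HF,
  mirroring the large/small frequency split);
* hair-like bright segments at 1.5 x melanin intensity floating 45-90 voxels
  (0.18-0.36 mm) above the surface, as hairs do in coupling gel — close
  enough to be caught by a full-depth first-crossing scan, far enough that a
  correct detector must reject them (a "hair" closer than the final search
  half-width of 40 voxels would be indistinguishable from surface by any
  threshold-crossing rule);
* optional Gaussian noise and isolated bright outlier voxels.

Generation is a pure function of spec plus seed. The benchmark population
used by the acceptance suite (`study_phantom_spec()`) draws a plane tilt up
to +/-30 voxels across the field, centred quadratic bowing up to 15 voxels,
0-3 hairs, and noise at 10% of melanin intensity, on the default
200 x 100 x 500 lattice. The recovery requirement is a pre-offset RMSE of at
most 3 depth voxels (12 um) against ground truth in at least 18 of 20 seeded
runs; the suite runs exactly that study.

What the phantom does *not* model: acoustic point-spread and frequency-
dependent blur, fluence decay with depth, speckle, reconstruction streaks,
motion between B-scans. Passing the recovery study therefore demonstrates the
geometry of the algorithm (tiling, thresholds, robust fitting, exclusion,
flattening) under controlled outliers and noise — not clinical performance.

## Rater-agreement statistics

Perceptual quality ratings (1 bad .. 4 perfect; scans x raters, optional
repeated sessions) are ingested from CSV. The mean opinion score (MOS)
averages a rater's two sessions first, then averages across raters. Paired
MOS differences `d = MOS_eMIP - MOS_MIP` are summarized by histograms
(bin width 0.125 for MOS anchored at multiples of the width, 1/3 for
differences centred on zero; boundary values fall to the left bin, i.e. bins
are left-open right-closed), the fraction of substantial differences
(`|d| >= 0.5`), a two-sample t test (pooled variance by default, Welch and
one-sided variants available) and a Wilcoxon signed-rank test with a seeded
percentile-bootstrap CI of the median.

Agreement uses the generalized weighted Fleiss' kappa for multiple raters
with linear disagreement weights `w_ij = |i - j|/3`:
`kappa = 1 - Do/De`, where `Do` is the mean observed pairwise disagreement
within scans and `De` the expected disagreement under the pooled marginal
distribution. Scans keep their own (possibly reduced) rater count; a table
with a single used category has `De = 0` and kappa is defined as 1. The
unconditional variance is the sum of an image-sampling component (the
closed-form linearized subject-sampling variance, treating the rater panel as
fixed) and a rater-sampling component (delete-one jackknife across raters for
inter-rater agreement; the unbiased variance of the per-rater kappas divided
by the panel size for intra-rater agreement). Confidence intervals use
`kappa +/- 1.96 * SE`.

Group-of-3 agreement forms all `C(8,2) * C(6,3) = 560` ordered pairs of
disjoint rater triples (the published construction counts each unordered pair
twice; kappa is symmetric, so the mean is unaffected), averages each group's
ratings per scan, and treats the ten attainable averages `3/3 .. 12/3` as an
ordinal scale with linear weights. Because averaged scores must live on that
attainable grid, group agreement uses first-session integer ratings. The
image-sampling variance of the group coefficient is the plain sum of the 560
per-pair variances — the published formula carries no normalizing factor and
is implemented as printed — and the rater-sampling variance is the delete-two
jackknife over the 28 six-rater subsets with prefactor `(8-2)/(2*8)`.

Agreement gains `kappa_eMIP - kappa_MIP` are tested one-sidedly against the
normal approximation, with the rater-sampling variance of the *paired*
difference supplied by the matching resampling scheme (delete-one jackknife,
per-rater paired differences, or delete-two jackknife). A zero gain with zero
variance reports p = 0.5 by continuity.

## Numerical and degenerate-case choices

* Rasterization ties (exact `.5`) go to the smaller depth index; out-of-range
  surface values clamp instead of erroring.
* A feasible range that contains no integer depth after clamping collapses to
  the nearest single voxel rather than erroring.
* `alpha_optimize` returns 0 with a warning for an identically zero HF image;
  joint scaling of a constant image pair returns a black image with a warning;
  a non-positive dynamic threshold renders that channel black.
* The train/test split and all RANSAC sampling derive from
  `DetectionConfig$random_seed` (per-iteration seeds are fixed offsets of
  it), so detection is bit-reproducible; the split is drawn once per fit
  call, not per candidate degree.
* Fewer than two residuals: exclusion is skipped with a warning and the
  finalization offset falls back to the bare 3-voxel guard.

## Problem sizes used by the test-suite studies

The recovery study runs 20 phantoms at the full default lattice
(200 x 100 x 500). Unit tests use 60 x 40 x 300 phantoms, which preserve all
geometric features (16 non-degenerate tiles, hairs above, vessels below) at a
fraction of the cost. The agreement simulations use 40-500 scans and 3-8
raters; the chance-level check uses 500 scans so that `|kappa| < 0.05` is a
meaningful bound on the estimator rather than on sampling noise.

## Known limitations

* The hyperparameter schedule is a phantom-calibrated default, not a
  clinically validated one; real scans with very weak melanin contrast or
  dense hair coverage may need a custom config (that is what `sensitivity`
  and the YAML schedule are for).
* Flattening shifts whole columns by integer offsets; there is no sub-voxel
  interpolation and no lateral motion correction.
* The kappa image-sampling variance follows one published closed form; other
  variants in the literature differ at O(1/n) and would give slightly
  different CIs (point estimates are unaffected).
* The float-TIFF layer implements the minimal classic-TIFF subset it writes
  (little-endian, uncompressed, grayscale float strips); exotic third-party
  TIFFs should go through NIfTI instead.
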