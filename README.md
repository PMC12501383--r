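# emipr

Surface-aligned, contrast-equalized renderings of dual-band raster-scan
optoacoustic mesoscopy (RSOM) volumes — the *enhanced maximum intensity
projection* (eMIP) — together with the conventional MIP baseline and the
rater-agreement statistics used to compare the two.

RSOM reconstructs the skin microvasculature as two co-registered 3D volumes,
a low-frequency band (LF, larger vessels) and a high-frequency band (HF,
capillary-scale structures), typically 200 x 100 x 500 voxels at
20 x 20 x 4 µm. Plain MIPs of these volumes suffer from two artefacts: the
skin surface is tilted/bowed with respect to the scan axes, smearing the
anatomy in lateral projections, and isolated bright structures (hairs,
reflections, strong absorbers) set the contrast reference and darken the
vasculature. `emipr` addresses both:

1. **Surface detection** — iterative first-crossing selection of candidate
   surface voxels under tile-local quantile thresholds on a 4 x 4 raster,
   robust fitting of a bivariate polynomial `sfit(x, y) = Σ c_ik x^i y^k`
   (RANSAC planes first, penalized least-squares degree selection with
   penalty `1.01^((n-1)² + (m-1)²)` later), outlier exclusion inside a
   `σ`/tile-local-`γ` band capped by an absolute distance, and progressive
   narrowing of the per-column search range; finalized with the safety
   offset `q80(r) + sd(r)/5 + 3`.
2. **Surface correction** — per-column integer shifts
   `s_ij = argmin_k |sfit(i,j) − k|` aligning the detected surface at the
   zero level `k = 100` (400 µm), cut/zero-padded at the volume limits.
3. **Dynamic contrast** — per band, channels are clipped, capped at
   `th⁺ = 1.25 · q0.95(z-MIP)` and scaled to [0, 1] (LF → red, HF → green),
   so no single absorber owns the display range. The baseline MIP instead
   equalizes the bands by the least-squares factor
   `α* = ⟨im_LF, im_HF⟩/⟨im_HF, im_HF⟩`, scales jointly and saturates at
   0.06/0.35.
4. **Agreement statistics** — mean opinion scores (1–4 scale) with repeat
   averaging, paired difference tests (t, Wilcoxon + bootstrap CI),
   generalized weighted Fleiss' kappa (linear weights `|i−j|/3`) with
   closed-form image-sampling variance and jackknife rater-sampling
   variance, group-of-3 agreement over all 560 disjoint rater-triple pairs,
   and one-sided gain tests.

A synthetic phantom generator (melanin sheet on a known polynomial surface,
band-specific vessels, hairs floating above the skin, noise and outliers)
provides ground truth for every stage; no clinical data is needed.

## Worked example

```r
library(emipr)

# A phantom with a tilted, bowed surface, two hairs and 10% noise
ph  <- generate_phantom(study_phantom_spec(seed = 42))
cfg <- detection_config()
det <- detect_surface(ph$pair, cfg)
det
#> <surface_detection> degree (2,1), offset 3.363, 38154/39965 points included

# Recovery against the known ground truth (pre-offset RMSE, in voxels)
est <- sf_eval_grid(det$surface, 200, 100) - det$offset
sqrt(mean((est - ph$truth$true_surface)^2))
#> [1] 0.01062283

# Flatten and render
imgs <- render_emip(ph$pair, det$surface, cfg)
attr(imgs, "thresholds")
#> $th_lf_plus
#> [1] 151.7254
#> $th_hf_plus
#> [1] 151.4774
write_rgb_png(imgs$y, "y-emip.png")   # straightened skin line, depth downward
```

The selected degree (2,1) matches the phantom's quadratic-in-x bow; the
offset (~3.4 voxels) is the deliberate safety margin placed between the
finalized surface and the detected surface points, and the RMSE of 0.011
voxels shows the pre-offset surface tracks the true phantom skin almost
exactly. The dynamic thresholds are what each colour channel is normalized
by: 1.25 × the 95th z-MIP percentile, where per-column noise maxima and the
phantom's hairs lift the upper tail above the melanin intensity of 100.

Rating tables are analysed either from R (`mos()`, `mos_differences()`,
`inter_kappa()`, `group3_kappa()`, `inter_kappa_gain()`, ...) or from the
shell:

```sh
Rscript inst/cli/emip.R phantom --out-dir scan --seed 7
Rscript inst/cli/emip.R emip  --lfr scan/lfr.tif --hfr scan/hfr.tif --out-dir scan/out
Rscript inst/cli/emip.R agree --ratings ratings.csv --out report.json
```

Subcommands: `phantom`, `detect-surface`, `mip`, `emip`, `agree`; every run
writes a `manifest.json` with flags, input hashes and timings. Exit codes:
2 bad input, 3 surface not found.

## Layout

| path | contents |
|---|---|
| `R/volume.R`, `R/io.R`, `R/io_tiff.R`, `R/config.R` | containers, TIFF/NIfTI/PNG/JSON/YAML IO |
| `R/tiling.R` | raster tiles, restricted z-MIP, local + adaptive thresholds |
| `R/surface_detection.R` | surface points, RANSAC/polyfit, exclusion, iteration |
| `R/surface_correction.R` | rasterization and z-column flattening |
| `R/projection.R` | MIPs, alpha/joint and dynamic contrast fusion |
| `R/agreement.R` | MOS, histograms, tests, weighted Fleiss' kappa machinery |
| `R/phantom.R` | synthetic scan generator with ground truth |
| `vignettes/emip-methods.Rmd` | model, conventions, calibration rationale |
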