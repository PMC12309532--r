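---
title: "Automated adipocyte sizing: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated adipocyte sizing: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiposizer)
```

## The measurement problem

White adipocytes in H&E-stained sections appear as large, bright,
near-circular lipid lumens bounded by thin dark membranes. Their
cross-sectional size is a routine readout in metabolic research: mean cell
diameter tracks adiposity, insulin resistance and depot-specific biology.
The classical workflow — an operator measuring ~100 cells per section by
hand — is slow and subject to selection bias (better-looking subregions,
conspicuous large cells). `adiposizer` implements a fully automated
alternative that processes whole-slide images with one fixed operator
recipe, so every sample in a batch is measured identically and the result
is reproducible bit-for-bit.

## The segmentation recipe

Each slide passes through a fixed sequence:

1. **8-bit conversion.** RGB input is collapsed by the unweighted channel
   mean `(R+G+B)/3`, rounded half-up. ITU-R BT.601 luma weights are
   available (`weights = "itu601"`) for sensitivity analysis; the default
   is the plain mean because the downstream threshold is recomputed per
   image, making the conversion choice largely immaterial.
2. **Triangle (Zack) auto-threshold.** A line is drawn from the histogram
   peak to the farthest nonzero bin on the peak's *longer-tail* side; the
   returned level maximises the perpendicular distance between histogram
   and line. Because only histogram shape matters, the level adapts to
   staining intensity and illumination differences between slides. With
   dark-background polarity the strict comparison `intensity > level`
   makes the bright lumens foreground.
3. **Noise cleanup.** One binary erosion (3×3 square element,
   out-of-bounds treated as background), removal of bright outliers with a
   circular-median filter of radius 2.5 px and deviation threshold 50,
   a second erosion, and a second outlier pass at radius 5.5 px. Disk
   membership is Euclidean (`dx² + dy² ≤ r²`), giving 21- and 97-pixel
   kernels; clamped border neighbourhoods use the lower median. A pixel is
   replaced by its neighbourhood median only when it exceeds it by more
   than the deviation threshold, so speckle disappears while coherent
   lumens survive.
4. **Particle analysis.** 8-connected components are measured in physical
   units and gated: area within **315–40000 µm²** (equivalent circular
   diameters ≈ 20–225 µm), circularity within **0.63–1.00**, and
   edge-touching particles excluded. Objects below the window are debris
   or non-adipocyte profiles; objects above it are almost always two or
   more cells whose shared membrane collapsed, and counting them would
   inflate the mean; the circularity gate exploits the roundness of intact
   mature adipocytes. Merged cells are *excluded*, never split.

All parameters are exposed (`seg_params()`, `particle_filter()`) but the
defaults are the validated recipe and should be changed only with reason.

### Fixed conventions

Several conventions are pinned down so that independent implementations
can agree bit-for-bit:

* Triangle peak = lowest modal bin; tail side = longer side of the peak,
  ties toward the foreground side; distance ties resolve to the lowest
  level. A single-nonzero-bin histogram returns that bin, so a uniform
  (blank) image yields an empty mask rather than an error.
* Thresholding is strict (`>` for dark background), so a uniform image at
  the threshold level itself maps to background.
* Erosion border policy: outside pixels are background, so one pass
  removes a one-pixel shell everywhere, including the image border.
* An N-pass erosion of an M-pixel bar leaves `max(M − 2N, 0)` pixels — the
  systematic size bias discussed under *Accuracy* below.

## Size measurement

Areas are pixel counts times `pixel_size²`; interior holes are excluded
(an `include_holes` switch reverses this). Perimeters come from the
Moore-traced outer contour using corner-corrected chain-code weights —
0.980 per axial step, 1.406 per diagonal step, −0.091 per direction
change — plus a half-pixel boundary offset of π pixels that accounts for
the pixel-centre polygon lying half a pixel inside the physical particle
boundary. A plain `1/√2`-weighted chain code systematically overestimates
smooth boundaries by ≈ 5.5%, which would depress circularity of a perfect
digital disk to ≈ 0.91 and distort the circularity gate; the corrected
estimator keeps both a rasterised disk (circularity ≥ 0.99 at r = 100 px)
and a rasterised square (0.827 vs the analytic π/4 ≈ 0.785) within a few
percent of their analytic values. Circularity `4πA/P²` is capped at 1 for
coarse discretisations.

Retained areas are reported as equivalent circular diameters
`d = 2·sqrt(A/π)`; per-sample summaries use the mean and the n−1 sample
SD, unrounded.

## Quality control

Per-sample cell counts gate the result: **≥ 200** retained cells is `ok`;
**100–199** is `inspect` — kept, but flagged for visual review, because a
low count can indicate a segmentation problem rather than sparse tissue;
**< 100** is `excluded`, since too few cells estimate the mean
unreliably. The count used is the *gated* (retained) count. For flagged
slides, `rethreshold_sample()` re-runs the pipeline at a hand-picked
level and marks the output `rethresholded`. `consolidate()` keeps one row
per sample whatever its fate; excluded samples carry `NA` summaries and
contribute nothing to the long-format diameter table.

## Method-comparison statistics and clinical indices

For validating one sizing method against another on paired per-sample
means, the package provides Bland–Altman agreement (`mean ± 1.96·SD`
limits on `method_b − method_a`; the difference direction is fixed so a
smaller-reading test method gives negative bias), paired t-tests (with
the zero-variance cases handled explicitly: identical methods give
`t = 0, p = 1`; a constant nonzero difference flags an infinite t),
Pearson/Spearman correlations, and Meng's Z-test for comparing two
correlated correlations that share a criterion. Meng's formula needs the
predictor intercorrelation `r12` as an explicit input — it is a property
of the paired data and cannot be inferred from the two criterion
correlations; the shrinkage factor `f` is clipped at 1 as in the original
method. The clinical indices HOMA-IR
(`insulin [µU/mL] × glucose [mmol/L] / 22.5`) and the sex-specific VAI
equations are provided for building validation panels against metabolic
markers.

## The synthetic tissue generator

Because validated patient slides cannot ship with a package, end-to-end
behaviour is established on generated images with known per-cell ground
truth. The generator emulates the features the pipeline actually relies
on:

* bright lumens on a membrane-intensity background, placed by dart
  throwing with centre separation at least the sum of radii plus a
  membrane thickness (default 2.5 µm), largest cells first;
* diameters from a truncated normal, default 65 ± 10 µm bounded to
  20–225 µm — the adult human range matching the gate window;
* outlines perturbed by 2nd/3rd-order radial harmonics (amplitude ≤ 5% of
  radius) so circularity spans realistic values just below 1;
* a linear illumination gradient (default 10% edge-to-edge) and Gaussian
  intensity noise (default SD 8);
* a configurable fraction of cells (default 5%) given a membrane breach —
  a lumen-bright corridor fusing them with their nearest neighbour — to
  exercise the oversize/misshape exclusion path for damaged tissue.

Default geometry is 4000×4000 px at 0.5 µm/px with 300 cells, a
whole-slide-scale problem that still analyses in well under a minute.
Output is deterministic per seed and the caller's RNG stream is
preserved.

What the generator does **not** model: fibrosis, immune infiltrates,
stain deconvolution subtleties, scanner vignetting beyond a linear ramp,
out-of-focus regions, and sectioning artefacts other than the stylised
membrane breach. Passing the synthetic suite therefore demonstrates that
the operator chain and its gates behave as specified, not that every real
slide will segment perfectly — which is exactly why the count-based QC
gates and the manual rethreshold hook exist.

## Accuracy, and the bias the recipe accepts

Two erosion passes remove a two-pixel shell from every lumen, so measured
diameters run ≈ 4 px (2 µm at 0.5 µm/px, about 3–4% at 65 µm) below
truth. On the default fixture the matched per-cell error is a stable
−2.6 µm with recall 1.0 for undamaged, fully-interior cells, and the
recovered mean sits within 4% of the ground-truth mean — inside the 5%
envelope we consider acceptable for a fixed, operator-free recipe. This
systematic undersizing relative to boundary-tracing manual measurement is
inherent to the cleanup steps and consistent across samples, so
between-sample contrasts are unaffected.

A known failure mode of triangle thresholding is worth stating: when
noise pushes a substantial pixel mass to the clipped extremes (0 or 255),
the saturated bin can capture the histogram peak and the level collapses
toward the extreme, detecting almost nothing. On the generator this
occurs around noise SD 30–60 (with recovery at even higher noise when the
opposite extreme wins) — far outside the realistic staining-noise regime
(SD ≲ 20), but it is precisely the situation the `inspect`/manual
rethreshold QC path is designed to catch, and the test suite constructs
such a slide deliberately.

## Numerical and degenerate-input choices

* Calibration: explicit override > TIFF resolution tags > error — a
  silently assumed pixel size would corrupt every µm² gate. The package's
  own TIFF writer stores calibration as rational resolution tags at
  10⁻⁶ µm precision, making write→load round-trips exact.
* Grayscale conversion rounds half-up; all intensity data are integer
  0–255 throughout the pipeline.
* Zero retained particles: `n = 0`, `NA` mean/SD, QC `excluded` — never
  an error. A blank image thresholds to an empty mask.
* Single-pixel particles get area one pixel and capped circularity 1.
* Greedy ground-truth matching uses a 15 µm centroid cap by default,
  roughly a quarter of the default mean diameter, small enough that
  distinct cells (separated by at least the sum of radii) cannot be
  confused.
* Problem sizes used by the automated validation: the default
  4000×4000/300-cell fixture for end-to-end recovery, 2000×2000 fixtures
  for the QC bands, and 100 random 64×64 images per operator for
  bit-exact comparison against brute-force reference implementations.

## Known limitations

* Merged cells are excluded rather than separated; heavily damaged
  sections lose cells and eventually fail QC (by design).
* The perimeter estimator, while accurate to ≈ 1% on disks and squares,
  is still a digital estimator; circularity near the 0.63 gate can differ
  by a few hundredths from other platforms' estimators, so gate-edge
  particles may be retained or dropped differently elsewhere.
* Only mean diameter (and SD) are summarised per sample; full
  size-distribution modelling is out of scope.
* Tiled analysis of slides larger than memory is not managed; if tiling
  externally, tiles must overlap by at least one maximum cell diameter,
  and edge exclusion applies per tile.
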