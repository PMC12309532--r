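# adiposizer

Automated measurement of white adipocyte cross-sectional size from
whole-slide images of H&E-stained adipose tissue, for metabolic-research
labs that need per-sample mean cell diameters at batch scale without
operator-dependent manual sizing.

Adipocytes appear in H&E sections as bright, near-circular lipid lumens
bounded by thin dark membranes. `adiposizer` segments them with one fixed,
fully scriptable recipe and converts every retained cell's area *A* to an
equivalent circular diameter

    d = 2 * sqrt(A / pi)

The recipe: 8-bit conversion → triangle (Zack) auto-threshold (dark
background, strict `>`) → binary erosion (3×3) → circular-median bright
outlier removal (radius 2.5 px, threshold 50) → erosion → outlier removal
(radius 5.5 px) → 8-connected particle analysis gated on area
**315–40000 µm²** (≈ 20–225 µm diameter), circularity **0.63–1.00**, and
edge exclusion. Per-sample results pass cell-count quality control
(≥ 200 `ok`, 100–199 `inspect`, < 100 `excluded`) and consolidate into one
tidy table per batch. Companion statistics cover method comparison
(Bland–Altman limits of agreement, paired t-tests, Pearson/Spearman
correlations, Meng's Z-test for correlated correlations) and the clinical
indices HOMA-IR and VAI. A synthetic H&E-like tissue generator with known
per-cell ground truth makes the whole pipeline testable end to end.

## Worked example

```r
library(adiposizer)

# a synthetic slide with known ground truth (2000x2000 px, 0.5 um/px)
gen <- generate_tissue(tissue_params(
  width = 2000L, height = 2000L, pixel_size = 0.5,
  n_cells = 230L, diameter_mean = 65, diameter_sd = 10, seed = 42L))

res <- analyze_slide(gen$image, sample_id = "demo", depot = "omental")
res$measurement
#> <sample_measurement> demo (omental): 122 cells, mean 62.2 um, SD 11.8 um, QC inspect
res$mask
#> <binary_mask> 2000 x 2000 px, 0.5 um/px, 48.7% foreground, threshold 192
```

The automatic triangle threshold landed at 192 for this slide; 122 cells
passed the size/circularity/edge gates, so the sample is kept but flagged
`inspect` (fewer than 200 cells — at this density a 2000×2000 px crop
simply holds fewer cells than a whole slide; a low count on a real slide
is the cue to look at the image and, if needed, re-run with
`rethreshold_sample()`). The mean diameter of 62.2 µm sits a little below
the generated 65 µm because the two erosion passes in the recipe shave
one pixel per side per pass — a stable, documented bias of about 2 µm at
this calibration.

Comparing two methods' per-sample means:

```r
ba <- bland_altman(c(71.2, 80.5, 68.3, 90.1, 75.0),   # method A (reference)
                   c(60.0, 70.2, 55.9, 78.3, 61.5))   # method B (test)
ba
#> <agreement_result> n = 5, mean difference -11.84, LoA [-14.21, -9.47]
plot_bland_altman(ba)
```

Method B reads on average 11.8 µm below method A; 95% of individual
samples are expected to disagree by −14.2 to −9.5 µm.

For batches there is a directory-level driver
(`run_batch("slides/", "results/")` writes `summary.csv`,
`diameters.csv` and one particle table per slide) and a thin CLI at
`inst/cli/adiposizer.R` with subcommands `run`, `rethreshold`, `compare`,
`indices` and `fixture`.

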