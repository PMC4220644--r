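# morphotex

Morphometric analysis of the **spatial complexity** of segmented tissue
patterns in bright-field histology.

First-order morphometry (area fractions, densities) cannot tell apart two
tissues that contain the *same amount* of a component arranged in
*different patterns*. The motivating case is the connective-tissue stroma
of a lobulated organ such as the carotid body: aging and chronic insult
can both raise the connective fraction to a comparable level, yet one
condition produces far more intralobular branching than the other.
`morphotex` quantifies that difference with second-order descriptors and
the inference machinery to test them:

- **Segmentation** — red-channel extraction (blue-collagen trichromes are
  dark in red), Otsu or manual thresholding, connected-component geometric
  filtering (area and circularity 4πA/P²), topology-preserving
  skeletonization, area fraction.
- **Dispersion** — Morisita's quadrat index
  `I_d = n (Σ X_i² − N) / (N (N − 1))` over a 12-quadrat grid.
- **Texture** — gray-level co-occurrence matrix `P(i,j)` at offset (d, θ)
  and the four classical features: entropy `−Σ P log P`, angular second
  moment `Σ P²`, variance `Σ (i − μ)² P`, correlation
  `(Σ ij P − μxμy) / (σxσy)`.
- **Fractal geometry** — multi-origin box-counting dimension
  `D = −slope of log N(s) vs log s`, averaged over seeded grid origins,
  and lacunarity as the mean coefficient of variation σ/μ of box masses
  over all grid sizes and origins; both computed on the skeleton by
  default.
- **Group statistics** — one-way ANOVA, Monte-Carlo Dunnett comparisons
  vs. a control group, Bonferroni-adjusted selected pairs, and empirical
  ROC curves with accuracy bands (AUC < 0.6 no value, then poor / fair /
  good / ≥ 0.9 excellent).
- **Synthetic ground truth** — a generator of histology-like images
  (Voronoi lobules, interlobular septa, random-walk intralobular branches)
  in which connective-tissue area fraction and branching complexity are
  *independently tunable*, plus a calibration routine that matches cohorts
  on area fraction. This is what makes the whole pipeline testable end to
  end.

## Worked example

Two synthetic cohorts, pre-calibrated (via `calibrate_area_fraction()`) to
the same 0.40 truth connective fraction, differing only in branch density
(0 vs 8 branches per lobule):

```r
library(morphotex)

specs <- list(
  sparse   = tissue_spec(branch_density = 0, septum_thickness = 17.98, seed = 1),
  branched = tissue_spec(branch_density = 8, septum_thickness = 17.24, seed = 1)
)
sim <- simulate_cohorts(specs, n_per_group = 10, seed = 99)
res <- run_study(sim$manifest)
res$anova
res$roc
```

```
         feature      F        p
1  area_fraction   2.90 1.06e-01
7      fractal_D 351.93 2.90e-13
8     lacunarity 323.74 5.93e-13
...
         feature  auc      band
1  area_fraction 0.33  no_value
7      fractal_D 1.00 excellent
```

The study reproduces the logic the package exists for: the **amount** of
connective tissue does not differ between the cohorts (area-fraction
ANOVA p = 0.11, AUC in the no-value band), while the **arrangement** does
— the fractal dimension of the skeleton separates the groups completely
(p ≈ 3e−13, AUC 1.0, "excellent" band), with lacunarity close behind.
Note that decreasing features (lacunarity, ASM) need
`roc_direction` set to `"lesser_is_positive"` in the `stats` config block
to report their discriminating power on the usual AUC > 0.5 scale.

Single images work the same way:

```r
spec <- tissue_spec(branch_density = 6, seed = 42)
gen  <- make_tissue_image(spec)          # image + exact truth mask
analyze_image(gen$image)
#  area_fraction morisita_index entropy       asm fractal_D lacunarity status
#          0.267           1.53   7.664 0.0007156     1.224      1.876     ok
```

`analyze_image()` also accepts TIFF/PNG paths; `run_study()` accepts a
manifest CSV (`image`, `subject_id`, `group`) and writes the full set of
feature/summary/ROC tables as CSV when given `out_dir`. A thin command
line wrapper with `simulate` / `features` / `study` verbs is installed at
`inst/scripts/morphotex.R`. All stage parameters live in one YAML
configuration (see `default_config()`), and every feature record carries a
hash of the configuration that produced it.

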