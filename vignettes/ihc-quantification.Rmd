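---
title: "Counting immunostained cells: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting immunostained cells: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcquant)
```

## The problem

Immunohistochemistry (IHC) marks cells expressing a target antigen with a
coloured chromogen on top of a counterstain (here: an alkaline-phosphatase
red product for CD117-positive mast cells over Harris hematoxylin).
Quantifying such cells by eye is slow and subjective; `ihcquant` implements
a reproducible computer-based protocol: separate the chromogen from the
counterstain, binarize, exclude non-specific structures, count connected
particles inside a physical area window, and report densities per region
in cells/mm². It also implements the agreement statistics used to validate
such a protocol against repeat counts and a pathologist's manual counts,
and a synthetic image generator so that every stage is testable with exact
ground truth.

## The optical model

Brightfield absorbances combine approximately additively in optical
density (Beer–Lambert). Per pixel and RGB channel,

$$OD_c = -\log_{10}\!\frac{I_c + \varepsilon}{I_0},
\qquad I_0 = 255,\ \varepsilon = 1/255,$$

floored at 0 so that pure white maps exactly to the zero vector (the raw
formula is infinitesimally negative at $I_c = 255$). With unit OD
direction vectors of the stains as columns of a matrix $M$, the mixing
model is $OD = M\,c$ and colour deconvolution is the per-pixel solve
$c = M^{-1} OD$. Concentrations are stored unclipped (noise can make them
slightly negative) so that re-mixing reconstructs the OD field to floating
precision; clipping happens only inside `binarize()`.

The default stain vectors pair hematoxylin $(0.650, 0.704, 0.286)$ with a
fast-red-type chromogen $(0.214, 0.851, 0.478)$; the third column is the
normalized cross product (a residual channel). These are conventional
values for this stain pair, not estimates from data — stain-vector
estimation (Macenko-style) is deliberately out of scope, and the matrix is
fully configurable.

## From mask to counts

1. **Binarization.** Otsu's threshold (256-bin histogram, between-class
   variance maximization) on the chromogen concentration plane by default;
   a fixed threshold is available and required for constant planes, where
   Otsu is undefined and raises an error rather than guessing.
2. **Exclusion.** A binary mask (nonzero = excluded) removes stained
   cutaneous appendages and non-specific foci *before* labelling, matching
   the manual-subtraction step of the interactive protocol while keeping
   runs reproducible.
3. **Particle analysis.** 8-connected components (the common
   particle-analysis default; 4-connectivity is available), each with an
   exact pixel count and physical area $A = n_{px} \cdot s^2$ for
   calibration $s$ in µm/px.
4. **Area filter.** Particles with $8 \le A \le 300$ µm² count as mast
   cells. Both bounds are inclusive: the protocol's wording ("between 8 to
   300") does not decide this, so inclusivity is fixed here and logged in
   every result row. `calibrate_area_range()` rebuilds such an interval
   from expert-confirmed areas as an empirical quantile range.
5. **Regions.** Depth bands are measured from a basal-membrane polyline as
   Euclidean distance (exact distance transform of the rasterized line, in
   µm), not vertical offset, so a curved epidermis is handled; for a
   straight horizontal line the two coincide, which is tested. A band
   $(lo, hi)$ contains dermal-side pixels with $lo < d \le hi$, so
   consecutive bands partition the dermis exactly; the defaults are the
   subepidermal 0–296 µm and deep dermal 296–1184 µm bands.
6. **Sampling and density.** Optionally, $n$ high-power fields (default
   protocol: 5) are drawn uniformly without replacement from all positions
   whose centre lies in the region, with an explicit integer seed recorded
   in the results. Particles are assigned to fields by centroid, counted
   at most once, and the pooled density count/total-area is the primary
   result; per-field rows are emitted alongside (whether the original
   protocol pooled or averaged is not stated — pooling is the less noisy
   default and both are reported). With sampling off, the whole region is
   the denominator. Density is `n_cells / sampled_area_mm2`, exactly.

Particles touching the image border are kept, and there is no
touching-cell splitting (watershed); both are conventions the interactive
protocol never specifies, chosen here for determinism and logged.

## Agreement statistics

Validation of such a protocol rests on repeat counts of the same
specimens. `ihcquant` implements:

- **ICC(2,1)** — two-way random effects, absolute agreement, single
  measures, the common SPSS choice for method comparison:
  $ICC = (MS_R - MS_E) / (MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$,
  with $p$ from $F = MS_R/MS_E$ on $(n-1, (n-1)(k-1))$ df. The exact
  variant used by the original SPSS analysis is unstated; the form is
  printed in the result so users can see exactly what was computed.
- **CV%** of a pair of counts, $100\sqrt{2}\,|a-b|/(a+b)$ (sample SD over
  mean).
- **Bland–Altman** limits of agreement, $\bar d \pm 1.96\,SD(d)$, with no
  small-sample bias correction (the conventional plot).
- **Wilcoxon signed rank**, two-sided, zeros dropped, midranks for ties;
  exact p by dynamic programming over the null distribution for ≤ 25
  informative pairs (valid under ties, checked against full $2^n$
  enumeration), normal approximation with tie and continuity correction
  above.

A nucleus criterion (`nucleus_filter()`) exists but is **off** by default:
the computer-based protocol's inclusion rule is purely the area interval,
with nucleus checks folded into the manual subtraction; the filter is
provided for pipelines that want it explicit, defined as ≥ a configurable
fraction of the 1-px-dilated particle overlapping the counterstain's Otsu
foreground.

## What the synthetic generator does and does not emulate

`generate_scene()` renders, in OD space on a white background: elliptical
cells (axis ratio uniform in [1, 2]) with areas drawn lognormal
(median ≈ 60 µm², log-sd 0.45) truncated to the counting range, each with
a concentric counterstained nucleus of 40% of the cell area; oversized
appendage-like distractors (450–1500 µm²) covered by a ready-made
exclusion mask; sub-minimum specks (1–6 µm²); optionally anucleate
chromogen foci and a straight or sinusoidal basal line (objects placed
dermally only). Gaussian noise (sd 0.02 OD) is added before conversion to
8-bit RGB. The default 0.5 µm/px emulates a 200× scan. Object placement is
rejection sampling with a 3-px minimum gap, so 8-connected labelling can
never merge objects; ground-truth areas are the rendered pixel areas, so
truth and raster agree exactly.

What it does **not** emulate: tissue texture and illumination gradients,
overlapping or touching cells, stain variability within an object,
chromogen–counterstain spatial correlation, or real appendage morphology.
A green end-to-end test therefore establishes that the pipeline's
geometry, calibration and bookkeeping are exact under the stated optical
model — not that segmentation is robust to real-world stain variation,
which is precisely why the original protocol was validated with ICCs
against a pathologist.

## Numerical choices

- $\varepsilon = 1/255$, $I_0 = 255$; OD floored at 0.
- Otsu on 256 bins over the finite value range; the returned threshold is
  the bin edge at the maximizing split; strict `>` for foreground.
- Quantiles in `calibrate_area_range()` are type-7 (R's default linear
  interpolation), so levels (0, 1) return the observed min/max.
- Degenerate inputs error early with typed conditions
  (`ihcquant_validation_error`, `ihcquant_io_error`) rather than warn.
- All randomness (field sampling, scene generation, ratings simulation)
  goes through an explicit seed and restores the caller's RNG state.
- Results CSVs are written with fixed `%.17g` formatting: write→read
  round-trips are lossless and identical runs are byte-identical.

## Known limitations

- The basal polyline must be single-valued in the column direction (a
  function of x); pathological foldings are not supported.
- Anisotropic pixel calibrations and whole-slide pyramidal formats are out
  of scope; TIFF support is limited to the 8-bit uncompressed baseline
  (use PNG otherwise).
- Sampled fields may overlap for small regions; the pooled denominator
  assumes the drawn field areas are distinct tissue. Counting by centroid
  makes double counting impossible regardless.
- ICC confidence intervals are not computed (only the F-test p-value).
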