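# ihcquant

Reproducible counting of chromogen-positive cells in calibrated
brightfield immunohistochemistry (IHC) images, plus the agreement
statistics used to validate such counts against repeat and expert counts.

Built for histology workflows like mast-cell quantification in skin
sections: CD117⁺ cells marked by a red alkaline-phosphatase chromogen over
a hematoxylin counterstain, counted per region (subepidermal band, deep
dermal band, granulation tissue) as densities in cells/mm².

## The method

1. **Colour deconvolution.** Per pixel, optical density
   `OD_c = −log10((I_c + ε)/I0)` (ε = 1/255, I0 = 255); stain absorbances
   mix additively (Beer–Lambert), `OD = M·c` with unit stain vectors as
   columns of `M`, so concentrations are `c = M⁻¹·OD`.
2. **Binarization** of the chromogen plane (Otsu by default, fixed
   threshold available).
3. **Exclusion** of non-specifically stained structures via a binary mask
   (the reproducible stand-in for interactive manual subtraction).
4. **Particle analysis**: 8-connected components; a particle of `n` pixels
   at `s` µm/px has area `n·s²`; cells are particles with area in
   **[8, 300] µm²** (inclusive).
5. **Regions**: depth bands measured from a basal-membrane polyline by
   exact Euclidean distance transform — defaults 0–296 µm (subepidermal)
   and 296–1184 µm (deep dermal) — or the whole image.
6. **Sampling/density**: optional seeded random high-power fields (5 by
   convention), pooled density `count / area` plus per-field rows.

Validation statistics: ICC(2,1) (two-way random effects, absolute
agreement, single measures) with its ANOVA F-test, pairwise CV%
(`100·√2·|a−b|/(a+b)`), Bland–Altman 95% limits of agreement, and an exact
tie-aware two-sided Wilcoxon signed-rank test.

A synthetic scene generator (`generate_scene()`) renders IHC-like images
in OD space with exact per-pixel ground truth — in-range cells with
nuclei, oversized appendage-like distractors plus their exclusion mask,
sub-threshold specks — so the entire pipeline is testable without any
slide data.

## Worked example

```r
library(ihcquant)

# a synthetic scene: 30 in-range cells, 5 masked distractors, 10 specks
scene <- generate_scene(scene_spec(seed = 1))
run <- run_quantify(scene$image, exclusion = scene$exclusion_mask)
print(run)
#> <quant_run>
#>    specimen region n_cells sampled_area_mm2 density_per_mm2
#> 1 specimen1   full      30         0.065536        457.7637
```

All 30 ground-truth cells are recovered: the distractors are removed by
the exclusion mask, the specks by the area filter. The 512×512 px canvas
at 0.5 µm/px is 0.065536 mm², hence 457.76 cells/mm².

```r
tab <- generate_ratings(6, 2, sigma_between = 10, sigma_within = 3,
                        mean = 50, seed = 2)   # 6 specimens, 2 repeats
icc_two_way(tab)
#> ICC = 0.9665 (p = 7.182e-05)
#>   two-way random effects, absolute agreement, single measures (ICC(2,1))
#>   n = 6 specimens, k = 2 raters
bland_altman(unclass(tab))
#> Bland-Altman: bias 2.167, 95% limits [-3.007, 7.34] (n = 6)
cv_percent(5, 15)
#> [1] 70.71068
wilcoxon_signed_rank(unclass(tab))
#> Wilcoxon signed rank: V = 18.5, p = 0.125 (exact, n = 6)
```

The ICC of 0.97 reflects the simulated world (between-specimen SD 10 vs
within SD 3, population ICC ≈ 0.92); the positive Bland–Altman bias of
2.17 counts says rater 1 reads slightly higher on these six specimens,
with 95% of differences expected in [−3.0, 7.3].

## Command line

```sh
WRAP=$(Rscript -e 'cat(system.file("exec", "ihcquant", package = "ihcquant"))')
Rscript "$WRAP" simulate --out-dir scene --seed 3
Rscript "$WRAP" quantify --image scene/image.tiff --microns-per-pixel 0.5 \
    --exclusion-mask scene/appendage_mask.png \
    --area-min 8 --area-max 300 --seed 11 --out results.csv
Rscript "$WRAP" validate --ratings ratings.csv --stat icc --out report.json
```

`quantify` writes a results CSV (`specimen,region,n_cells,
sampled_area_mm2,density_per_mm2,area_min_um2,area_max_um2,threshold,
seed`) and a JSON log echoing every parameter; reruns with identical
inputs are byte-identical. The ratings CSV is long-form
`specimen,rater,count`.

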