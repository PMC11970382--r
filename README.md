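# spotniche

Spatial niche quantification for spot-based transcriptomics and multiplex
imaging, in R.

Tumor stromal niches — neighborhoods where endothelial and fibroblast
subsets (e.g. SELP⁺ high endothelial venules, APOD⁺ myCAFs) co-occur with
immune cells — are read out from two modalities: Visium-style spots with
deconvolved per-spot cell-type abundances, and mIHC point patterns of
phenotype-labelled cells. `spotniche` is for analysts who have those
intermediate products (a positions table, an abundance matrix, a count
matrix, a coordinate CSV, a cohort table) and need the niche statistics on
top of them:

* **Co-localization** (`coloc_test()`): for each cell type, member spots
  are those whose abundance strictly exceeds its mean; members are binned
  into a shared 30 × 30 density histogram, and every ordered pair is scored
  with the Kullback–Leibler divergence
  `D(P‖Q) = Σᵢ p'ᵢ log(p'ᵢ/q'ᵢ)` (pseudo-count ε = 1e-10, renormalized;
  `NaN` for pairs with an empty histogram). Significance comes from a
  permutation null — 1000 rounds of jointly shuffling coordinate tuples
  over random 80% spot subsets — with plus-one-corrected empirical
  p-values in both orientations (dissimilarity and co-localization tails).
* **ROI scoring** (`define_roi()`, `signature_score()`,
  `lr_coexpression()`, `compare_in_out()`): above-average ROIs,
  control-gene-matched signature scores (25 expression bins, 50 controls
  per gene), ligand–receptor co-expression as the per-spot mean of the
  pair, and Wilcoxon rank-sum in/out contrasts (exact for small untied
  samples).
* **Proximity** (`nearest_distance()`, `radial_counts()`,
  `compare_distances()`): nearest cell-to-niche-object distances, radial
  count/density profiles over 0–300 µm annuli, Welch t contrasts.
* **Cohort dynamics** (`composition_fractions()`, `paired_change_test()`,
  `group_fraction_test()`, `response_rates()`, `star_annotation()`):
  paired pre/post composition tests per cell type and clinical
  response-rate summaries.
* **Synthetic data** (`simulate_spatial_map()`, `simulate_point_pattern()`,
  `simulate_cohort()`): seeded generators for every input above, with
  controllable niche co-localization, ligand–receptor elevation inside
  niches, distance shifts, and paired composition effects.

The methods vignette (`vignettes/spatial-niche-methods.Rmd`) documents the
models, defaults, and design choices, including why the permutation
reference statistic is computed on a size-matched subsample.

## Worked example

Simulate a slide with one mosaic stromal niche shared by two types, test
co-localization, score a ligand–receptor pair in the ROI, and compare
pre/post point patterns:

```r
library(spotniche)

niche <- niche_spec(center = c(0.3, 0.3), spread = 0.15,
                    member_types = c("SELP_HEV", "APOD_myCAF"),
                    lr_pairs = list(c("ICAM1", "ITGAL")),
                    elevation = 4, strength = 5, allocation = "mosaic")
sim <- simulate_spatial_map(
  n_spots = 2500,
  cell_types = c("SELP_HEV", "APOD_myCAF", "STMN1_cEC", "T_NK", "malignant"),
  niches = list(niche), baseline_conc = 20, seed = 7
)

res <- coloc_test(sim$spots, sim$abundance,
                  run_config(n_perm = 200, seed = 7,
                             tail = "co_localization"))
print(res)
#> Co-localization test: 5 cell types, 2500 spots, 200 permutations
#>   tail = co_localization, observed scope = subsample_matched
#>   KL matrix: 0 NaN pair(s) above diagonal

summary(res)   # selected rows
#>      type_a    type_b kl_ab p_as_written p_co_localization
#>   malignant STMN1_cEC 0.708            1           0.00498
#>  APOD_myCAF  SELP_HEV 6.243            1           0.00498
```

The niche pair `SELP_HEV`/`APOD_myCAF` is significantly co-localized
(`p_co_localization = 1/201`, the smallest value 200 permutations allow):
its KL divergence (6.24 — its member spots interleave rather than
coincide) sits far below the shuffled null. Background pairs such as
`malignant`/`STMN1_cEC` are also flagged, for a real reason: types not in
the niche are jointly depleted there, so they share the complement of the
niche. Note the `as_written` orientation reads the same evidence as
p ≈ 1, since it counts permutations that are *more dissimilar* than
observed.

```r
expr <- normalize_expression(sim$counts)
roi  <- define_roi(sim$abundance[, "SELP_HEV"], sim$spots$spot_id)
print(roi)
#> ROI mask: 663 of 2500 spots above mean abundance (threshold 0.2776)

lr  <- lr_coexpression(expr, "ICAM1", "ITGAL")
cio <- compare_in_out(as.numeric(lr), roi)
#> ICAM1:ITGAL in/out ROI: median 5.452 vs 5.097, W = 968048, p = 1.76e-112
```

The ligand–receptor score is higher inside the HEV ROI, as simulated
(`elevation = 4` inside the niche kernel).

```r
pre  <- simulate_point_pattern(5, 500, 180, seed = 1)   # pre-treatment
post <- simulate_point_pattern(5, 500, 120, seed = 2)   # post-treatment
d_pre  <- nearest_distance(pre[!pre$is_niche, ],  pre[pre$is_niche, ])
d_post <- nearest_distance(post[!post$is_niche, ], post[post$is_niche, ])
compare_distances(d_pre, d_post)
#> mean distance pre 174.2 um vs post 123.0 um, Welch t = 10.45, p = 3.2e-24 ***
```

Cells generated at a 120 µm target distance are recovered ~50 µm closer to
the niche objects than the 180 µm pattern, with the significance stars the
cohort module prints (`***` = p < 0.001). Paired cohort dynamics:

```r
spec <- cohort_spec(n_per_arm = c(Im = 34, ImC = 34),
                    effects = data.frame(cell_type = "fibroblast",
                                         arm = "ImC", shift = 0.06),
                    noise_sd = 0.02)
cohort <- simulate_cohort(spec, seed = 11)
head(composition_change_table(cohort, arm = "ImC"), 4)
#>     cell_type n_pairs mean_change statistic  p_value stars
#> 1   malignant      34    -0.00798     -3.44 1.60e-03    **
#> 2 endothelial      34    -0.00567     -1.97 5.73e-02    ns
#> 3  fibroblast      34     0.05148     19.73 7.69e-20   ***
#> 4        T_NK      34    -0.00749     -2.33 2.63e-02     *

response_rates(c(Im = 3, ImC = 16), 34)
#>   Im  ImC
#>  8.8 47.0
```

The simulated +0.06 fibroblast shift is recovered (mean change 0.051 after
renormalization against the other types, which absorb small negative
changes), and response counts of 3/34 and 16/34 print as 8.8% and 47.0%.

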