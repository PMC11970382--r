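---
title: "Quantifying spatial niches: models, parameters, and design choices"
author: "spotniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial niches: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotniche)
```

# Scope

Tumor stromal niches — local neighborhoods where particular endothelial and
fibroblast subsets co-occur with immune cells — are studied with two
complementary data modalities: spot-based spatial transcriptomics, where a
deconvolution method (e.g. cell2location) assigns each ~55 µm spot a vector
of cell-type abundances, and multiplex immunohistochemistry (mIHC), which
yields micrometre-resolution coordinates of phenotype-gated single cells.
`spotniche` implements the statistics used to quantify niches on both:

1. a Kullback–Leibler (KL) divergence test of pairwise cell-type
   co-localization on binned spatial density maps, with a permutation null;
2. region-of-interest (ROI) scoring of gene signatures and ligand–receptor
   co-expression inside versus outside a cell subset's territory;
3. nearest-distance and radial count profiling of cell-to-niche-object
   point patterns;
4. paired pre/post cell-type composition dynamics for a two-arm cohort,
   with clinical response-rate summaries.

A seeded synthetic-data module generates all the inputs these analyses
consume, so the full pipeline is testable without sequencing or imaging
data.

# The co-localization test

## Density histograms and KL divergence

For each cell type $k$ the *member spots* are, by default, the spots whose
deconvolved abundance strictly exceeds the mean abundance of that type over
all analyzed spots — the same above-average rule used for ROIs and for the
reported per-type spot proportions. Member spots are binned on a shared
$B \times B$ grid ($B = 30$ by default) over the bounding box of all
analyzed spots, and the histogram is normalized to total mass 1. Using one
shared grid keeps histograms comparable across type pairs. Bins are
half-open with a right-inclusive top edge, so boundary spots are never
dropped. An abundance-weighted histogram
(`membership_mode = "weighted"`) and a pair of concatenated 1-D per-axis
histograms (`hist_kind = "per_axis"`) are available as variants; the 2-D
grid is the default because spot density is two-dimensional.

For an ordered pair $(P, Q)$ of non-empty histograms the divergence is

$$D(P \,\|\, Q) = \sum_i p'_i \log \frac{p'_i}{q'_i}, \qquad
p' = \frac{p + \varepsilon}{\sum_j (p_j + \varepsilon)},$$

in nats, with a pseudo-count $\varepsilon = 10^{-10}$ added to every bin
before renormalization. The pseudo-count exists because $D$ is undefined
when some $q_i = 0 < p_i$; for histograms whose occupied bins are bounded
away from $\varepsilon$ the value is insensitive to $\varepsilon$ (the test
suite verifies shifts below $10^{-6}$ between $\varepsilon = 10^{-10}$ and
$10^{-12}$), while for sparse histograms the non-overlap mass is priced at
$\log(1/\varepsilon)$, which is exactly how empty-versus-occupied bins
should dominate the comparison. If either histogram of a pair is empty (a
type with no above-average spot), the pair is skipped and `NaN` is
recorded in the KL matrix and in the p-value matrices; the diagonal is
exactly 0 where defined. KL is directed, and the full asymmetric matrix is
reported; a Jensen–Shannon summary (`js_divergence()`) is available when a
symmetric number is wanted.

## Permutation null and p-values

The null distribution is built by repeating, `n_perm = 1000` times
(200 in the validation suite): draw $\lfloor 0.8 n \rfloor$ spots without
replacement, permute the $(x, y)$ coordinate tuples jointly among the
sampled spots while each spot keeps its abundance row, recompute
memberships, histograms (bounding box from the sampled spots), and the
full KL matrix. Joint permutation of coordinate tuples preserves the spot
lattice and severs only the link between expression profile and location.
Each permutation runs on its own RNG substream derived from the master
seed, so the entire result object is a pure function of (inputs, config).

Empirical p-values are plus-one corrected. Two orientations are computed
and stored:

* `as_written`: $p = (\#\{\mathrm{null} > \mathrm{obs}\} + 1)/(M + 1)$ —
  the fraction of permutations exceeding the observed divergence. Under
  this orientation a strongly co-localized pair (small KL) has $p$ near 1;
  it flags pairs whose spatial distributions are *more dissimilar* than
  chance.
* `co_localization`: $p = (\#\{\mathrm{null} < \mathrm{obs}\} + 1)/(M+1)$,
  so small KL is significant. This is the orientation under which
  "co-localized" reads as "significant".

`run_config(tail = ...)` selects which orientation populates the main
`pvals` matrix; both are always present in the result, and `summary()`
reports both, because the choice is a reporting convention rather than a
statistical one.

## Why the observed reference is size-matched

A subtle calibration issue arises when the null is computed on 80% subsets
but the observed statistic on all spots: the KL of two sampled histograms
has a sample-size-dependent noise floor (fewer spots means sparser
histograms and stochastically larger divergence), so the null is shifted
upward relative to the full-data statistic *even when there is no spatial
structure at all*. In simulations with structureless maps this literal
comparison produces p-values piled near 1 (as-written orientation) at
every map size we examined — a bias, not a subtlety of the data. The
default (`observed_scope = "subsample_matched"`) therefore computes the
reference statistic for the p-value comparison on one seeded, *unshuffled*
subsample of the same size as the null subsamples; with matched sizes the
p-values on structureless maps are approximately uniform (checked in the
test suite with a Kolmogorov–Smirnov bound of $D < 0.2$ over 50
exchangeable pairs). The reported KL matrix itself is still computed on
all analyzed spots, and `observed_scope = "all_spots"` reproduces the
literal comparison for anyone who wants it.

## What the test can and cannot detect

KL between binned densities only sees *bin co-occupancy*. Because the
permutation keeps each spot's abundance row intact, two types that are
high *in the same spots* have overlapping member sets whose shared spots
land in the same bins under both the observed and the shuffled maps — that
component of similarity is preserved by the null and contributes no
evidence. Detectable co-localization is therefore carried by *distinct*
member spots that co-occupy bins, which requires maps dense enough that a
bin holds several spots. This is the situation in real slides (thousands
of spots against a 30 × 30 grid) and it shapes the synthetic power
scenario below.

# ROI analysis

ROIs are spots whose abundance for the focal subset strictly exceeds its
mean — strict inequality, so a constant abundance column yields an empty
ROI (with a warning) rather than an all-spot ROI. The companion summary
`proportion_above_average()` is the ROI size divided by the number of
spots; the two rules are consistent by construction and cross-checked in
the tests.

Expression is depth-normalized per spot to the median library size and
`log(1 + x)`-transformed before scoring; the normalization record travels
with every score vector so outputs are auditable. Signature scores follow
the control-gene-matched scheme: genes are ranked by mean normalized
expression into 25 equal-size bins, each signature gene draws 50 control
genes from its own bin (signature genes excluded; with replacement when
the bin is small), and the score is the mean over signature genes minus
the mean over the pooled control multiset, per spot. The control draw is
seed-pinned. Ligand–receptor co-expression is the arithmetic mean of the
two genes' normalized expression per spot. In-versus-out-of-ROI contrasts
use the two-sided Wilcoxon rank-sum test, with exact enumeration whenever
the smaller group has at most 8 untied observations and the tie- and
continuity-corrected normal approximation otherwise; the same routine
serves the cohort module.

# Point-pattern proximity

Distances are Euclidean and centroid-to-centroid, from each target cell to
its nearest niche object. Radial profiles assign each target to the
half-open annulus $[lo, hi)$ of its nearest-object distance over the
default edges 0–300 µm in 30 µm steps (covering the 120–180 µm interaction
range of interest and fully configurable); targets at or beyond the last
edge fall in an overflow bucket so counts always sum to the number of
targets. Annulus densities divide by the annulus area summed over objects
without overlap correction, which overestimates area where annuli of
different objects intersect — acceptable for sparse objects, and the
counts themselves are unaffected. Group comparisons use Welch's two-sided
unpaired $t$-test by default (pooled-variance Student's test behind a
flag). Because "average distance" can be pooled over cells or averaged per
image first, `mean_distance()` reports both aggregations.

# Cohort dynamics

Per-sample fractions partition each sample's cells over a fixed type
universe (absent types count 0). Paired pre/post changes use Student's
paired $t$ on per-patient differences — algebraically the one-sample $t$
of the differences against zero, an identity the tests exercise.
Zero-variance differences report `p = NaN` with a warning instead of
erroring, so degenerate inputs surface visibly. Unpaired group contrasts
reuse the Wilcoxon routine above; the signed-rank variant is exposed for
paired designs since figure conventions vary. Clinical response
percentages are reported truncated (rounded down) to one decimal, the
convention that reproduces printed two-arm trial rates such as 3/34 =
8.8% and 16/34 = 47.0% from their counts. Significance stars use strict
thresholds: `*` < 0.05, `**` < 0.01, `***` < 0.001, `ns` otherwise, `NE`
for undefined p.

# The synthetic-data generators

The generators are first-class, seeded, pure functions of their parameters
used throughout the validation suite.

**Spatial maps.** Spots sit on a jittered hexagonal-like grid spanning the
unit square. Abundances are a symmetric Dirichlet background (default
concentration 1) plus, for each niche, a Gaussian kernel bump
$s \cdot e^{-d^2 / 2\sigma^2}$ added to its member types and renormalized
per spot, so with no niches the map is exactly structureless. A niche's
bump can be `"shared"` (every member type bumped at every spot — member
types co-occur within spots) or `"mosaic"` (each spot's bump assigned to
one member type drawn uniformly — member types interleave spot by spot
while sharing the region, the pattern of a mixed stromal niche where each
spot is dominated by a vessel or a fibroblast bundle). Counts are Poisson
draws around per-spot gene means built from per-type marker signatures
weighted by the abundances, with lognormal library sizes
(meanlog $\log 5000$, sdlog 0.3 — a typical Visium depth distribution),
and ligand–receptor genes multiplied by
$1 + (\mathrm{elevation} - 1)e^{-d^2/2\sigma^2}$ inside the niche.

The validation suite uses three map regimes, chosen once as the package's
study conditions: structureless 400-spot maps with 10 types for null
calibration; 200-spot maps with a shared-bump niche pair versus two
disjoint niches for the small-map KL ordering; and dense 2500-spot maps
(background concentration 20, i.e. a low-variance background in which
membership is niche-driven rather than noise-driven; bump strength 5,
spread 0.15, mosaic allocation) for permutation-test power. The dense
mosaic regime is the strong-co-localization scenario: as explained above,
the joint-shuffle null discounts same-spot co-occurrence, so a pair is
detectably co-localized only when its member spots interleave densely
enough to share bins.

**Point patterns.** Niche objects are uniform on a 5000 × 5000 µm field
(sparse objects on a whole-slide region — the default of 5 objects keeps a
cell's nearest object almost always the one it was placed around); each
cell picks an object at random and sits at a gamma-distributed distance
(shape 4, i.e. CV 0.5 — a strictly positive, unimodal kernel) at a uniform
bearing, clipped to the field. The pre-clipping generating distances are
attached to the output for validation. Denser object geometries make the
recovered nearest-distance mean undershoot the generating target, because
a cell placed 180 µm from one object is increasingly likely to have a
different object even closer; with the default geometry the bias is within
the suite's 10% recovery tolerance.

**Cohorts.** Two arms of 34 patients (mono-immunotherapy `Im` and
immunochemotherapy `ImC`) with responder rates 0.147 and 0.764 — the
arms' printed major-response rates — baseline fractions from a symmetric
Dirichlet (concentration 8, modest between-patient variability over the 8
major cell types), and post fractions equal to baseline plus
stratum-specific shifts plus Gaussian noise, clipped at zero and
renormalized; with zero shift and zero noise the post row equals baseline
exactly.

**What the generators do not emulate:** transcriptome-wide gene–gene
correlation, spatial autocorrelation of the background (each spot's
background is independent), segmentation or phenotyping errors in point
patterns, histology, and dropout beyond Poisson sampling. Passing tests
therefore certify the statistical machinery under a known generative
model, not robustness to every artifact of real slides.

# Numerical choices and degenerate inputs

* Strict `>` everywhere "exceeds the average" appears; constant input
  gives an empty set, never a full set.
* Histogram bins half-open with the top edge right-inclusive; a
  single-spot bounding box (zero width or height) is a
  degenerate-geometry error.
* Pseudo-count $10^{-10}$, applied to both histograms and renormalized;
  plus-one correction so no permutation p-value is 0; `NaN` propagates
  from KL to p-values.
* Percentages truncate to one decimal; significance stars use strict
  thresholds.
* CSV reals are serialized with 12 significant digits (UTF-8, LF), so
  write/read round-trips agree to that precision; MatrixMarket I/O goes
  through the `Matrix` package and duplicate triplets collapse by
  summation on load.
* Exact Wilcoxon enumeration is limited to untied samples with the
  smaller group ≤ 8; ties switch to the corrected normal approximation.

# Validation problem sizes

The test suite runs entirely on synthetic data: null calibration on
10 × 400-spot maps at 200 permutations (50 exchangeable pairs pooled
across maps, which also breaks the strong within-map correlation of
p-values that share permutations); power on 20 seeds of the 200-spot and
2500-spot regimes; brute-force KL equivalence on ≤ 50-spot, ≤ 5-bin maps;
exhaustive rank-sum enumeration for all untied inputs with
$n_1 + n_2 \le 10$; distance recovery at targets 120 and 180 µm with 500
cells over 20 seeds; and cohort power at 30 pairs, +0.05 shift, noise sd
0.01 over 100 seeds. `scripts/acceptance.R` recomputes the same headline
quantities from scratch under a caller-supplied master seed.

# Known limitations

* The KL statistic is blind to spatial proximity between *different*
  bins; co-localization at scales finer than the bin width, or between
  types that only co-occur within spots, is not detectable by the
  permutation test (the KL magnitude itself still reflects the latter).
* Histograms on sparse maps are dominated by the $\log(1/\varepsilon)$
  non-overlap price, which makes absolute KL values comparable only
  within a map and bin configuration, not across datasets.
* The subsample-matched reference removes the size bias but inherits the
  sampling variability of one subsample; at the default 1000 permutations
  this is negligible relative to the null spread.
* Radial densities ignore annulus overlap between objects, and distances
  are centroid-to-centroid (no object extent).
* Coordinates are unit-agnostic; nothing converts between pixel and
  micrometre frames. Analyses assume consistent units within one input.
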