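---
title: "Population-based farm survey diagnostics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based farm survey diagnostics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfsdiag)
```

`pfsdiag` implements a population-based farm survey (PFS) workflow for
diagnosing yield-limiting soil nutrients in smallholder maize landscapes. The
idea transfers the logic of population-based disease surveillance to soil
health: instead of a handful of fertiliser trials, a rigorously sampled
population of farm fields is characterised cheaply (infrared spectroscopy in
place of full wet chemistry), deficiency "cases" are defined against critical
soil-test values calibrated on the survey itself, nutrient imbalance is
ranked with DRIS indices, and the spatial pattern of limitation is mapped and
tested for clustering. This vignette records the models behind each step, the
tunable parameters, and the design decisions taken where the methodology was
genuinely open.

## 1. The sampling frame

The survey uses a nested Land Degradation Surveillance Framework (LDSF)
hierarchy: a square 100 km^2 block is divided into 16 tiles (6.25 km^2
each), each tile into 10 sub-tiles; 8 tiles and 32 sub-tiles (4 per selected
tile) are drawn at random, 2 maize fields are sampled per sub-tile (a third
candidate coordinate serves as a fallback), and each field receives a
Y-frame of 4 plots: a central plot placed 20 m from the field boundary and
three satellites at a 12.2 m radius, 120 degrees apart. The defaults
therefore give exactly 64 fields and 256 plots.

Two counts in the source design are mutually inconsistent (a 6.25 km^2 tile
cannot contain ten 0.25 km^2 sub-tiles); we keep 10 sub-tiles per tile and
let the sub-tile area follow as tile area / 10. Both numbers are
configuration, not constants.

All geometry is computed in a local metre-true equirectangular projection
anchored near the block (default anchor 34.25 E, 0.07 N); longitude/latitude
are carried alongside every plot record. At a 10 km scale near the equator
the distortion of this projection is negligible relative to plot geometry.
The boundary bearing of a field (the direction of the farmer's homestead) is
unknowable in simulation, so each field draws a random bearing from the
design seed.

## 2. The synthetic landscape generator

No field data ship with the package; a generator with known ground truth
stands in, so that every downstream stage is testable end to end. It
emulates:

* **Spatially correlated nutrient surfaces.** Each nutrient is a stationary
  random field built from a superposition of 96 seeded cosine waves whose
  wave vectors follow the spectral density of a Gaussian correlation
  function, giving correlation `exp(-(d/range)^2)` with a default range of
  2000 m. The construction is evaluable at arbitrary coordinates in O(waves)
  and needs no covariance factorisation. Soil N is normal with mean 0.15%
  and CV 25%; extractable P (Mehlich-3) and exchangeable K are lognormal
  with means 21 mg kg^-1 (CV 61%) and 4.24 cmol_c kg^-1 (CV 35%). (The
  published summary table swaps the P and K units relative to its text; we
  follow the text.)
* **A saturating yield response** per nutrient: linear below a true critical
  soil value, flat at the plateau above it,
  `plateau * max(0, 1 - curvature * max(0, critical - soil))`, with defaults
  plateau 4.5 Mg ha^-1 and criticals 0.13% N, 18.3 mg kg^-1 P,
  5.3 cmol_c kg^-1 K. Per-nutrient factors combine multiplicatively by
  default — the landscape exhibits multiple co-limitation in the same
  places — with a Liebig-minimum switch available.
* **Tissue-soil uptake links.** Ear-leaf N, P, K follow Michaelis-Menten
  saturation of the soil value (`t_max * s / (s + k_m)`) times
  multiplicative noise; the published record does not state this functional
  link, so the saturating form is a modelling choice, chosen because leaf
  concentration plateaus at luxury supply.
* **Crop response proxies.** A target biovolume is linked linearly to
  expected yield and plant height/basal diameter are back-solved through
  the cylinder formula `BV = H (BD/2)^2 pi`, so the recorded morphometrics
  are exactly consistent with the recorded biovolume.
* **Survey imperfections.** 7% of yields are missing at random (fields
  harvested before measurement) and 11/256 of plots carry a x3 tissue-N
  outlier, mirroring the screening the analysis must survive.

A fixed seed reproduces tables byte for byte. What the generator does *not*
emulate: physically meaningful mid-infrared band assignments, management and
weather covariates, within-plot sampling error structure, or non-stationary
fertility gradients (terraces, homestead effects). Passing tests therefore
demonstrate the *statistical machinery*, not predictive skill on real
spectra.

One landscape realisation covers a single 10 x 10 km block with a 2 km
correlation range, i.e. only a few dozen independent fertility patches.
Landscape-level summaries (mean soil N, baseline prevalence) consequently
vary a lot between seeds — as they would between real survey blocks.

## 3. Spectral calibration

Spectra are simulated on the 4000-600 cm^-1 grid at 2 cm^-1 spacing as a
linear mixture of smooth analyte loading curves plus a low-order polynomial
baseline and white noise (default SD 0.003 absorbance, which puts hold-out
soil-N skill in the 0.75-0.9 R^2 regime typical of mid-infrared soil
calibrations). A 25% reference subset, selected at random by seed, plays the
role of the wet-chemistry calibration set.

Preprocessing is a Savitzky-Golay first derivative, polynomial order 2,
window 3 — the smallest window consistent with a first derivative, which
reduces to the central difference; the smoothing-window reading of the
published "3-point gap" is recorded as such. Edge bands without a full
window are trimmed rather than padded. P and K are calibrated on the
natural-log scale (they are strongly right-skewed); back-transformation is
naive exponentiation by default with Duan's smearing factor available behind
a flag.

The regression is PLS1 (NIPALS). No dedicated PLS package is part of the
package's dependency set, so the algorithm is implemented here and pinned by
the classical identity that full-rank PLS reproduces ordinary least squares,
which the test suite checks against `lm()` on small instances. Model
selection under `ncomp = "auto"` minimises the cross-validated RMSECV with a
parsimony rule (smallest component count within 2% of the minimum). Hold-out
cross-validation defaults to 10 seeded folds; the published account does not
say whether its hold-out was k-fold or a single split, so the fold count is
configurable. Reported statistics are `R2 = 1 - SSE/TSS` on held-out pairs
and `RMSECV = sqrt(mean((yhat_cv - y)^2))`, both on the analysis scale.

## 4. Diagnostics: critical values and cut-offs

**Deficiency classification** is strict: a plot is deficient when its value
is strictly *below* the threshold, so a value exactly at the critical level
counts as sufficient. Baseline thresholds default to 0.2% N,
10 mg kg^-1 P, 3 cmol_c kg^-1 K (established soil criticals) and tissue
criticals to 3.00% N, 0.25% P, 2.00% K.

**Cate-Nelson analysis** partitions the soil-test/yield scatter with an
exhaustive two-way scan over candidate criticals (midpoints of consecutive
sorted unique values on each axis). The selected pair maximises the number
of points in the agreeing quadrants — low-x/low-y (responsive) and
high-x/high-y (non-responsive) — *in excess of the count expected under
independent margins*. The chance correction is essential: the raw count is
degenerate, because a corner split isolating a single extreme point scores
n-1 agreeing points and always wins on noisy data. With the correction, the
scan recovers a known critical value of 0.13% from 200-point linear-plateau
data with 10% noise to within +-15% in well over 90% of replicates (checked
in the test suite). Ties are broken by the raw agreeing count, then by the
binary-split R^2 of yield on the x-split, then by the smaller critical_x and
critical_y; the whole procedure, including tie-breaks, is declared canonical
and pinned to an independent brute-force oracle for all n <= 50. Degenerate
inputs (constant x or y, fewer than 8 complete pairs) raise errors rather
than returning arbitrary splits.

**Localized cut-offs** come from the overlap of the frequency distributions
of the deficient and sufficient subpopulations: a normal density is fitted
to each group (on the log scale for P and K, reported back-transformed) and
the cut-off is the density crossing between the two means — the exact root
of the two-normal equality, not the equal-z-score approximation
`(m1 s2 + m2 s1)/(s1 + s2)` (for N(0.08, 0.02^2) vs N(0.15, 0.03^2) the
true crossing is 0.1114 while the approximation gives 0.108). When variances
are so unequal that no crossing lies between the means, the cut-off falls
back to the midpoint between the upper 90% population bound of the
lower-mean group and the lower bound of the other, and the result records
which branch ran. Swapping the group labels never changes the answer.

**Outlier screening** for the rare very-high tissue-N records flags values
exceeding the leave-one-out mean + 3 SD. The leave-one-out form matters: a
self-inclusive bound can never flag anything in small samples (the largest
attainable within-sample z-score in a sample of n is `(n-1)/sqrt(n)`), while
at n = 256 the two forms agree. Only the high side is screened, once,
without iteration.

## 5. DRIS norms and indices

The population is split into *deficient* and *sufficient* subpopulations at
a grain-yield threshold; the pipeline uses the critical yield from the
soil-N Cate-Nelson analysis, nitrogen being the reference nutrient for the
landscape (an alternative tissue-N-based split can be configured). Norms
are the means of the tissue ratios N/P, N/K, P/K over the sufficient
subpopulation, with CVs in percent; records with a zero or missing ratio
denominator are excluded and counted, and the deficient/sufficient variance
ratio of each ratio is attached with an F-test p-value as the classical
separation check.

The ratio function is
`f = (observed/norm - 1) * k / CV` for observed above the norm and
`-(1 - observed/norm) * k / CV` below — algebraically the same expression,
written to make the branch continuity at `observed = norm` explicit. The
sensitivity constant defaults to k = 1000 (100 is also used in the DRIS
literature and is configurable); the CV is that of the sufficient
subpopulation, in percent.

Index combination uses the standard sign convention that subtracts a
ratio's f wherever the nutrient sits in the denominator:

```
index_N = ( f_NP + f_NK) / 2
index_P = (-f_NP + f_PK) / 2
index_K = (-f_NK - f_PK) / 2
```

so the three indices of every plot sum to zero exactly (a printed variant
with all-positive sums contradicts the sum-to-zero property it is stated to
have; the subtractive convention is the deliberate correction). The most
negative index marks the most limiting nutrient. Ranking reports both the
population-mean ordering and the per-plot most-limiting prevalence, since
the two summaries can legitimately disagree and both appear in practice.

## 6. Spatial analysis

Weights are inverse distance, `W_ij = 1/d_ij^power` with power 1 by default
("the inverse of the distance"), zero diagonal, optional row
standardisation; coincident sites are floored at half the smallest nonzero
distance and counted. Global Moran's I uses the standard cross-product form;
its null expectation is -1/(n-1). Local Moran's I uses the population
variance in the denominator, which makes the mean of the locals equal the
global statistic under row-standardised weights — a property the tests pin.
Significance comes from a Monte Carlo permutation test (599 permutations by
default, minimum attainable p = 1/600), one-sided toward clustering because
that is the hypothesis; a two-sided variant is available. The test holds its
nominal 5% size within [0.02, 0.09] over 200 null replicates in the
acceptance suite.

Interpolation maps use IDW with power 2 (the conventional mapping default,
deliberately different from the weighting power); a cell whose centre
coincides with a data point takes that point's value exactly, and every
interpolated value lies within the data range. Severity binning of mapped
values into severe/moderate/low/optimum classes at breaks 0.5/2/5 is a
presentation choice, exposed as configuration.

The pipeline aggregates plot indices to field level (mean over the four
Y-frame plots) before the spatial step: plots 12-24 m apart are
pseudo-replicates at landscape scale and would dominate inverse-distance
weights.

## 7. Orchestration and reproducibility

`run_pipeline()` executes survey -> diagnose -> rank -> map from a single
`pfs_config()` object. Every published constant (12.2 m radius, thresholds,
599 permutations, 25% reference fraction, 7% missing yield, k = 1000) lives
in the configuration, not in code. All randomness derives from one root
seed, split per stage by fixed offsets; the same configuration reproduces
the report byte for byte. Each filtering step (outlier screening, missing
yield, incomplete tissue records) logs its before/after counts in the
report. Artifacts are plain text: survey and index CSVs, GeoJSON point and
frame layers, ESRI ASCII grid rasters, and a JSON report.

Problem sizes used in the automated checks — a 256-plot landscape, 100
replicate recovery draws at n = 200, 200 null replicates of the 599-
permutation Moran test at 64 sites, 20-site oracle instances — were chosen
to make sampling error small relative to the tested tolerances while
keeping the full suite fast on a single CPU.

## 8. Known limitations

* The tissue-soil uptake link and the multiplicative co-limitation are
  modelling choices; real uptake interacts with moisture, micronutrients
  and management in ways the generator does not represent.
* Cate-Nelson criticals inherit an upward bias under co-limitation: factors
  from the other nutrients act as heteroscedastic noise on the scanned
  relation.
* The localized cut-off assumes near-normal subpopulations on the analysis
  scale; strongly multimodal groups would need a different overlap notion.
* One block is one landscape: between-seed variation of landscape summaries
  is large by design, and nothing here addresses extrapolation beyond the
  surveyed block.
* IDW is a deterministic interpolator; no kriging variance or variogram
  modelling is provided.
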