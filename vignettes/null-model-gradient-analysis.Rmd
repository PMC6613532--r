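---
title: "Null-model analysis of a bounded latitudinal richness gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model analysis of a bounded latitudinal richness gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macronull)
```

macronull asks one question of a one-dimensional species richness
gradient: which of its features survive comparison with models that
contain no ecology at all? The motivating system is the freshwater
mollusk fauna of continental Chile — 84 taxa spread over 18–56°S, a
domain with hard geographic limits (the arid diagonal in the north,
continental fragmentation in the south) — but every function works on
any set of species ranges discretized into contiguous one-degree bands.

This vignette explains the models implemented, the parameters that
matter, the synthetic-data generators used to validate them, and the
numerical and design choices a user should know about.

## The incidence matrix

All analyses run on a binary species × band matrix. Bands are the
half-open intervals $[k, k+1)$ degrees S; a latitude equal to the
southern limit is clamped into the last band, so the default 18–56°S
domain has exactly 38 bands and no degenerate 39th. Two constructions
are available, because survey data rarely say which one a published
matrix used:

* `ranges_to_incidence()` (the default everywhere) marks every band
  that intersects a species' latitudinal extent — ranges are assumed
  cohesive, so each row is a contiguous run of 1s;
* `records_to_incidence()` marks only bands containing point records,
  or, with `fill = TRUE`, first derives each species' extremes and then
  interval-fills, which is provably identical to the range route.

`pack_matrix()` orders rows and columns by decreasing totals with
*stable* tie-breaking. Packing order is deliberately deterministic:
nestedness statistics are computed on the packed matrix, and an
arbitrary tie rule would make them irreproducible across sessions.

## Inventory completeness: Chao2

With bands as incidence samples, `chao2()` estimates total richness
from the uniques $Q_1$ and duplicates $Q_2$:
$\hat S = S_{obs} + Q_1^2 / (2 Q_2)$ when $Q_2 > 0$, switching to the
bias-corrected form
$S_{obs} + \frac{m-1}{m} \frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)}$ when
$Q_2 = 0$ ($m$ = number of bands). The estimate is a floor on how
incomplete the inventory may be, not a prediction of true richness.

## Rapoport's rule as a randomized regression

`rapoport_test()` regresses range extent (response) on range midpoint
(predictor), the midpoint method: a positive slope means ranges widen
poleward. Significance comes from shuffling extents across midpoints.
Defaults that matter:

* two-tailed p-value — the null of interest is "slope = 0" without a
  declared direction; a one-tailed option tests the rule's own
  direction;
* the `+1` correction, $p = (1 + \#\{|b^*| \ge |b|\}) / (1 + B)$, so a
  Monte Carlo p-value is never exactly 0;
* `n_perm = 999` by default; the permutation distribution of a slope on
  ~84 points is cheap, so raising this to 50,000 costs seconds.

The correlation coefficient is reported to three decimals and the test
takes no position on which published summary of it one should match.

## The mid-domain effect null

`simulate_mde()` implements the geometric null: keep the observed range
sizes, strip away everything else, and place each range uniformly at
random between the domain limits. Per-band 2.5% and 97.5% quantiles
over the simulated richness curves form the envelope; observed bands
outside it (`mde_deviations()`) are the candidates for non-geometric
explanation.

Three choices are worth making explicit:

* **Discrete placement.** Sizes are taken as occupied-band counts and
  lower edges are placed uniformly on the integer-feasible positions
  $\{0, \dots, D - b\}$. Observed richness is band-discretized anyway,
  and integer placement admits an exact enumeration oracle
  (`expected_mde()` gives the closed-form expectation, which the test
  suite verifies against exhaustive enumeration). A
  `placement = "continuous"` flag provides the real-valued variant;
  the two agree closely away from the domain edges.
* **Replacement modes.** `"without"` re-places the empirical size
  multiset itself (a randomization — every simulated curve conserves
  total occupancy); `"with"` bootstraps sizes before placement.
* **Closed envelope.** An observed value exactly on a bound counts as
  inside; with discrete counts this is the conservative reading.

Calibration: when data are themselves generated by the null, the 95%
envelope captures the observed value in roughly 95% of band×replicate
cases (the acceptance suite checks 0.95 ± 0.03 over 200 replicates of
84 species at 5,000 simulations each). Quantile discreteness makes the
envelope slightly conservative, so realized coverage sits a little
above 0.95.

## Nestedness: NODF, temperature, discrepancy

Three metrics, one question — are depauperate bands subsets of rich
ones, as a source–sink dynamic would leave behind?

* `nodf()`: for every ordered line pair with *strictly* decreasing
  marginal totals, the percentage overlap of the poorer line; averaged
  over row pairs, column pairs, and all pairs. Equal-fill pairs
  contribute zero, so NODF = 100 only for a strict staircase. Values
  agree exactly with vegan's implementation and with a brute-force
  pair loop.
* `nestedness_temperature()`: a 0–100 "disorder" score. We formalize
  the classic temperature as follows: cells of the packed matrix map to
  the unit square, the perfect-nestedness isocline is the curve
  $x^p + y^p = 1$ with $p$ solved so the enclosed area equals the
  matrix fill, and every unexpected presence/absence contributes its
  squared relative distance from the isocline along the main-diagonal
  line through the cell, normalized by the conventional 0.04145 per
  cell. The legacy calculator's exact parameterization was never
  published to full precision, so numeric parity with historical
  software output is *not* claimed — the scale, the zero point
  (perfectly nested packed matrices score 0) and the direction are.
* `br_discrepancy()`: with columns packed by decreasing totals, the
  count of absences among the leftmost $r_i$ cells of each row — the
  presences that would have to be shifted to achieve maximal packing.

`nestedness_null_test()` compares any of these against Monte Carlo
nulls. The default null is *fixed rows, equiprobable columns*: each
species keeps its occurrence frequency but redraws which bands it
occupies, encoding the assumption that any band could in principle be
occupied. A fixed-fixed option (via the SIM9 chain) and a fully
equiprobable option are provided. P-values are one-tailed in each
metric's nested direction (high NODF, low T, low BR), with the `+1`
correction, and the null 2.5–97.5% percentile interval is reported.

## Co-occurrence: C-score against SIM9

`c_score()` averages the checkerboard units
$CU_{ij} = (r_i - S_{ij})(r_j - S_{ij})$ over species pairs.
`cooccurrence_test()` compares it with the fixed-fixed ensemble sampled
by `sim9_chain()`: pick a random row pair and column pair; if the 2×2
submatrix is a checkerboard, swap its diagonal. The transition kernel
is symmetric, so the stationary distribution is uniform over all
matrices with the observed margins — on enumerable cases the chain mean
matches exhaustive enumeration, and on a 2×2 checkerboard it visits
both states evenly.

Chain defaults (exposed, since no standard exists): 30,000 attempted
swaps of burn-in, one retained state per 10 attempts, 5,000 retained
states. *Attempted* swaps — including rejections — count toward burn-in
and thinning, which makes chain length deterministic. Both tail
probabilities are reported alongside the standardized effect size
$(obs - \bar{null})/sd(null)$: a significantly high C-score indicates
segregation, a significantly low one aggregation, and the package does
not prejudge which tail a user should interpret.

## Band similarity, UPGMA, SIMPROF

`cluster_bands()` chains three classical steps: Jaccard similarity
between band species sets (empty bands are dropped with a message —
similarity of two empty sets is undefined), UPGMA agglomeration on
$1 - J$, and a SIMPROF permutation test applied top-down from the root.
SIMPROF asks whether a group of bands has more internal structure than
expected if each species' presences were arranged at random across
those bands: the statistic is
$\pi = \sum_k |s_{(k)} - \bar s_{(k)}^{null}|$ over the ordered
similarity profile. Descent stops at homogeneous nodes; the retained
partition (`significant_groups()`) is the set of maximal homogeneous
subtrees, with nodes of fewer than three bands treated as homogeneous.
A single permutation budget is split 2:1 between estimating the mean
profile and building the null $\pi$ distribution. Under exchangeable
bands the test's p-values are uniform (checked by simulation), and
`alpha = 0.05` follows common practice.

## Richness regressions: Poisson GLMs ranked by AICc

`fit_poisson()` wraps a log-link Poisson GLM. Predictors are z-score
standardized by default: the eleven per-band covariates span degrees
Celsius to square kilometres, and only on a common scale are
coefficients comparable (a per-metre altitude coefficient of ~1 would
be absurd; a per-SD one is not). `rank_single_predictors()` fits one
model per covariate and sorts by
$AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$; `stepwise_aicc()` runs
bidirectional selection to a local AICc minimum with ties broken by
predictor name, so results do not depend on column order. Both
McFadden's and Nagelkerke's pseudo-$R^2$ are always reported, because
"pseudo-$R^2$" without a formula is ambiguous; the two can differ by a
factor of two or more on the same fit.

A caution the test suite encodes rather than hides: AICc selection is
not consistent. With one strong planted predictor among independent
noise covariates at $n = 38$, the planted variable is essentially
always retained, but a spurious companion clears the $2k$ penalty in a
sizeable minority of replicates. Exact-support recovery should not be
expected of this (or any) information-criterion stepwise.

## The synthetic-data generators

Every statistic above is validated by parameter recovery on data whose
structure is known by construction:

* `gen_ranges()` draws range sizes from a lognormal truncated to
  [1 band, domain width] (defaults `meanlog = 0`, `sdlog = 1`, keeping
  over half of the ranges under 2°, the right-skew typical of this
  fauna) and places midpoints uniformly on their feasible interval —
  the MDE null's own placement rule reused as a generator.
* `gen_nested()` interpolates between a deterministic staircase
  (`rho = 1`; for a square matrix at triangular density this is the
  exact $R..1$ staircase scoring NODF = 100) and uniform noise at
  matched density (`rho = 0`) by relocating presences.
* `gen_cooccurrence()` plants aggregation or segregation by
  *margin-preserving directional checkerboard swaps* from a random
  start: greedy SIM9 moves that monotonically lower (aggregated) or
  raise (segregated) the C-score. This construction was chosen over the
  seemingly natural alternative — duplicating site profiles across
  species groups — because duplication also lumps the column margins,
  and the fixed-fixed null conditioned on those lumpy margins has a
  *lower* mean C-score than the observed matrix: the planted
  "aggregation" shows up in the wrong tail. Directional swaps leave the
  margins of the random start untouched, so the planted matrix sits in
  the intended tail of its own null ensemble by construction.
* `gen_glm_bands()` draws per-band counts from
  $\text{Poisson}(\exp(\beta_0 + X\beta))$; `gen_covariates()` supplies
  a latitude-trended synthetic covariate table with the eleven standard
  predictor columns.

All generators are pure functions of their arguments and a seed; a
master seed is split into per-stage substreams
(`macronull:::substream_seeds()`) so pipeline stages are individually
reproducible.

What the generators deliberately do *not* emulate: spatial
autocorrelation of covariates beyond a smooth latitude trend, range
fragmentation (all synthetic ranges are cohesive), detection error in
records, and phylogenetic structure among species. Passing tests
therefore demonstrate correctness of the statistics and calibration of
the tests under their own assumptions — not that those assumptions hold
for any particular empirical fauna.

## Numerical choices and degenerate inputs

* Monte Carlo p-values all use the `+1` correction and report the
  iteration count.
* Calibration experiments (envelope coverage, p-value uniformity,
  coefficient coverage) redraw *both* design and response per
  replicate, so estimates are marginal over data sets rather than
  conditional on one unlucky realization.
* Degenerate inputs fail loudly: empty matrices (Chao2), zero-variance
  midpoints (Rapoport), all-ones/all-zero matrices (temperature),
  single-species matrices (C-score). A matrix with no swappable
  checkerboard makes the SIM9 ensemble collapse to the observed matrix,
  with a warning rather than an error.
* Default iteration counts are desk-scale (hundreds to a few thousand;
  the test suite uses 150–5,000 and the acceptance script 2,000–50,000
  per stage, chosen so each stage's Monte Carlo error is small relative
  to the effects probed). All counts are arguments, so published-scale
  runs (50,000 everywhere) are one argument away.

## Running everything at once

`run_pipeline()` drives all stages from one declarative config (an R
list or YAML file), writes per-stage CSVs, a consolidated
`summary.json` and a log with versions, seeds and iteration counts, and
aborts naming the stage on any failure. Identical configs reproduce
identical summaries.

```{r pipeline, eval = FALSE}
cfg <- list(
  ranges = system.file("extdata", "demo_ranges_synthetic.csv",
                       package = "macronull"),
  covariates = system.file("extdata", "demo_covariates_synthetic.csv",
                           package = "macronull"),
  seed = 1, out_dir = "mollusk-run",
  n_sim = 5000, n_iter = 2000, n_perm = 999
)
results <- run_pipeline(cfg)
```

## Known limitations

* The domain is strictly one-dimensional; two-dimensional range
  geometry and soft boundaries are out of scope.
* Temperature values are comparable within this package but not
  digit-for-digit with legacy calculators (see above).
* The regression stage ignores spatial autocorrelation of residuals;
  n = 38 bands is treated as 38 independent observations, which
  overstates precision when richness is spatially smooth.
* SIMPROF's split permutation budget makes its p-value itself a Monte
  Carlo quantity; near-threshold decisions at small budgets can flip
  between seeds.
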