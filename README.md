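# macronull

Null-model macroecology of bounded latitudinal richness gradients.

`macronull` is an R package for asking which features of a
one-dimensional species richness gradient survive comparison with
models containing no ecology: random range placement between hard
geographic limits, marginal-preserving matrix randomizations, and
permutation nulls. It was built around the freshwater mollusk fauna of
continental Chile — 84 taxa distributed over 18–56°S, binned into 38
one-degree latitudinal bands — but applies to any assemblage whose
ranges can be discretized along one axis.

## What it computes

Everything runs on a binary species × band incidence matrix (built from
a range table or from point records):

| Stage | Function | Model / statistic |
|---|---|---|
| Inventory completeness | `chao2()` | Chao2: S_obs + Q1²/(2Q2), bias-corrected when Q2 = 0 |
| Rapoport's rule | `rapoport_test()` | extent ~ midpoint OLS slope vs extent-shuffling permutation null |
| Geometric limits | `simulate_mde()` | mid-domain effect: observed sizes re-placed uniformly in the domain, 95% richness envelopes (randomization and bootstrap modes) |
| Nestedness | `nodf()`, `nestedness_temperature()`, `br_discrepancy()`, `nestedness_null_test()` | NODF (0–100, high = nested), matrix temperature T (0–100, low = nested), BR discrepancy; fixed-row/equiprobable-column Monte Carlo null |
| Co-occurrence | `c_score()`, `sim9_chain()`, `cooccurrence_test()` | C-score = mean (r_i − S)(r_j − S) over species pairs vs the SIM9 fixed-fixed sequential-swap ensemble, with SES and both tails |
| Biogeographic zones | `cluster_bands()`, `significant_groups()` | Jaccard similarity, UPGMA dendrogram, recursive SIMPROF pruning |
| Environmental models | `fit_poisson()`, `rank_single_predictors()`, `stepwise_aicc()` | log-link Poisson GLMs of per-band richness, ranked by AICc; McFadden and Nagelkerke pseudo-R² |
| Everything | `run_pipeline()` | one config, per-stage CSVs, JSON summary, seeded log |

A synthetic-data module (`gen_ranges()`, `gen_nested()`,
`gen_cooccurrence()`, `gen_glm_bands()`, `gen_covariates()`) generates
inputs with known structure — right-skewed range sizes, tunable
nestedness, planted aggregation/segregation, known Poisson coefficients
— so every statistic is validated by parameter recovery. Results are
tidyverse-friendly: `tidy()`, `glance()` and `autoplot()` methods exist
for each result type.

## Worked example

Using the bundled synthetic demonstration data (84 species, 18–56°S;
generated by `gen_ranges()`, so the truth is "random placement"):

```r
library(macronull)

ranges <- read_ranges(system.file("extdata", "demo_ranges_synthetic.csv",
                                  package = "macronull"))
m <- ranges_to_incidence(ranges, band_domain(18, 56))
m
#> <incidence> 84 species x 38 bands, fill 0.095

chao2(m)
#> # A tibble: 1 × 5
#>   s_obs    q1    q2     m s_est
#> 1    84     0    25    38    84

rapoport_test(ranges, n_perm = 9999, seed = 1)
#> Rapoport randomized regression (extent ~ midpoint)
#>   slope = 0.0520, r = 0.272, p = 0.0114 (two-tailed, 9999 permutations)

simulate_mde(ranges, mode = "without", n_sim = 5000, seed = 2)
#> Mid-domain null envelope (without replacement, 5000 simulations)
#>   38 bands, coverage 94.7%; 2 band(s) outside the envelope
#>   deviating bands: 41 (above), 42 (above)

nestedness_null_test(m, "NODF_total", n_iter = 2000, seed = 3)
#> Nestedness test: NODF_total = 10.43 (null fixed-equiprobable, 2000 iterations)
#>   null mean 10.29, 95% CI (9.715-10.94), one-tailed p = 0.3173

cooccurrence_test(m, n_iter = 2000, burn_in = 30000, thin = 10, seed = 4)
#> C-score vs SIM9 fixed-fixed null
#>   observed 10.5410, null mean 10.1454 (var 0.000292), SES 23.17
#>   p(null >= obs) = 0.0004998 [segregation], p(null <= obs) = 1 [aggregation]
```

Reading these: the inventory looks complete (no uniques, so Chao2 adds
nothing); the extent–midpoint slope is small but nominally significant
at this permutation budget; ~95% of bands sit inside the mid-domain
envelope, as expected for ranges that really were placed at random,
with a mild excess at 41–42°S; nestedness is indistinguishable from the
fixed-row null (p = 0.32). The C-score SES of 23 on "random" data is a
deliberate lesson rather than a bug: interval-filled ranges are
*contiguous*, and contiguity alone makes species pairs checkerboard far
more than the SIM9 ensemble (which scrambles ranges into fragments)
allows. Co-occurrence tests on range-fill matrices test contiguity
first and biology second.

## Layout

* `R/` — implementation (one file per analysis stage)
* `tests/testthat/` — unit, property and calibration tests, including
  brute-force enumeration oracles for every matrix statistic
* `vignettes/null-model-gradient-analysis.Rmd` — models, assumptions,
  parameter choices, generator design, limitations
* `inst/extdata/` — small synthetic demonstration CSVs
* `scripts/acceptance.R` — end-to-end reproduction script
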