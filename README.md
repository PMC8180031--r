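# skintrace

People leave traces of their skin microbiome on everything they touch.
`skintrace` is an R package for asking whether those traces identify a
person, how fast they decay, and how they move between surfaces. It is
aimed at microbiome researchers working with twice-daily time series of
MetaPhlAn-style relative-abundance profiles from skin, household and
public surface sites, and it ships a synthetic community generator with
planted ground truth so every estimator can be calibration- and
recovery-tested without sequencing data.

Three analyses are implemented end to end:

1. **Forensic matching.** A surface *query* is matched to the person with
   the smallest mean distance between the query and that person's palm
   samples in a per-timepoint *reference pool*, using the Canberra
   distance in the `vegdist()` dialect,
   `d = (1/NZ) Σ |x−y|/(x+y)` over non-double-zero taxa, or Bray-Curtis
   `Σ|x−y| / Σ(x+y)`. Accuracy is tabulated over sampling delay
   (−228 h … +228 h in 12 h steps), its decay is measured by Spearman's ρ
   against |delay|, and time-of-day effects are tested with Pearson
   chi-squared on AM/PM strata. PERMANOVA, indicator-family source
   profiling and same- vs different-location dissimilarity tests cover
   the community level.
2. **Diurnal species detection.** Each (species, site, location) series
   is decomposed into trend, seasonal and random components by moving
   averages with a 1-day (AM/PM) period; seasonality strength
   `F_S = max(0, 1 − Var(R)/Var(S+R))` is tested against 999 random
   permutations of the series (`p` = proportion of permutations with
   larger `F_S`). Robustness re-analyses cover negative-control species
   removal and the compositional artefact in which one genuinely diurnal
   species induces apparent antiphase rhythms in others.
3. **Dispersal networks.** Per (location, family), a 6-node lag-1
   dynamic Bayesian network over the sites is learned by greedy hill
   climbing under a BDeu score (5 equal-width abundance bins, ≤5 parents
   per node); edges are read as dispersal routes and summarised by site
   class with Kruskal-Wallis tests.

## Worked example

Generate a synthetic study (4 persons × 6 sites × 20 timepoints) with
daily public-pool turnover, then match all public-surface queries
against the skin reference pools:

```r
library(skintrace)

sim <- generate_synthetic(synthetic_config(public_turnover = 0.3,
                                           seed = 21))
mt  <- evaluate_matching(sim$table, sim$metadata, metric = "canberra",
                         query_sites = c("public_handrail",
                                         "subway_handrail"))
round(100 * mean(mt$results$correct), 1)
#> [1] 41.1
spearman_delay_accuracy(mt$curve, "public_handrail")[c("rho", "p")]
#> $rho
#> [1] -0.719892
#>
#> $p
#> [1] 2.399419e-07
```

Public queries are matched well above the 25% chance level overall, and
accuracy decays strongly with the absolute delay between query and
reference collection (ρ ≈ −0.72): the public pool turns over daily, so
stale references lose their match. Household queries under the same
settings match at ~100% with no delay decay — household surfaces hold
their occupant's signature across the whole 10-day window.

Detecting a planted diurnal species and checking its day/night peak:

```r
tr  <- sim$truth$diurnal_species[1, ]
ser <- prepare_series(sim$table, sim$metadata, tr$species, tr$site,
                      tr$location)
permutation_test(ser, n_permutations = 999, seed = 1)[c("f_s", "p")]
#> $f_s
#> [1] 0.8295362
#>
#> $p
#> [1] 0.001001001
```

`F_S` ≈ 0.83 says most of the series' variance is 1-day seasonal; only
one of 999 permutations exceeds it, so `p = 1/999`, far below the 0.05
detection threshold.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full study on synthetic data, writing TSV tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # data set + planted ground truth
Rscript analysis/02_matching.R    # accuracy curves, delay decay, time of day
Rscript analysis/03_diurnal.R     # PERMANOVA, diurnal catalog, robustness
Rscript analysis/04_dbn.R         # dispersal networks and edge roles
```

`run_all()` performs the same pipeline in one call from a single
(optionally YAML) configuration and writes a manifest whose content hash
is identical across reruns with the same seed.

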