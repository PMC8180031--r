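---
title: "Methods: matching, diurnal decomposition and dispersal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matching, diurnal decomposition and dispersal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skintrace)
```

skintrace implements three linked analyses of skin and surface microbiome
time series sampled on a fixed spatiotemporal grid — 4 residences (one
occupant each), 6 sites per residence (left/right palm, bed headboard,
door knob, and two nearby public handrails), 10 days, morning and evening
— plus a synthetic community generator that emulates that design with
known planted structure. This vignette records the models, the parameters
that matter, the numerical choices, and what the synthetic experiments do
and do not demonstrate.

## Forensic microbiota matching

A surface sample (the *query*) is matched against a *reference pool*: the
set of all palm samples from all persons at one timepoint. Pools missing
any person are excluded. For each person we average the distance between
the query and that person's palm samples; the predicted person is the
argmin, and a match is *correct* when that person lives at the query's
location. Ties (exact to 1e-12) go to the lowest person id, with a
warning, so results are deterministic. A `nearest_sample` rule (argmin
over individual references rather than per-person means) is available,
since with two palms per person either reading of "smallest mean
distance" is defensible.

Two kernels are provided. The Canberra distance follows the `vegdist()`
dialect:

$$d(x, y) = \frac{1}{NZ} \sum_{i:\; x_i + y_i > 0}
  \frac{|x_i - y_i|}{x_i + y_i},$$

where $NZ$ counts non-double-zero taxa; every rare taxon present in only
one of the two communities contributes a full unit, which is what makes
this kernel discriminative for grossly similar communities. The unscaled
textbook sum is available via `scaled = FALSE`. Bray-Curtis is
$\sum|x_i-y_i| / \sum(x_i+y_i)$.

Every (query, pool) combination is attempted, so the sampling delay
$12\,\mathrm{h} \times (t_\mathrm{query} - t_\mathrm{ref})$ spans
−228 h … +228 h on the full grid. Accuracy is aggregated per (site,
delay); the delay decay is summarised by the Spearman rank correlation of
accuracy against |delay|, and time-of-day structure by stratifying on
query/reference period with plain Pearson chi-squared comparisons (no
continuity correction; large-sample comparisons, with Yates correction
available as an option).

Community-level companions: a one-factor PERMANOVA on Bray-Curtis
distances (pseudo-F from among/within sums of squared distances, label
permutation with the $+1$ convention so $p > 0$), a per-sample source
profile summing abundance over user-supplied indicator families (the
indicator lists are external inputs, not shipped data), and a
Mann-Whitney comparison of same- versus different-location skin-surface
dissimilarities.

## Diurnally varying species

For each (species, site, location) the 20-slot relative-abundance series
is decomposed additively at frequency 2 (one day = AM + PM): the trend is
the centred moving average with weights $(0.25, 0.5, 0.25)$, the seasonal
figure is the per-period mean of the detrended series centred to sum to
zero, and the random component is the remainder — the classical recipe of
`decompose()`, re-implemented in vectorised form because the permutation
null requires on the order of $10^5$–$10^6$ decompositions;
`stats::decompose()` serves as the independent oracle in the test suite.
Additive rather than multiplicative decomposition is used, matching that
routine's default since nothing in the method requires otherwise.

Seasonality strength is

$$F_S = \max\!\left(0,\; 1 - \frac{\mathrm{Var}(R_t)}
  {\mathrm{Var}(S_t + R_t)}\right) \in [0, 1],$$

with sample variances (denominator $n-1$) over the slots where the trend
(hence $R_t$) is defined — the first and last slot drop out. Whether the
original computation used all slots or trend-complete slots is not
determinable; trend-complete is our documented choice. $F_S$ is invariant
to adding a constant and is 1 for a perfectly alternating series.

Significance: the (gap-filled) series is permuted uniformly 999 times,
each permutation decomposed, and
$p = \#\{F_{S,\mathrm{perm}} > F_{S,\mathrm{obs}}\} / 999$ — strict
inequality and no $+1$ correction, exactly the "proportion of
permutations" reading; a conservative $+1$ option exists. Permutations
act on post-interpolation values so observed and null statistics share
support. A zero-variance series returns $p = 1$ flagged degenerate:
every permutation ties the observed statistic and the strict inequality
would otherwise yield a vacuous $p = 0$. Under an i.i.d. null the
rejection rate at $\alpha = 0.05$ sits inside the exact binomial 95% CI
(test suite, 200 replicates × 199 permutations).

Practical rules: species with non-zero abundance at fewer than 4
timepoints are excluded (presence means abundance > 0, not merely a
non-missing sample); leading/trailing missing slots are trimmed; internal
gaps are filled by seasonal-aware interpolation (subtract per-period
means, interpolate linearly, re-add), which is exact on a noiseless
alternating series. No multiplicity correction is applied by default —
detection uses the raw $\alpha = 0.05$, as in the original method; a
corrected variant can be had by adjusting the catalog's p-values.

A paired alternative tests per-day (AM, PM) pairs with the two-sided
Wilcoxon signed-rank test: exact via the signed-rank distribution when
$n \le 25$ without ties, exact by sign-flip enumeration with average
ranks when ties or zeros occur and $n \le 14$, and the normal
approximation otherwise.

Robustness re-analyses mirror the two artefact checks: removal of a
negative-control species set (remove, renormalise to 100%, re-detect,
report removed/lost/retained), and single-species removal at one
(site, location) to demonstrate compositional induction — a genuinely
diurnal species forces an apparent antiphase rhythm in others through
closure, which disappears on removal and renormalisation.

## Dispersal networks

Per (location, family): species are aggregated to family level, each
site's series is $\log_2(x + \varepsilon)$-transformed with
$\varepsilon$ = half the smallest non-zero abundance in the table (the
original zero-handling is unstated; this keeps zeros finite and below
every observed value), internal gaps are linearly interpolated, and each
site is discretised into 5 equal-width bins over its own range ("i5").
Structure over the 6 site nodes is restricted to Markov lag 1 — an edge
means the parent site's abundance at $t$ informs the child site's at
$t+1$ — with at most 5 parents per child and no self-edges (a child's
candidate parents are the 5 other sites). The score is BDeu with
equivalent sample size 1, a documented stand-in for the original
engine's unspecified default evaluator (BIC is available and the choice
is recorded per model); the score is decomposable, so hill climbing over
single-edge additions/deletions rescoring one child per move is exact
and cheap. The search restarts from the empty network with shuffled move
enumeration (the shuffle only matters at exact score ties), replacing
the original engine's simulated-annealing machinery, which is
unnecessary for 6-node networks. Transitions spanning a missing slot at
the series edge are dropped, not imputed.

Edge roles are summarised by (parent class, child class) counts and
per-node in/out-degrees, with Kruskal-Wallis tests across the three site
classes. One caveat specific to the synthetic design: the two handrail
sites are noisy replicates of a single public pool, so public→public
edges (one handrail predicting the other) are strong by construction and
can rival public→skin counts; the planted-direction comparison is
therefore made against the reverse direction (skin→public), which shares
the same node pair structure.

## The synthetic generator

`generate_synthetic()` emulates the study design and is the ground truth
for every recovery experiment. Per location, compartments evolve on the
20-slot grid:

* **Baselines.** Species log-baselines are $\mathcal{N}(0,1)$ per
  (location, site class); each person's 5 signature species are boosted
  ×10 on their skin. The public pool starts from one baseline shared by
  all locations.
* **Dispersal.** At each PM slot, skin ← $(1-m_p)$·skin + $m_p$·public
  pool ($m_p = 0.3$ by default); at each AM slot skin is pulled back
  toward the personal baseline with weight 0.8 (overnight
  normalisation); household surfaces mix in the previous slot's skin
  with weight 0.3 at every step. With `public_turnover` > 0 a fraction
  of pool species is resampled daily, independently per location, so
  pools diverge over the study — without this, public queries are
  chance-level by construction and no delay decay exists to recover.
* **Diurnal species.** 8 species per (site, location) are amplified ×3
  in their peak period. The multiplier is applied to the site's
  expectation *after* the compartment dynamics, so the planted AM/PM
  expectation ratio is exactly the amplitude (testable through ratios to
  a non-planted species, which cancel closure) and the planted effect
  does not feed back into the mixing dynamics.
* **Noise and missingness.** Each expectation is multiplied by
  $e^{\mathcal{N}(0, 0.3)}$, closed to 100%, and each sample is dropped
  with probability 0.05 (absence of a metadata row, never a zero-filled
  column).

Compartments are burned in for 10 slots before recording so household
surfaces already carry their occupant's signal at day 1 — real homes are
not microbially naive, and without burn-in day-1 household queries would
be unmatchable in principle.

What the generator deliberately does not emulate: taxon-taxon
interactions, within-day public-pool dynamics, absolute biomass (only
compositions), sequencing depth and detection limits, and any planted
link between a species' abundance and its diurnality — so the diurnal vs
non-diurnal abundance comparison is exercised against an expected null
on synthetic data. Noise is log-normal multiplicative rather than
Dirichlet, preserving the rare-taxon structure that Canberra matching
depends on. Passing recovery tests therefore show the estimators work
when their assumptions hold, not that real data satisfy them.

Two emergent behaviours are worth knowing about. First, compositional
closure of the planted diurnal species induces *genuine* antiphase
rhythms in non-planted species (roughly a 10% alternation at default
settings), so false-positive rates among non-planted species exceed
$\alpha$ by construction; a clean null requires amplitude 1 *and*
dispersal off, which is what the calibration tests use. Second, the
dispersal dynamics themselves give skin communities a real 12-h rhythm
even with no planted species, which is the intended mechanism behind the
time-of-day matching asymmetries (morning references beat evening
references for household queries because evening skin has just mixed
with the public pool).

## Problem sizes and determinism

All randomness flows from explicit integer seeds; the same seed gives
bit-identical tables, catalogs and networks. Reported experiments use:
full 4×6×20 grids (~460 samples after missingness); 999 permutations per
series for detection and 199 for calibration sweeps (200 replicates);
PERMANOVA with 99–999 label permutations; DBN recovery over 25 seeded
generations of 8 families each, and sparsity-under-null over the full
120 (location, family) grid. The analysis drivers under `analysis/`
catalog the planted species plus a 30-species background rather than the
full 150×24 grid; the full grid is supported and scales linearly.

## Known limitations

* The matching experiment assumes the correct person is in every pool
  (closed-set identification); open-set behaviour is out of scope.
* $F_S$ at series length 20 with frequency 2 is upward-noisy; the
  permutation null absorbs this for testing, but raw $F_S$ values are
  not comparable across series lengths.
* BDeu(ESS = 1) is a stand-in for an unspecified scoring default; with
  ~19 transitions and 5 bins, uniform bin occupancy can favour large
  parent sets (singleton parent configurations score as uniform
  predictions), though discretised abundance series concentrate
  occupancy in practice and the empty network dominates under
  independence.
* The paired signed-rank exact path enumerates $2^n$ sign patterns only
  for $n \le 14$; beyond that with ties it falls back to the normal
  approximation.
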