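---
title: "Null-model analysis of cave community incidence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model analysis of cave community incidence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cavecomm)
```

## The scientific setting

Caves are island-like habitats: small, environmentally stable, and
colonised by organisms of very low dispersal ability. For such systems
the central question is whether local communities are shaped by
deterministic processes — habitat filtering, interspecific competition —
or are consistent with neutral colonisation–extinction dynamics
(ecological drift). With only species lists per site available, the
evidence has to come from the *geometry of occurrence*: how species
co-occur across sites, how nested the system is, how taxonomically
related the co-occurring species are, and how these patterns change in
space. This package implements that entire analysis for binary
species-by-site incidence matrices, together with seeded data
generators that emulate each assembly scenario.

## Data model

The central object is the incidence matrix: rows are species, columns
are sites, entries are 0/1 (counts binarize on read, since all
statistics are presence-absence based). Row totals $r_i$ give species
occupancy, column totals $c_j$ site richness, and $F = \sum_{ij} x_{ij}$
the fill. Companion tables carry site metadata (coordinates, cave
length/depth/altitude in metres, survey visits), a ranked taxonomic
classification, and categorical species traits. Survey effort is
classified from visit counts (1–3, 4–6, 7–9, 10–12 visits map to classes
1–4; values outside 1–12 are rejected rather than clamped because the
classification is defined only there), and `filter_by_visits()`
implements the exclusion of under-surveyed sites (default: fewer than 3
visits), dropping and reporting species whose rows empty out —
all downstream metrics are defined on the analysed matrix, so the pool
size γ is recomputed after filtering.

Missing length/depth/altitude values are permitted and excluded
pairwise per regression model, which preserves the per-model sample
size.

## Diversity partitioning

Proportional turnover is $\beta_P = 1 - \alpha/\gamma$ with $\alpha$
the *mean* per-site richness (the median is reported separately). It is
computed per site and averaged; the reported uncertainty is the
standard error of the per-site values. The allometric exponent solves
$\gamma = \alpha N^z$, i.e. $z = \ln(\gamma/\alpha)/\ln N$; natural
logs are used throughout, including the log–log (power-law) richness
regressions. Their significance is assessed by permuting the response
across sites, with the add-one estimator $p = (b+1)/(n_{perm}+1)$ so
that $p = 0$ never occurs. "Occurring in more than half of the sites"
uses a strict inequality on the site count.

## Co-occurrence metrics

For a species pair with occupancies $r_a, r_b$ and $S$ shared sites,
the checkerboard-unit count is $CU = (r_a - S)(r_b - S)$, which equals
the number of $2\times2$ submatrices of the form
$\{\{1,0\},\{0,1\}\}$ or $\{\{0,1\},\{1,0\}\}$ the pair spans. The
**C-score** is the mean CU over all unordered species pairs — no
further normalization by $r_a r_b$ or by site pairs, which is the form
consistent with "a normalized count of checkerboard submatrices". For
matrix-level inference any constant normalization cancels out of the
standardized effect size anyway.

**NODF** scores a pair of rows only when their totals *differ*
("decreasing fill"): the paired nestedness is then
$100\,S/\min(r_a,r_b)$, else 0; same over column pairs; the final score
divides the grand sum by the number of row pairs plus column pairs. The
richer member of a pair is decided by marginal totals, not physical
position, which makes the score invariant to row/column permutation.
Pairs whose smaller total is zero contribute 0.

Both metrics are verified in the test suite against exhaustive
enumeration oracles on matrices up to 7×7 (exact equality) and against
vegan's independent implementations.

## Null models and standardized effect sizes

Three randomization engines, all conserving $F$ exactly:

* **EE (equiprobable):** $F$ occurrences placed uniformly among cells.
  The null of no differences in species colonisation ability or site
  capacity.
* **PP (proportional):** sequential draws without replacement with cell
  probability $\propto r_i c_j$, renormalized after each draw. This is
  the drift null — a neutral model without dispersal limitation, where
  marginal totals reflect regional abundance and site capacity.
* **FF (fixed–fixed):** chains of random checkerboard flips, preserving
  every row and column total exactly. Ensembles are thinned Markov
  chains (burn-in 10·F successful swaps, one matrix saved every F
  swaps; both configurable). On a 3×3 instance with unit marginals the
  chain provably reaches all six permutation matrices (checked in the
  tests); uniformity of the chain is not asserted.

Inference uses $SES = (Obs - Exp)/StDev_{Exp}$ with the $n-1$ standard
deviation over the ensemble (the null values are a sample from the null
distribution), plus add-one empirical tail probabilities. The ensemble
default is 200 replicates. Zero-variance nulls leave the SES undefined
(flagged, never silently 0) while the tail probabilities are still
reported.

**Degenerate matrices.** By default EE/PP resample whole matrices until
no row or column is empty (capped at 10,000 attempts), keeping the
conditional distribution clean — degenerate draws would break NODF and
pool definitions. This conditioning becomes practically unsamplable for
very sparse matrices: a 20-site window holding 50+ species at fill
~110 has acceptance probability around $10^{-5}$, far beyond any
reasonable rejection budget. The window analysis therefore defaults to
the unconstrained null (`condition = FALSE`), which is also the
classical form of these randomization tests; both engines expose the
flag.

**Calibration.** On equiprobably assembled 20×30 matrices (fill 150)
tested against EE ensembles of 200, replicate SES values have mean ≈ 0,
SD ≈ 1.0–1.1 and ~5–8% exceedance of |1.96| (test suite and a 600-run
check during development). Observed and null matrices are exchangeable
by construction here, so the SES is exactly centred; the calibration
test in the suite asserts a ±0.15 band on the mean of 100 replicates,
which is ~1.5 standard errors wide and thus intentionally strict — a
small fraction of seeds fail it even under perfect calibration.

## Taxonomic relatedness

The classification has eight internal ranks (order, suborder,
superfamily, family, subfamily, tribe, genus, subgenus); the species is
the terminal level. The pairwise dissimilarity is the number of taxon
nodes on the tree path between two species: the lowest common taxon,
counted once, plus every recorded rank node below it on both descents,
species tips excluded; unrecorded ranks contribute no node. Two
species sharing everything through the subgenus are 1 step apart; two
species of different orders with seven recorded internal ranks each are
$1 + 7 + 7 = 15$ steps apart. This is the unique simple convention
consistent with the worked 15-step example that fixes the metric, and
it makes distance matrices ultrametric-consistent whenever all ranks
are recorded.

**NRI** is the SES of a community's mean pairwise distance (MPD)
against richness-matched draws from the pool, *without* the sign flip
some authors apply: positive NRI = overdispersed, negative = clustered.
Null draws are equiprobable (not occupancy-weighted), matching the
equiprobable standard the analysis tests against, and default to 1000
replicates (cheap, and stabilizes the SD; the 200-replicate default
applies only to the co-occurrence ensembles, which are far more
expensive per replicate). The pool is all species of the analysed
matrix. Communities below richness 2 and zero-variance nulls are
flagged, not dropped silently.

## Spatial analysis

Sites are sorted by longitude (ties: latitude, then site id — a total,
deterministic order) and cut into non-overlapping windows, nine windows
of 20 sites at the 189-cave scale; the surplus at the high-longitude
end is reported unassigned. Each window's submatrix (empty species rows
dropped) gets its own C-score and NODF ensembles, and each SES series
is regressed on window pooled richness with a permutation test.

The spatial covariate EV1 is the first principal-coordinate axis of the
Euclidean distance matrix of raw decimal-degree coordinates: squared
distances, double-centred, leading eigenvector scaled by the square
root of its eigenvalue. That is the standard construction yielding a
usable regression covariate; the leading eigenvector of the raw
distance matrix is available as `method = "raw"`, and both are centred
and oriented to correlate positively with longitude so the sign is
reproducible. Great-circle distances are deliberately not used — at the
regional scale of interest plain Euclidean distance on decimal degrees
is what "Euclidean distance matrix of sites" means; users needing
haversine can supply projected coordinates.

## Inference layer

`glm_eta2()` fits main-effects linear models and reports, per term, the
partial sum of squares by term deletion (Type III for a main-effects
model), partial $\eta^2 = SS_{term}/(SS_{term}+SS_{res})$, the F-test
p-value with conventional stars, and — for single-df terms — the
coefficient sign. Rank-deficient designs are an error naming the
collinear terms; a numerically constant response yields all-zero
$\eta^2$ rather than 0/0 noise.

Pairwise co-occurrence inference pre-screens pairs for significant
tails ($p < 0.05$ in either direction, tagged aggregated/segregated)
before the trait ANOVA, because the vast majority of pairs do not
interact and would swamp any signal. In the trait ANOVA each pair is
coded 1 where both species share the trait level and 0 otherwise, and
pair observations are treated as independent despite shared species —
the classical screening approach; this underestimates the dependence
among pairs, which is a known limitation of the method rather than of
the implementation.

## Synthetic data: what it emulates, and what it does not

* `gen_random_matrix()` — equiprobable occupancy at fixed fill,
  conditional on no empty row/column (a flag disables the conditioning
  for error-path testing).
* `gen_nested_matrix()` — threshold (stair) matrices with strictly
  decreasing site richness; `noise` flips a fraction of cells. The
  square steepness-1 case has distinct totals on both margins and
  scores NODF = 100; non-square stairs are perfectly subset-nested but
  tie some row totals, which NODF scores as 0 by definition.
* `gen_checkerboard_matrix()` — perfectly complementary species pairs
  on disjoint site halves; within-pair CU is $(N/2)^2$, maximal given
  the marginals.
* `gen_drift_assembly()` — passive sampling: each site draws its
  community without replacement with probability proportional to
  species pool weights. With lognormal weights this produces the
  right-skewed occupancy distributions of real regional data sets.
* `cave_study_scenario()` — the bundled study: 141 species × 189
  sites, lognormal site capacities (meanlog log 4.2, sdlog 0.75, giving
  median ≈ 4 and mean ≈ 5.6 species per site, hence
  $\beta_P \approx 1 - 5.6/141 \approx 0.96$ by construction), weights
  with sdlog 1.5, capacities coupled weakly to generated cave length
  (exponent 0.25), coordinates in a Carpathian-sized box, lognormal
  cave lengths and depths, visits in 3–12, a random 9-rank taxonomy and
  binary traits. Species never drawn receive one occurrence at a random
  site so γ is exactly 141.

These generators reproduce the statistical structure the pipeline
assumes — marginal skew, nestedness, segregation, drift — but not the
features of real survey data that have no bearing on the algorithms:
spatially autocorrelated sampling effort, taxonomically clustered
occupancy, imperfect detection, or literature-compilation biases.
Passing tests on synthetic data therefore validate the machinery and
its calibration, not any biological claim about a particular fauna.

## Numerical choices and problem sizes

Tie-breaks and degenerate inputs are handled deterministically
throughout: window sorting is total; EV1 orientation is fixed; NODF
pairs with tied or zero totals contribute 0; zero-variance SES and
sub-richness-2 NRI are NA with a reason. Randomization ensembles are
reproducible given (seed, model, reps).

The test suite exercises the full pipeline at deliberately compact
sizes — exhaustive oracles up to 7×7, calibration at 20×30 with
200-replicate ensembles and 100 replicate experiments, NRI calibration
with 200 communities of a 60-species pool at 300 draws each, and one
full 141×189 drift scenario with nine 20-site windows at 200
replicates — sizes chosen so the whole suite completes in well under a
minute while keeping every Monte-Carlo check adequately powered. The
reproduction script (`scripts/acceptance.R`) uses the full
141×189 scenario end to end.

## Known limitations

* The FF engine asserts reachability, not provable uniformity, of its
  swap chain; very long thinning intervals are the standard mitigation
  and are configurable.
* The sequential-weighted PP draw is $O(F \cdot n_{cells})$; it is
  comfortable at the 141×189 scale but not intended for matrices with
  millions of cells.
* The trait ANOVA treats pairs as independent (see above).
* NODF's "decreasing fill" convention means heavily tied marginals
  deflate the score; this is a property of the metric, not a knob.
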