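# cavecomm

Null-model analysis of species-by-site incidence data from insular
habitats — caves, islands, habitat fragments — where the scientific
question is whether community assembly deviates from neutral
(drift-like) colonisation. The package was built around cave-dwelling
springtail (Collembola) communities but applies to any binary
presence-absence matrix.

## What it computes

Given a binary incidence matrix (rows = species, columns = sites, row
totals *r\_i*, column totals *c\_j*, fill *F*):

- **Diversity partitioning.** Proportional turnover
  β\_P = 1 − α/γ (α = mean per-site richness, γ = pool richness), site
  richness summaries, single-site endemics, and the allometric exponent
  *z* solving γ = α·N^z.
- **Co-occurrence metrics.** The **C-score**, the mean number of
  checkerboard units CU = (r\_i − S)(r\_j − S) over species pairs
  (segregation), and **NODF** (nestedness by overlap and decreasing
  fill, 0–100), both matrix-wide and per species pair.
- **Null models.** Equiprobable (**EE**: F occurrences placed uniformly),
  proportional (**PP**: placement probability ∝ r\_i·c\_j — the
  ecological-drift null), and fixed–fixed (**FF**: checkerboard-swap
  chains preserving all marginals). Inference is by standardized effect
  size, SES = (Obs − Exp)/StDev\_Exp over an ensemble of 200 randomized
  matrices, with add-one empirical tail probabilities; |SES| > 1.96
  flags a two-sided 5% deviation.
- **Taxonomic relatedness.** Step-count distances from a ranked
  9-level classification (number of taxon nodes between two species via
  their lowest common taxon), mean pairwise distance (MPD), and the net
  relatedness index **NRI** — the SES of MPD against richness-matched
  random pool draws, *without* a sign flip, so positive NRI means
  overdispersion.
- **Spatial structure.** Longitude-sorted non-overlapping shifting
  windows (nine windows of 20 sites for a 189-cave study) with
  per-window C-score/NODF SES, and **EV1**, the dominant
  principal-coordinate eigenvector of the inter-site Euclidean distance
  matrix, as a spatial covariate.
- **Inference layer.** Main-effects linear models reporting partial
  η² = SS\_term/(SS\_term + SS\_residual) per term, permutation tests
  for power-law (log–log) richness regressions, significance
  pre-screening of species pairs, and trait-identity ANOVA on pairwise
  SES values.
- **Synthetic data.** Seeded generators for random, nested,
  checkerboard and drift-assembled matrices, 9-rank taxonomies, cave
  metadata and categorical traits, so the full pipeline runs
  end-to-end with no external data.

## Worked example

```r
library(cavecomm)

# a drift-assembled metacommunity at the cave-study scale
study <- cave_study_scenario(seed = 1)
diversity_summary(study$matrix)
#> Diversity summary: 141 species x 189 sites
#>   alpha: mean 6.10, median 4, range 1-38
#>   beta_P = 0.96 +/- 0.00
#>   single-site endemics: 50 (35.5%)
#>   species in > half the sites: 1
#>   allometric exponent z = 0.60
```

β\_P = 0.96 says that a site of average richness contains only 4% of the
regional pool: near-total turnover between caves, the signature of
isolated, independently colonised habitats. A random (equiprobable)
matrix is correctly *not* flagged by the C-score test, while planted
checkerboard pairs are strongly segregated:

```r
m <- gen_random_matrix(20, 30, fill = 150, seed = 7)
null_model_test(m, "cscore", model = "EE", reps = 200, seed = 8)
#> Obs = 31.5684, Exp = 30.7665 (SD 1.0542), 200 null values
#> SES = 0.761  (p_lower = 0.7662, p_upper = 0.2488)

cb <- gen_checkerboard_matrix(5, 20, seed = 31)
null_model_test(cb, "cscore", model = "EE", reps = 200, seed = 32)
#> Obs = 55.5556, Exp = 24.1139 (SD 1.9287), 200 null values
#> SES = 16.302  (p_lower = 1, p_upper = 0.004975)
```

The SES of 16.3 (p = 1/201) is the smallest possible upper-tail
probability with 200 randomizations — every null matrix scored below
the observed one.

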