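# minemicro

Soils flanking rivers that drain mining areas carry two intertwined
signals: a heavy-metal pollution gradient decaying with distance from the
mine, and a soil microbial community that reorganises along that gradient
and with land use (abandoned land, vegetable fields, paddy fields).
`minemicro` is an R package for analysing exactly this kind of survey —
a metal concentration panel, a 16S OTU table, and a sample environment
table — the way soil-microbiology studies report it: pollution indices
with grades, alpha/beta diversity, constrained ordination against
environmental drivers, and environment–taxon correlation tables. A seeded
synthetic-scenario generator emulates the whole sampling design so every
stage can be exercised and validated without field data.

It is aimed at environmental microbiologists and soil scientists who have
an OTU table and a set of site measurements and want the standard analysis
chain as composable, tested, pipe-friendly functions rather than a GUI or
a heap of one-off scripts.

## What it computes

**Pollution scoring** (per site, over metals *i* with measured
concentration Cs, regional background Cn and Hakanson toxic-response
factor Tr):

- contamination factor `Cf_i = Cs_i / Cn_i`
- ecological risk `Er_i = Tr_i · Cf_i` and the potential ecological risk
  index `RI = Σ_i Er_i`
- Nemerow comprehensive pollution index
  `PN = sqrt((max(Cf)² + mean(Cf)²) / 2)`, which always lies between
  `mean(Cf)` and `max(Cf)`
- grade labels (PN: clean ≤ 0.7 < warning ≤ 1 < light ≤ 2 < moderate ≤ 3 <
  heavy; RI: low < 150 ≤ moderate < 300 ≤ strong < 600 ≤ very strong) and
  site rankings.

**Community structure**: observed species, bias-corrected Chao1, Shannon
(base 2 by default), Gini–Simpson; exact hypergeometric rarefaction
curves; Bray–Curtis dissimilarity on relative abundances; PCoA by Gower
double-centering (negative eigenvalues reported, not corrected);
shared-OTU (Venn) accounting; UPGMA similarity clustering.

**Environment–community association**: redundancy analysis (RDA, PCA of
the fitted values of a multivariate regression of the Hellinger-transformed
community on standardized environment variables), Monte Carlo permutation
tests with `p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm)`, greedy forward
selection, variance partitioning on the adjusted-R² (Ezekiel) scale, and
Spearman/Pearson correlation tables with `*`/`**` significance stars.

## Worked example

```r
library(minemicro)

sc <- generate_scenario(seed = 1)      # 7 sites x 3 composite samples
scores <- assess_pollution(sc$panel, sc$background)
scores
#> Pollution assessment (mean_conc) over metals: Cu, Zn, Pb, Cd, Ni
#> # A tibble: 7 x 7
#>   site     ri    pn pn_grade ri_grade rank_pn rank_ri
#>   <chr> <dbl> <dbl> <chr>    <chr>      <int>   <int>
#> 1 S1    470.  10.2  heavy    strong         1       1
#> 2 S2    369.   8.02 heavy    strong         2       2
#> 3 S5    296.   6.44 heavy    moderate       3       3
#> 4 S3    273.   5.90 heavy    moderate       4       4
#> 5 S6    150.   3.23 heavy    low            5       5
#> 6 S4    126.   2.72 moderate low            6       6
#> 7 S7     64.6  1.41 light    low            7       7
```

The mine-side site S1 is the most polluted on both indices and pollution
decays with distance from the mine, with left-bank sites (S1–S4) scoring
above right-bank sites at comparable distance — the spatial structure the
generator plants and the indices recover.

```r
alpha_diversity(sc$otu) |> head(3)
#> # A tibble: 3 x 5
#>   sample observed_species chao1 shannon simpson
#> 1 S1-1                 96  97      5.31   0.960
#> 2 S1-2                 85  85      4.97   0.946
#> 3 S1-3                 89  89.5    5.23   0.961

pcoa_ord(bray_curtis(sc$otu))
#> PCoA of 21 samples; axis 1: 41.41%, axis 2: 19.82%

ra  <- relative_abundance(collapse_taxa(sc$otu, "phylum"))
env <- env_numeric(sc$env, c("pH", "MC", "TOC", "TN", "TP", "AK", "PN"))

rda_fit(t(ra), env)
#> RDA on 7 variable(s); R2 = 0.550 (adj 0.308)
#> Constrained axes: RDA1 60.99%, RDA2 19.17%

forward_select(t(ra), env, n_perm = 199, seed = 1)
#> # A tibble: 2 x 4
#>   variable r2_added cum_r2 p_value
#> 1 pH          0.296  0.296   0.005
#> 2 MC          0.119  0.415   0.025
```

Forward selection finds pH first — the generator gives taxa log-linear
responses to pH (and to the true pollution index), and the selection
recovers the planted driver. `vpa()` then splits the explained variance
between predictor groups, and `spearman_matrix()` +
`plot_cor_heatmap()` produce the usual clustered environment–taxon
heatmap. Each fitted object has `tidy()`, `glance()` and `autoplot()`
methods; `run_pipeline()` chains every stage and writes TSV artifacts plus
a seed-stamped manifest (a command-line wrapper ships in
`inst/scripts/run_pipeline.R`).

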