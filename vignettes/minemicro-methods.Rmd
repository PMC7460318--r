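---
title: "Methods: pollution indices, ordination and the synthetic scenario"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollution indices, ordination and the synthetic scenario}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minemicro)
```

`minemicro` implements the analysis chain of a river-bank soil survey
around a mining area: heavy-metal pollution scoring, OTU-table diversity
and ordination, and environment–community association. This vignette is
the package's own account of the models, the defaults, and the choices
made where the methodology was genuinely open.

## Pollution indices

For metal $i$ at a site, with measured concentration $C_{s,i}$ (mg/kg),
regional background $C_{n,i}$ (mg/kg) and toxic-response factor $T_{r,i}$:

$$C_{f,i} = \frac{C_{s,i}}{C_{n,i}}, \qquad
  E_{r,i} = T_{r,i}\, C_{f,i}, \qquad
  RI = \sum_i E_{r,i}, \qquad
  P_N = \sqrt{\tfrac{\max_i C_{f,i}^2 + \overline{C_f}^2}{2}}.$$

$P_N$ is pinned between $\overline{C_f}$ and $\max_i C_{f,i}$, so it is
driven by the single worst pollutant; $RI$ weights each metal by its
biological toxicity, so cadmium ($T_r = 30$) dominates even at modest
enrichment. Both are *ratios*: rescaling all concentrations and
backgrounds by a common factor leaves every index unchanged, which the
test suite checks as a property.

Two conventions are inputs, not constants:

* **Backgrounds** $C_n$ are region-specific. `default_background()`
  ships literature-plausible values for copper-mining soils of the lower
  Yangtze region (Cu 24.4, Zn 66.5, Pb 26.2, Cd 0.186, Ni 29.8 mg/kg),
  but any real assessment should supply its own table.
* **Toxic-response factors** follow the Hakanson convention
  (Cu = Pb = Ni = 5, Zn = 1, Cd = 30), overrideable per metal in the same
  file.

Grade labels use the customary cut tables
(PN: clean $\le 0.7$, warning $\le 1$, light $\le 2$, moderate $\le 3$,
heavy $> 3$; RI: low $< 150$, moderate $< 300$, strong $< 600$, very
strong $\ge 600$).

With replicate composite samples per site, `assess_pollution()` offers
two aggregation modes. `mean_conc` (default) averages concentrations per
site before scoring; `per_replicate` scores each composite and reports
mean ± sd. $RI$ is linear in concentrations, so the modes agree on it
exactly; $P_N$ is convex, so the replicate-mean $P_N$ is never smaller
than the mean-concentration $P_N$ (Jensen), and the gap grows with
replicate noise. Field reports that quote "$P_N \pm$ sd" per site
implicitly use the second mode; both are provided because surveys are not
consistent about this.

## Alpha diversity and rarefaction

`observed_species`, bias-corrected Chao1
($S_{obs} + F_1(F_1 - 1)/(2(F_2 + 1))$, defined even without doubletons),
Shannon entropy, and Gini–Simpson ($1 - \sum p_i^2$). Shannon defaults to
base 2 — the convention of the early QIIME lineage this analysis style
descends from — with the base exposed because the natural log is equally
common; the choice only rescales values.

Rarefaction ("dilution") curves use the exact hypergeometric expectation
of richness in a without-replacement subsample (via `vegan::rarefy`)
rather than repeated subsampling: the curve is deterministic, monotone
and concave, equals the observed richness at full depth, and the test
suite confirms the expectation against Monte Carlo resampling.

## Beta diversity and unconstrained ordination

The survey style this package supports names no β-diversity metric, so
the default is the QIIME convention: Bray–Curtis on relative abundances
(depth-invariant by construction). PCoA is classical metric scaling:
Gower double-centering of $-d^2/2$ and an eigendecomposition, with axis
scores scaled by the square roots of positive eigenvalues. Bray–Curtis
is non-Euclidean, so negative eigenvalues occur; they are *reported*, not
corrected (no Cailliez/Lingoes), and proportions explained are taken over
positive eigenvalues only — transparency over cosmetic positive-definiteness.
On genuinely Euclidean input, PCoA reproduces the configuration's pairwise
distances to machine precision, which is the oracle the tests use.

Shared-OTU (Venn) accounting marks an OTU present in a group when its
summed count there is positive, and partitions the OTU union over all
non-empty group subsets; the partition property is checked against a
brute-force power-set enumeration. The similarity heatmap ordering uses
UPGMA — no linkage is standard for such heatmaps, and average linkage is
the common default and exactly recoverable on ultrametric input.

## Constrained ordination, permutation inference, VPA

RDA is implemented as its definition: Hellinger-transform the community
(square root of relative abundances — the standard variance
stabilisation making linear ordination appropriate for counts; a `"none"`
option exists), column-centre, regress on the standardized environment
matrix by least squares (QR), and take the SVD of the fitted values.
$R^2 = SS_{fit}/SS_{total}$; adjusted $R^2$ uses the Ezekiel correction
$1 - (1 - R^2)(n-1)/(n-m-1)$, which variance partitioning needs to be
approximately unbiased. Collinear environment columns are an error that
names the dependent column, rather than a silent drop.

The Monte Carlo significance test permutes environment rows uniformly
(no blocking — the design emulated here states none) and recomputes the
pseudo-F; $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$, so $p$
can never be 0 and the smallest attainable value is $1/(n_{perm}+1)$.
Default $n_{perm} = 999$; seeds are explicit arguments recorded in the
result objects and in pipeline manifests. Calibration is tested: under a
simulated null the rejection rate at $\alpha = 0.05$ sits within a
percentage point of 0.05 over 10,000 simulations.

Forward selection greedily adds the candidate with the largest added
$R^2$, admitted while the permutation p-value of its *conditional*
contribution (candidate column permuted, selected columns fixed) is at
most $\alpha = 0.05$, stopping at the first rejection. Power is checked
by simulation: a planted pH driver at the generator's default effect size
is selected first in well over 90% of replicates.

VPA computes the adjusted $R^2$ of every union of 2–4 predictor groups
and solves the inclusion–exclusion system
$R(S) = \sum_{T \cap S \neq \emptyset} a_T$ for the unique/shared atoms;
the residual is $1 - R(\text{all})$. By construction the fractions sum to
1 exactly (the tests assert it to $10^{-9}$, and agreement with
`vegan::varpart` on two-group designs to $10^{-6}$). Shared fractions may
be slightly negative — an artifact of the adjusted scale — and are
reported as-is. Which variables form which circle is configuration: the
pipeline's default contrasts chemistry (pH + PN) against
nutrient/physical variables, but any 2–4 disjoint groups are accepted.

## Correlation tables

Spearman (taxa × environment) and Pearson (environment × environment)
tables report $\rho$, a two-sided p from the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, and stars at exactly $p<0.05$ (`*`)
and $p<0.01$ (`**`). No multiple-testing correction is applied by default
— matching how such heatmaps are conventionally presented — but
`adjust = "BH"` appends a Benjamini–Hochberg column, and honesty
recommends it: with site-level means ($n = 7$) most star-level claims are
fragile, which is why the correlation functions accept either composite
replicates or site means as observations. Taxa are pre-filtered at mean
relative abundance > 1% across all samples (the "> 1%" convention is
ambiguous between per-sample and mean; the mean reading is implemented).
Constant columns yield a missing $\rho$ with a warning rather than an
error, and are imputed as 0 for display clustering only.

The group-difference helper is the classical equal-variance one-way
ANOVA (`oneway.test(var.equal = TRUE)`), the test conventionally quoted
for "differed significantly" statements about site nutrient tables.

## The synthetic scenario generator

`generate_scenario()` emulates the *statistical structure* the analysis
assumes, not any particular data set:

* **Design**: seven sites, four on the left (mine-side) bank at 100,
  300, 600 and 1200 m from the mine, three on the right bank at 400, 900
  and 2000 m; the farthest site is a low-disturbance reference. Land use:
  abandoned land nearest the mine, vegetable fields near settlements,
  paddy fields elsewhere. Three composite samples per site (21 samples).
* **Metals**: expected concentration
  $C_n \cdot (1 + A\,e^{-d/\lambda} + b\,\mathbb{1}[\text{left}])$ with
  per-metal amplitude $A$ (Cu 10, Cd 14, Pb 2.5, Zn 3.5, Ni 1.2),
  e-folding distance $\lambda = 600$ m and left-bank penalty $b = 0.4$,
  times lognormal measurement noise (sd 0.15). Exponential decay is the
  simplest monotone model for pollution spreading from a point source;
  the bank penalty encodes the mine lying on one side of the river. Site
  spacing is deliberately such that neighbouring sites' expected indices
  differ by more than replicate-level noise, so rankings are identifiable
  — a degenerate near-tie would make ranking recovery meaningless for any
  method.
* **Environment**: pH, MC, TOC, TN, TP, AK drawn per vegetation class
  (e.g. paddy: high MC and nutrients; abandoned: low nutrients, high TP;
  vegetable: elevated pH), with within-class normal noise.
* **Community**: 120 taxa assigned to 12 realistic phyla (10 bacterial,
  2 archaeal); expected proportions from a log-linear model in
  standardized pH and the true $P_N$ (coefficients drawn with sd 0.8 and
  0.5); counts sampled Dirichlet-multinomial at depth 20,000 with
  concentration $\theta = 200$ for overdispersion ($\theta = \infty$
  degenerates to multinomial). Sequencing depth, taxon count and effect
  sizes were fixed once at values giving communities that behave like
  field 16S data at phylum level (dominant phyla at tens of percent,
  detectable but not overwhelming environmental signal).
* **Ground truth** (noise-free concentrations, true PN/RI, decay and
  response coefficients, expected proportions) rides along, so recovery
  is scorable at every stage, and `write_scenario()` emits exactly the
  file formats the readers consume plus a seed-stamped JSON manifest.

What passing tests on this generator do and do not show: they validate
the *computational chain* — indices, estimators, ordination and inference
recover planted structure at realistic noise — but the generator draws
taxa independently given pH and PN, has no spatial autocorrelation beyond
the distance decay, no compositional interactions between taxa, and no
sequencing artifacts (chimeras, contamination, variable read quality).
Results on real data inherit none of these guarantees.

## Numerical choices and degenerate inputs

* OTU counts must be integral within $10^{-9}$ and are then coerced;
  all-zero samples are dropped with a warning (a common artifact of
  subsetting), never silently kept or fatal.
* Relative-abundance columns sum to 1 within $10^{-12}$; Venn
  subset counts partition the union exactly; `collapse_taxa()` conserves
  per-sample totals exactly, pooling lineages lacking the rank under
  `"Unassigned"` so the audit trail closes.
* PCoA/RDA axis retention uses a relative eigenvalue/singular-value
  tolerance of $10^{-9}$ of the largest; ties in site rankings use
  `ties.method = "min"`.
* Permutation p-values compare with a $10^{-12}$ slack on
  $F_{perm} \ge F_{obs}$ so exact ties (as under tiny $n$) count as
  exceedances, the conservative direction.
* $|\rho| = 1$ correlations report the smallest representable two-sided p
  rather than 0, keeping $p \in (0, 1]$.

## Problem sizes used in validation

The test suite and the acceptance script validate at sizes chosen to make
the checks sharp but routine on a laptop: ordination oracles on
$10 \times 8$ random instances, permutation calibration over 10,000 null
simulations at $n = 10$, forward-selection power over 200 generated
scenarios, and scenario-level checks on the default 7-site × 3-replicate
design. Dirichlet-multinomial convergence is checked at depth $10^6$
against a 0.005 tolerance.

## Known limitations

* The pipeline consumes an already-built OTU table; read QC, chimera
  removal, clustering and taxonomy assignment are upstream concerns.
* UniFrac and other phylogeny-aware metrics are out of scope (no tree is
  built); NMDS and CCA are likewise not provided.
* Figure-level percentages from published surveys (PCoA/RDA axis
  interpretations) depend on the original reads and unstated tool
  versions and cannot be regenerated from tables alone; the package
  validates its ordination against algebraic oracles instead.
* The t-approximation for Spearman p-values is asymptotic; at $n < 10$
  exact permutation p's differ by up to a few hundredths (tested), which
  is another reason to prefer replicate-level observations.
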