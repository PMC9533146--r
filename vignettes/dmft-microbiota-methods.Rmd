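---
title: "Characterizing oral microbiota along the DMFT index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing oral microbiota along the DMFT index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmftmicro)
```

## The scientific question

Dental caries is diagnosed macroscopically and scored with the DMFT index —
the count of decayed, missing (due to caries) and filled teeth, binned here
into five severity categories: healthy (0), low (1–3), medium (4–6), high
(7–13) and extremely high (≥ 14). The open question this package addresses
is whether salivary 16S community profiles carry a reproducible signal
along that clinical axis: does diversity, the pan/core/accessory structure,
the co-occurrence network, or total microbial biomass change as caries
severity progresses?

`dmftmicro` implements that analysis as a tested, reusable pipeline over a
sample × taxon count table, a taxonomy, sample metadata and a phylogenetic
tree, together with a cohort simulator that plants known structure so every
stage can be validated end to end without sequence data.

## The analysis stages and their models

### Depth filtering and aggregation

Samples with fewer than 3,000 reads (the conventional amplicon cutoff; the
comparison is inclusive) are removed before analysis; shallow libraries
make prevalence and rarity statements unreliable. Counts are then summed to
a working rank, genus by default. Presence means count > 0 throughout — no
detection floor is imposed, so prevalence statements are exactly
reproducible from the table.

### Diversity and ordination

Alpha diversity uses observed richness and Shannon entropy in nats
(`H = -sum p_i log p_i`); the log base is a convention and nats are the
analytical default. Rarefaction curves use seeded subsampling without
replacement.

Beta diversity offers Bray–Curtis and Jensen–Shannon divergence on relative
abundances, and both UniFrac variants over the tree: unweighted UniFrac is
the fraction of branch length unique to one of two samples among branch
length present in either; weighted UniFrac sums branch length times the
absolute difference of read proportions descending through each branch,
normalized by default so distances lie in [0, 1]. JSD is returned as the
divergence (bounded by log 2), with the metric square-root form behind a
flag.

Principal coordinate analysis Gower-centres `-D^2/2` and eigendecomposes;
coordinates are built only from positive eigenvalues. Bray–Curtis and JSD
are semi-metric, so negative eigenvalues occur; they are reported and
truncated at zero for the variance statistic below (no Lingoes/Cailliez
correction by default — the simplest defensible convention; a Lingoes-style
option exists). The headline ordination statistic is **TVE**, the fraction
of positive ordination variance captured by the first five principal
coordinates. Five axes is the pipeline default (`k = 5`) and the quantity
is monotone in `k` by construction.

Group association is tested by PERMANOVA: total squared distance is
partitioned into between- and within-group components, the pseudo-F
statistic is referenced against label permutations (9,999 by default), and
the p-value uses the `+1` convention so it is never zero.

### Pan, core and accessory microbiota

Per DMFT category, the **pan** microbiota is every taxon observed at least
once, the **core** is the taxa present in at least 85% of that category's
samples (inclusive at the boundary), and the **accessory** ("invaders") is
pan minus core — the identity `|accessory| = |pan| - |core|` holds exactly.
The **DMFT core** is the intersection of the per-category cores, i.e. the
genera resident at every severity stage. Prevalence is computed within
category, matching the per-category definition of the core. The working
unit is a caller-chosen rank (genus by default), since the biological
claims are about genera.

Richness proportions assign each pan genus to exactly one group by the
precedence DMFT-core > accessory > disease-associated > normal flora >
unclassified. The precedence is a package convention chosen so the four
reported proportions always come from disjoint groups; the genus lists are
editable plain-text files shipped under `inst/extdata/` and results should
be reported with the list source used.

### Co-occurrence networks and the entropy statistic

Genus–genus association uses Spearman rank correlation on relative
abundances with average ranks for ties. P-values come from the two-sided
large-sample t approximation (recommended for n ≥ 10; an exact option via
the rank-statistic null distribution exists for small untied samples), and
are Benjamini–Hochberg adjusted as one family per network — all testable
pairs, whether or not they survive pruning. An edge is kept when
|rho| > 0.5 **strictly**; FDR significance at 0.05 is stored as an edge
attribute, never used for pruning, so non-significant strong correlations
remain visible. The correlation matrix is symmetric, so the graph is
undirected; an export flag duplicates arcs for tools that expect them.

The **entropy statistic** is the fraction of associations that are
significant. A community whose surviving associations are almost all
significant is far from random — low entropy in the ecological reading; the
raw fraction is reported and interpretation left to the caller. The default
denominator is the retained edges; an all-pairs denominator is available
and is what the null-calibration suite uses, because under independence the
pruned network frequently has no edges at all (where the edge-based
fraction is undefined by contract).

Communities are extracted by greedy modularity-maximizing agglomeration on
absolute edge weights, merging the connected pair with the best modularity
gain until no gain remains and returning the partition with maximal
modularity along the path. Ties break on the lexicographically smallest
pair, so the result is fully deterministic; isolated genera stay
singletons. Degree-centrality ranking is descending with lexicographic
ties, truncated to the top 50.

### Leave-one-genus-out influence (delta-TVE)

Candidate genera — the top 50 by mean relative abundance, or by network
degree — are dropped one at a time: the genus column is removed, its leaf
pruned from the tree, and TVE recomputed from a fresh weighted-UniFrac
PCoA. `delta_tve = tve_without - baseline` is signed; influence is read
from |delta|. Drops are independent, never cumulative, so candidate order
is irrelevant. Each perturbed run recomputes distances from scratch —
correctness over speed at these problem sizes. A genus with no reads has
delta exactly zero (its branch carries no proportion), which the tests
assert identically. Reports can be annotated with an oxygen-utilization
class per genus (aerobic/anaerobic/facultative, defaulting to unknown)
from a two-column TSV.

### Per-category biomass models

Microbial biomass is modelled per DMFT category by quasi-Poisson
regression: log-link count regression fitted by IRLS with a free dispersion
`phi = Pearson chi-square / (n - p)`; standard errors are Poisson errors
inflated by `sqrt(phi)`. The outcome is the per-sample total genus-level
count — the simplest operational reading of "mean taxonomic abundance";
the outcome and covariates are explicit arguments so other readings are
selectable. Covariates are sex, HIV status, periodontal status and
relative abundances of an explicit list of families (the pipeline defaults
to the three most abundant, fewer when a category is small, and drops
covariates constant within a category as unidentifiable). One model per
category with an identical covariate set makes the per-cell Wald stars
comparable across severity stages; no multiplicity correction is applied
by default (a BH option covers the joint table).

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions the pipeline targets:

| parameter | default | rationale |
|---|---|---|
| samples per category | 11/32/21/16/8 | the cohort's descriptive table |
| taxa / core size | 165 / 65 | category pan ≈ 80 genera, ≈ 75–80% core |
| depth (lognormal, log scale) | mean log(14,351), sd 1.1 | median library ~14k reads; wide spread so the 3,000-read filter removes a handful of the 88 samples |
| core / base concentration | 1.0 / 0.05 | core genera abundant and universal; accessory sparse and rare |
| accessory rate / occupancy | 0.85 / 0.7 | category-private accessory taxa at low prevalence |
| latent factors / strength | 3 / 1 | strongly structured co-occurrence, as observed in oral communities; 0 is the calibration null |
| DMFT scores | uniform on each category's range (extremely high capped at 20) | only category totals are known |

Mechanism: per sample, clinical covariates are drawn at cohort-typical
frequencies; library depth is lognormal, scaled by any planted covariate
effects (so biomass effects are recoverable by the GLM stage); latent
factor scores shift the log Dirichlet concentrations of loaded taxa
(inducing positive rank correlations controlled by `factor_strength`);
composition is Dirichlet and counts multinomial at the drawn depth.
Accessory genera have zero concentration outside their own category. At a
core prevalence target of 1.0, presence is guaranteed by construction: any
core genus the multinomial left at zero receives one read transferred from
the sample's most abundant taxon (a negligible distortion at these
depths); targets below 1 use Bernoulli presence masks and are approximate.
Identical designs and seeds give bit-identical data, and a ground-truth
record (core membership, accessory sets, loadings, planted coefficients)
accompanies every dataset.

What the generator does **not** emulate: sequencing error, chimeras,
taxonomic misassignment, phylogenetic signal in abundance (the tree is
random), rank correlation induced by shared environment rather than latent
factors, and zero-inflation beyond what Dirichlet-multinomial sparsity
produces. Passing recovery tests therefore demonstrates that the pipeline's
statistics behave as designed under their own assumptions — not that those
assumptions hold in any particular real cohort.

Two artefacts of compositional count data surfaced while calibrating the
independence null and are worth knowing about. First, closure: relative
abundances of k independent taxa carry a built-in correlation of about
−1/(k−1), so "mean Spearman ≈ 0" is only observable with enough taxa (the
null suite uses 100). Second, depth coupling: with widely varying library
sizes, rare taxa drop below detection together in shallow samples, which
induces weak positive correlations that are a property of sampling depth,
not of the community; the null suite therefore holds depth nearly constant.

## Numerical and testing choices

* Distance matrices are symmetrized against floating-point drift and
  validated (symmetry 1e-12, exact zero diagonal).
* PCoA treats eigenvalues below `1e-9 * max` as null; TVE requires at
  least one positive eigenvalue and errors otherwise.
* PERMANOVA permutes within fixed label slots, recomputing only the
  within-group sum; p is `(1 + #{F* >= F}) / (1 + n_perm)`.
* Constant genera have undefined correlation: flagged, excluded from
  testing, never silently zeroed.
* Greedy modularity requires strict gain (`> 1e-15`) to merge, so
  floating-point ties cannot reorder the deterministic scan.
* The IRLS fit rejects rank-deficient designs naming the aliased columns,
  and reports `converged` rather than failing silently.

Problem sizes in the test and acceptance suites are chosen for a laptop
run: oracle-equivalence fixtures use ≤ 10 samples, the PERMANOVA type-I
suite runs 1,000 exchangeable datasets of n = 20 at 199 permutations, the
entropy null 50 replicates of 40 × 100, GLM recovery n = 2,000, and the
planted-signal influence suite 20 replicates of a 30 × 10 cohort. The whole
suite completes in well under a minute; the acceptance script, which also
runs the full default cohort with 9,999-permutation PERMANOVA, in under a
minute.

## Known limitations

* Spearman correlation on relative abundances is not
  compositionality-aware; with few taxa, closure effects bias correlations
  negative (see above). SparCC-style estimators are out of scope by design.
* The core definition is threshold-based and sensitive to category sample
  size (an 8-sample category quantizes prevalence coarsely).
* Quasi-Poisson on library-size-driven biomass yields very large
  dispersions when depth is lognormal; coefficients remain interpretable
  but the mean–variance relationship is closer to log-normal than Poisson.
* The influence statistic measures impact on variance concentration (TVE),
  not on any particular axis or grouping; a genus can be influential by
  either adding or destroying structure, which is why the sign is kept.
* PERMANOVA assumes exchangeability under the null; with strongly unequal
  group dispersions its rejection can reflect dispersion, not location.
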