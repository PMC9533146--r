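# dmftmicro

Oral microbiota dynamics along the DMFT caries severity index.

## What this package is for

Dental caries is scored macroscopically with the DMFT index — the count of
**d**ecayed, **m**issing (due to caries) and **f**illed **t**eeth, binned
into five severity categories: healthy (0), low (1–3), medium (4–6), high
(7–13) and extremely high (≥ 14). For cohorts profiled by 16S amplicon
sequencing of saliva (the motivating setting is caries in people living
with HIV in resource-limited clinics), `dmftmicro` asks whether the
community carries a signal along that clinical axis, via five linked
analyses over a sample × taxon count table, a taxonomy, clinical metadata
and a phylogenetic tree:

1. **Diversity & ordination** — observed richness and Shannon entropy
   (nats), rarefaction; Bray–Curtis, Jensen–Shannon and weighted/unweighted
   UniFrac distances; PCoA with **TVE**, the fraction of positive
   ordination variance in the first five principal coordinates
   `TVE = Σ_{i≤5} max(λ_i,0) / Σ_i max(λ_i,0)`; and PERMANOVA
   (pseudo-F, R², permutation p with the +1 convention).
2. **Pan / core / accessory partition** — per category, the pan microbiota
   (taxa seen at least once), the core (prevalence ≥ 0.85, inclusive), the
   accessory `= pan \ core`, and the **DMFT core**, the intersection of
   per-category cores; plus richness proportions against editable
   normal-flora and disease-associated genus lists.
3. **Co-occurrence networks** — genus-level Spearman correlation with
   BH-FDR adjusted significance, pruning at |ρ| > 0.5 (strict; significance
   is an edge attribute, not a filter), deterministic greedy-modularity
   communities, degree-centrality ranking, and the **entropy statistic**:
   the fraction of associations that are significant (a high fraction =
   non-random, low-entropy community structure).
4. **Influence analysis** — leave-one-genus-out **ΔTVE**: drop each
   candidate genus (column and tree leaf), recompute weighted-UniFrac PCoA
   from scratch, and report `tve_without − baseline` per genus, optionally
   annotated by oxygen-utilization class.
5. **Biomass models** — per-category quasi-Poisson regression (log link,
   free dispersion φ = Pearson χ²/(n−p), SEs scaled by √φ) of total
   microbial abundance on sex, HIV status, periodontal status and
   family-level abundances, with an aligned cross-category comparison
   table.

A **synthetic cohort generator** (Dirichlet-multinomial with planted core/
accessory structure, latent-factor correlations, covariate effects on
biomass and a ground-truth record) makes every stage testable without any
sequence download, and a config-driven `run_pipeline()` orchestrates the
whole analysis deterministically.

## Worked example

```r
library(dmftmicro)

# a standard synthetic cohort: 88 samples, 5 DMFT categories, planted core
ds <- generate_dataset(synthetic_design(seed = 1))
ft <- filter_by_depth(ds$table, 3000)
ft
#> <feature_table> 83 samples x 165 taxa; total count 2,477,484

md <- ds$metadata[ds$metadata$sample_id %in% sample_ids(ft), ]
part <- partition_by_category(ft, md, prevalence_threshold = 0.85)
part
#> <partition_result> prevalence threshold 0.85
#>   healthy         n=10  pan=80   core=65   accessory=15
#>   low             n=30  pan=82   core=65   accessory=17
#>   medium          n=20  pan=82   core=65   accessory=17
#>   high            n=15  pan=81   core=65   accessory=16
#>   extremely_high  n=8   pan=79   core=65   accessory=14
length(dmft_core(part))
#> [1] 65

d <- unifrac(ft, ds$tree, weighted = TRUE)    # normalized weighted UniFrac
ord <- pcoa(d)
ord
#> <ordination_result> 83 samples, 50 positive axes; TVE(5) = 0.639

groups <- as.character(md$dmft_category)[match(sample_ids(ft), md$sample_id)]
permanova(d, groups, n_perm = 9999, seed = 1)
#> PERMANOVA: pseudo-F = 1.0164, R2 = 0.0495, p = 0.4189 (9999 permutations)

ids <- md$sample_id[md$dmft_category == "low"]
sp <- spearman_matrix(feature_table(ft$counts[ids, , drop = FALSE]))
g <- build_graph(sp$rho, sp$p, rho_threshold = 0.5, alpha = 0.05,
                 category = "low")
g
#> <cooccurrence_graph> [low] 165 genera, 205 edges (|rho| > 0.50), 175 significant
entropy_statistic(g)
#> [1] 0.8536585
```

Reading the output: 83 of 88 simulated samples pass the 3,000-read filter;
every category recovers the 65 planted core genera exactly (so the DMFT
core is 65 and the accessory counts are the per-category pan minus 65);
the five-axis TVE of the weighted-UniFrac ordination is 0.639; PERMANOVA
finds no DMFT clustering in this unsignalled cohort (R² ≈ 0.05, p ≈ 0.42),
as it should; and in the low category 85% of the retained co-occurrence
associations are FDR-significant — a strongly non-random (low-entropy)
community, driven by the generator's latent factors.

The one-command version of all of the above, with per-stage TSV/JSON
artifacts and a provenance-stamped `summary.json`:

```r
run_pipeline(pipeline_config(seed = 1), "out/")
```

or from a shell: `Rscript inst/scripts/dmftmicro.R run --out out --seed 1`.

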