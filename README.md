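# rarebiome

Comparative biogeography of **abundant and rare taxa** in regional microbial
community surveys, as an end-to-end, reproducible R pipeline. It is written
for microbial ecologists who have a rarefied OTU table (samples × OTUs),
per-sample environmental metadata and (optionally) a phylogeny over the
OTUs, and who want the full battery of analyses this literature runs on
abundant/rare subcommunities:

1. **Rarity classification** — every OTU is placed in one of six categories
   from the per-sample minimum *m* and maximum *M* of its relative
   abundance, with abundant meaning ≥ 1% and rare meaning < 0.01%:
   always abundant (AAT, *m* ≥ 1%), conditionally abundant
   (CAT, *m* ≥ 0.01% with *M* ≥ 1%), moderate (MT, always in between),
   conditionally rare (CRT, *m* < 0.01%, *M* < 1%), always rare
   (ART, *M* < 0.01%) and conditionally rare and abundant
   (CRAT, *m* < 0.01% with *M* ≥ 1%). Abundant taxa AT = AAT ∪ CAT, rare
   taxa RT = ART ∪ CRT.
2. **Diversity and niche breadth** — richness, Shannon H (nats),
   Bray–Curtis and Jaccard dissimilarities, Levins niche breadth
   B = 1/Σqᵢ², Mann–Whitney group tests with compact letters.
3. **Biogeography** — haversine geographic distances, log(x+1)+z
   environmental distances, distance–decay regressions of similarity
   (1 − Bray–Curtis) with a sample-jackknife slope CI, Mantel and partial
   Mantel tests (Spearman, permutation), iterative VIF screening,
   db-RDA with forward selection, and variation partitioning into pure
   environmental / pure geographic / shared / residual adjusted-R²
   fractions.
4. **Community assembly** — the nearest taxon index
   NTI = −(MNTD_obs − mean MNTD_null)/sd MNTD_null under a tip-shuffle
   null (NTI > 2 ⇒ phylogenetic clustering / determinism), and the
   normalized stochasticity ratio NST ∈ [0, 1] under a
   proportional-occupancy, fixed-richness (PF) null — NST = D/E when
   D < E, (1−D)/(1−E) otherwise — with 0.5 as the
   deterministic/stochastic boundary.
5. **Co-occurrence networks** — Spearman edges (|ρ| > 0.6 and BH-FDR
   q < 0.01), per-category edge blocks, centralities, small-world and
   scale-free diagnostics against Erdős–Rényi references, Louvain modules
   ranked by mean relative abundance, TMM-CPM normalization and
   module–environment regressions, GraphML export.
6. **Synthetic data with ground truth** — a community generator with
   known assembly regime (environmental filtering on phylogenetically
   autocorrelated niche optima, dispersal limitation, planted co-occurrence
   modules), used by the validation suite to show each statistic recovers
   the mechanism it targets.

Everything is seeded: a pipeline rerun with the same configuration is
byte-identical.

## Worked example

```r
library(rarebiome)

sim <- generate_community(scenario_config(n_otus = 400, depth = 20000, seed = 1))
sim$table
#> OTU table: 36 samples x 400 OTUs (with taxonomy)
#> total counts: 720,000; per-sample depth range: 20000-20000

rel <- to_relative_abundance(sim$table)
summarize_classification(classify_otus(rel))
#>  group     level   n percent
#>    AAT  category  10    2.50
#>    CAT  category  31    7.75
#>    ART  category  32    8.00
#>    CRT  category 199   49.75
#>     MT  category 128   32.00
#>   CRAT  category   0    0.00
#>     AT aggregate  41   10.25
#>     RT aggregate 231   57.75
#>     MT aggregate 128   32.00
#>   CRAT aggregate   0    0.00
#>  total     total 400  100.00
```

Ten OTUs stay at ≥ 1% in every sample (AAT) while 231 of 400 are rare taxa
— the long-tailed structure typical of rarefied field surveys (the larger
the pool, the more extreme the rare fraction; the 2000-OTU default exceeds
90% RT). This community was generated with moderate environmental filtering
and dispersal limitation, and the downstream statistics see both mechanisms:

```r
nst(sim$table, metric = "bray", n_null = 200, seed = 1)$nst_mean
#> NST (Bray-Curtis) group mean: 0.841      # mostly stochastic at these strengths

fit <- ddr_fit(bray_curtis(sim$table), geographic_distance(sim$metadata))
#> DDR slope: -3.06e-04 per km (95% CI -3.26e-04 to -2.86e-04), r2 = 0.94
```

Similarity decays significantly with distance (negative slope, CI excluding
zero). The full pipeline — classification, diversity, biogeography, assembly
and networks, written as a directory of TSV/GraphML report tables — runs as:

```r
cfg <- pipeline_config(sim$table, sim$metadata, sim$tree, outdir = "report")
run_pipeline(cfg)
```

See the methods vignette (`vignettes/rare-taxa-biogeography.Rmd`) for the
models, null-model details and design decisions.

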