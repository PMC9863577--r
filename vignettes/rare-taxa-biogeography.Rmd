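---
title: "Methods: biogeography of abundant and rare microbial taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biogeography of abundant and rare microbial taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions behind
`rarebiome`, in the spirit of the long-form methods vignettes of vegan or
DESeq2. The package analyses the comparative biogeography of abundant versus
rare taxa in regional amplicon surveys: which taxa are consistently abundant
or rare, how community similarity decays with geographic and environmental
distance, whether assembly is dominated by deterministic selection or by
stochastic processes, and how taxa co-occur in correlation networks.

## The occupancy-abundance classification

Every analysis starts from a rarefied OTU table converted to relative
abundances. An OTU's per-sample minimum `m` and maximum `M` relative
abundance place it in exactly one of six categories, with an *abundant*
threshold of 1% (closed bound, `>=`) and a *rare* threshold of 0.01% (open
bound, `<`):

| category | condition |
|---|---|
| AAT always abundant | `m >= 1%` |
| CAT conditionally abundant | `m >= 0.01%` and `M >= 1%` (not AAT) |
| MT moderate | `0.01% <= m`, `M < 1%` |
| CRT conditionally rare | `m < 0.01%`, `0.01% <= M < 1%` |
| ART always rare | `M < 0.01%` |
| CRAT conditionally rare and abundant | `m < 0.01%`, `M >= 1%` |

Abundant taxa (AT) are AAT plus CAT; rare taxa (RT) are ART plus CRT. CAT is
defined by "never below the rare threshold" in *all* samples: the six
regions of the (m, M) plane then tile it completely, so the assignment is a
partition — the common looser phrasing "in most samples" does not yield one.
Summary percentages are rounded half-up to two decimals, the convention of
published category tables. An OTU absent from every sample has `m = M = 0`
and falls in ART.

```{r}
rel <- to_relative_abundance(rarefy(table, depth = 20000, seed = 1))
cl <- classify_otus(rel)             # 1% and 0.01% defaults
summarize_classification(cl)
```

## Diversity and niche breadth

Alpha diversity is OTU richness and Shannon entropy in natural-log units
(the vegan convention). Beta diversity is Bray-Curtis on abundances and
Jaccard on presence/absence; "box-plot" beta diversity for a subcommunity is
the full set of its pairwise dissimilarities. Levins niche breadth for an
OTU with cross-sample abundance profile `q` (normalized to sum 1) is
`B = 1 / sum(q^2)`, ranging from 1 (single sample) to the number of samples
(perfectly even); it is reported per OTU, and group contrasts (e.g. AT vs
RT) use the per-OTU distributions rather than community-weighted means.
Group comparisons use the two-sided Mann-Whitney U test — exact when both
groups have at most 8 observations and no ties, otherwise the tie-corrected
normal approximation — with Benjamini-Hochberg adjustment across pairs and
an insert-absorb compact letter display at alpha = 0.05. The adjustment is a
package choice; sources that report such letters are typically silent about
multiplicity.

## Biogeography

Geographic distances are great-circle (haversine) distances on a 6371 km
sphere, in km. Environmental variables except pH are log(x+1)-transformed,
then all are z-standardized; environmental distance is Euclidean on the
retained variables.

Distance-decay relationships (DDR) regress community *similarity*
(1 − Bray-Curtis) on distance by OLS over all unordered pairs, so
dispersal-limited or environmentally filtered communities give negative
slopes. Two caveats are built in. First, the parametric p-value treats the
n(n−1)/2 pairs as independent, which they are not; it is reported for
comparability, but `ddr_fit` also returns a leave-one-*sample*-out jackknife
confidence interval for the slope, which is the package's preferred
inferential statement (under exchangeable samples it has close to nominal
coverage, while the parametric interval is anti-conservative). Second,
permutational inference for distance matrices is delegated to the Mantel
machinery rather than to the regression.

Mantel and partial Mantel tests use Spearman correlation of the unfolded
distance vectors with simultaneous row/column permutation, one-sided
("greater"), `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)` — the vegan
conventions. Per-variable Mantel rows (the Table-2-style output of the
pipeline) use the Euclidean distance of one transformed variable at a time.

Collinearity screening iteratively removes the predictor with the largest
variance inflation factor (`1/(1−R²)` against the remaining predictors)
until all VIFs are at most 10, dropping the larger column index on ties;
perfect collinearity gives an infinite VIF and is removed first.

db-RDA (`vegan::capscale`) with forward selection adds, at each step, the
predictor with the best adjusted-R² gain whose marginal permutation test
(conditioned on the already-selected set) has p ≤ 0.05, and stops when no
candidate improves the adjusted R². The additional "global adjusted-R² cap"
of some forward-selection variants is deliberately not applied: with one
strong driver plus pure-noise covariates the global model's Ezekiel-adjusted
R² sits at or below the driver-only value up to sampling noise, so the cap
randomly blocks legitimate first steps; the permutation test already
controls the false-selection rate. Negative PCoA eigenvalues are handled by
capscale's standard bookkeeping (imaginary axes kept out of the constrained
solution); a Lingoes-type correction was considered and rejected as it
changes the response geometry for all methods downstream.

Variation partitioning computes Ezekiel-adjusted R² for db-RDA on the
selected environmental predictors, on the geographic representation, and on
both, and reports `env-only = R²(env+geo) − R²(geo)`, the symmetric
geographic fraction, `shared = R²(env) + R²(geo) − R²(env+geo)` (which may
legitimately be negative) and the residual; the four fractions sum to 1.
Geography is represented by latitude and longitude as two predictor columns:
with 12 sites the spatial eigenvector (dbMEM) basis would contribute at most
a handful of axes, and the two raw coordinates keep the partition
interpretable.

## Community assembly: NTI and NST

The nearest taxon index per sample is
`NTI = −(MNTD_obs − mean(MNTD_null)) / sd(MNTD_null)`, with MNTD the mean
patristic distance from each OTU present in the sample to its nearest other
present OTU (unweighted by default, matching the common `ses.mntd`
default; an abundance-weighted flag is provided). The null shuffles tip
labels across the OTUs of the analyzed table ("taxa.labels", delegated to
picante), with 999 randomizations by default. NTI > +2 indicates
phylogenetic clustering, i.e. deterministic selection on phylogenetically
conserved traits; samples with fewer than two OTUs or with zero null
variance (e.g. on a star phylogeny, where every shuffle gives the same
MNTD) are flagged undefined rather than given an arbitrary value.

The normalized stochasticity ratio compares each pair's observed
dissimilarity `D` (Bray-Curtis or Jaccard) with its null expectation `E`:

* selection toward similarity (`D < E`): `NST = D / E`;
* selection toward dissimilarity (`D > E`): `NST = (1 − D) / (1 − E)`;

clamped to [0, 1], so full determinism maps to 0, full stochasticity
(`D = E`) to 1, and the group mean sits below 0.5 when deterministic
processes dominate. The null model is "PF": each null sample keeps its
observed richness, draws taxa with *inclusion probability proportional to
regional occupancy frequency*, and allocates its reads multinomially in
proportion to regional relative abundances of the drawn taxa. The inclusion
probabilities are computed exactly (capped at 1 with iterative
redistribution) and realized by systematic PPS sampling over a randomized
item order. This matters: naive sequential weighted sampling without
replacement materially under-includes the highest-occupancy taxa, so null
pairs look far more dissimilar than data generated by a genuinely neutral
process and even neutral communities would be scored "deterministic". With
exact inclusion probabilities, taxa present in every sample remain present
in every null sample, and communities generated by the null model itself
score close to 1. The published NST framework defines several null variants;
PF is the one implemented here, and results are labelled with the null name
and null-model size (1000 draws by default).

## Co-occurrence networks

Edges are Spearman correlations between OTUs of the prevalence-filtered
table (detected in at least one fifth of samples, `ceiling(n/5)`), with
p-values from the t approximation on n − 2 degrees of freedom, ties handled
by average ranks, Benjamini-Hochberg FDR computed over the full family of
upper-triangle pairs, and retention requiring *both* |rho| > 0.6 *and*
q < 0.01. Constant OTUs have undefined correlations and are excluded with a
warning. Networks are built per organism with the rarity aggregate as node
attribute, and positive/negative edge counts are tabulated per
category-pair block.

Topology: average clustering coefficient (nodes of degree < 2 contribute
zero), average path length over the largest connected component, and Newman
modularity of the Louvain partition (resolution 1, fixed seed). Random
references are Erdős–Rényi G(n, m) ensembles with matched node and edge
counts. The scale-free diagnostic is the R² of the OLS fit of
log10(frequency) on log10(degree) over the integer degree distribution with
zero-frequency bins dropped; it is flagged undefined with fewer than three
distinct positive degrees. Degree, betweenness and per-component normalized
closeness come from igraph; eigenvector centrality is computed by power
iteration on A + I (tolerance 1e-10, at most 10⁴ iterations, scaled to
maximum 1) — the shift guarantees convergence on bipartite components where
the extreme adjacency eigenvalues tie in modulus.

Modules are ranked by the mean over samples of the summed relative
abundance of their members ("mean abundance"; the field's published usage is
ambiguous, and this reading weighs modules by the community fraction they
represent); the top four are flagged as major modules. Module-environment
regressions accumulate TMM-normalized CPM over each major module's members
within an aggregate (AT or RT) and regress that total on pH and MAT by OLS,
reporting slope, Pearson r and the parametric p with 0.05 as the
significance convention. TMM normalization is delegated to edgeR
(30% M-trim, 5% A-trim, inverse-asymptotic-variance weights, factors scaled
to geometric mean 1).

## The synthetic community generator

The generator produces the study conditions every validation runs on:
12 sites × 3 replicates on a 1000 × 1000 km landscape, a lognormal regional
pool (μ = 0, σ = 2 — a standard species-abundance model that makes rare
taxa dominate, with well over half of OTUs below 0.01% mean relative
abundance at the defaults), site gradients in MAT (6–14 °C) and pH
(6.5–8.5) aligned with the landscape axes, and multinomial sequencing at a
fixed depth (20000 by default; 2000 OTUs in the default pool, 400 in the
validation presets — 300 for the modular preset — so that full pipeline runs
stay in the minutes range; these sizes are the package's validation choices,
not estimates of any particular survey).

Mechanisms, each with a strength in [0, 1]:

* **Environmental filtering.** Each OTU has Gaussian niche responses on the
  standardized MAT and pH axes with Brownian-motion optima simulated on the
  generated birth–death phylogeny (birth 1.0, death 0.5, ultrametric), so
  optima are phylogenetically autocorrelated and strong filtering produces
  phylogenetically clustered communities by construction. Niche width is
  linked to pool abundance — abundant taxa are generalists (sd up to 2 z
  units), rare taxa specialists (down to 0.3) — for 80% of OTUs, with 20%
  decoupled at random: the link keeps always-abundant generalists ubiquitous
  (populating AAT and reproducing the broader niche breadth of abundant
  taxa), while the decoupled abundant specialists generate the
  conditionally-rare-and-abundant class. Strength up to 0.5 only sharpens
  selection; beyond 0.5 it also narrows all niches toward the specialist
  floor, so strength 1 approximates disjoint, clade-structured site pools.
  A side effect is that weak filtering (≲ 0.5) moves mainly rare
  specialists and is barely visible to abundance-weighted statistics — the
  NST trend over filtering strengths is monotone only up to Monte-Carlo
  noise in that regime.
* **Dispersal limitation.** Each OTU originates at a random site and its
  expected abundance decays exponentially with distance from the origin
  (e-folding 200 km at full strength), producing negative distance-decay
  slopes without any environmental signal.
* **Planted modules.** OTUs are assigned round-robin to K modules, and each
  module carries a lognormal (sd 1.5) per-site multiplier shared by its
  members, which induces strong within-module co-occurrence across the 12
  site profiles.

Every latent quantity (pool, optima, origins, module memberships and
profiles, site environments) is returned as a ground-truth record and can be
serialized beside the data. Regeneration from the same configuration is
bit-identical.

What the generator does *not* emulate: compositional coupling beyond the
multinomial constraint, sequencing error and chimeras, taxonomy assignment
error (lineages are synthetic, cut from the tree's clades), temporal
dynamics, and the interaction structure real networks inherit from ecology
rather than shared habitat preference. Passing the ground-truth recovery
suite therefore shows that each statistic responds to the mechanism it
targets under clean conditions — not that it is unbiased on real data.

Four seeded presets fix the validation conditions: `neutral` (both
strengths 0 — exchangeable multinomial draws from one pool), `filtered`
(filtering 1), `dispersal_limited` (dispersal 1) and `modular` (four planted
modules, no filtering or dispersal).

## Numerical and reproducibility choices

* One master seed per pipeline run; every stochastic stage (rarefaction,
  permutation tests, null models, Louvain, random references) uses a stream
  derived from it by fixed offsets, and reruns are byte-identical.
* Null-model sizes: 999 (Mantel, NTI), 1000 (NST), 100 (random graph
  references) by default; the validation suite and the bundled acceptance
  script use 199–200 where full defaults would add minutes without changing
  any decision boundary.
* Percentages round half-up; all thresholds are applied with the closed /
  open conventions stated above; ties in VIF dropping go to the larger
  column index; Louvain uses resolution 1.
* Degenerate inputs are flagged, not silently patched: all-zero samples,
  constant OTUs, star-tree null distributions with zero variance, and
  module-aggregate cells without members are reported as warnings, errors
  or explicit `undefined` flags as documented on each function.

## Known limitations

* The DDR parametric p-value ignores pair dependence (by design, for
  comparability); use the jackknife interval or the Mantel test for
  inference.
* NST is reported for the PF null only; other occupancy/abundance null
  variants can rank regimes differently.
* With 12 sites, the geographic representation in variation partitioning
  (latitude + longitude) captures only broad-scale spatial structure.
* The compact letter display reflects BH-adjusted pairwise decisions; with
  many groups it can be conservative.
* Spearman co-occurrence on relative data is not compositionally aware;
  SparCC-style inference is out of scope.
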