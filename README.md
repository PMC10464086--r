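# sedistrat

Depth-resolved analysis of microbial community assembly in dated,
dam-impacted lake sediment cores.

Damming changes a lake abruptly: sedimentation accelerates, nutrients
accumulate, and the sediment column preserves that history as a
stratigraphic horizon. `sedistrat` implements the quantitative stack used
to ask *how* such a horizon restructures the buried microbial
metacommunity: sediment interstitial-space physics, depth-profile
community statistics, phylogenetic null-model partitioning of assembly
processes, niche-breadth profiling, and a random-forest screen for
damming-sensitive taxa — plus a synthetic stratified-core generator with
known ("planted") assembly regimes so every stage can be validated end to
end. It is written for microbial ecologists and biogeochemists working
with OTU/ASV tables, phylogenies and core metadata.

## What it computes

**Sediment physics.** From paired water-content measurements, the
gas-space volume fraction of a layer

> VP(a) = 1 − (Moi(v) · ρ(w)) / (Moi(m) · ρ(w&s))

where Moi(v) = V(w)/V(T) is in-situ volumetric water content, Moi(m) =
M(w)/(M(w)+M(s)) mass water content from drying, ρ(w) pore-water density
and ρ(w&s) the density of the degassed water–solid mixture (submerged
weighing, so its volume basis excludes gas). Total interstitial space is
TIS = Moi(v) + VP(a). A piecewise-linear age–depth model over dated
anchors yields interpolated ages and mean deposition rates.

**Community structure.** Rarefaction, Chao1 (bias-corrected) and Pielou
evenness, Bray–Curtis and binary-Jaccard dissimilarities, PCoA, UPGMA
layering with ANOSIM, Baselga's abundance-based multiple-timepoint
dissimilarity (balanced-variation vs abundance-gradient partition), and
OTU–layer connection degrees (log10 abundance ≥ 1).

**Assembly processes.** Abundance-weighted βMNTD with a tip-shuffling
null gives βNTI; the Bray–Curtis-based Raup–Crick metric (RC_bray)
compares observed dissimilarity to richness- and abundance-preserving
null assemblies. Pairs are partitioned: βNTI > 2 heterogeneous selection,
βNTI < −2 homogeneous selection, and for |βNTI| < 2, RC > 0.95 dispersal
limitation, RC < −0.95 homogenizing dispersal, otherwise ecological
drift. `adjacent_layer_profile()` traces these metrics across every
layer boundary.

**Niche breadth.** Levin's B_j = 1/Σ P_ij² per taxon, the
abundance-weighted community mean B̄_i per layer, and its quadratic depth
fit (vertex = the generalist bulge of a transition zone).

**Damming-sensitive taxa.** An ensemble of random forests classifies
pre- vs post-horizon samples; pooled mean-decrease-Gini importances are
segmented by optimal (dynamic-programming) breakpoints, and the taxa
ahead of the first breakpoint form the sensitive set. Unsupervised RF
clustering cross-checks the two-layer structure without labels.

## Worked example

Simulate a dated 8-layer core sampled in 3 seasons with a damming horizon
after layer 4 — selection-structured above, dispersal-limited below — and
run the core stages:

```r
library(sedistrat)

cfg <- generator_config(n_taxa = 300, n_layers = 8, n_seasons = 3,
                        damming_layer = 4, library_size = 4000, seed = 7)
ds <- generate_dataset(cfg)

prof <- physics_profile(ds$physics)
aggregate(cbind(vp, tis) ~ layer, prof, mean)
#>   layer    vp   tis
#> 1     1 0.000 0.900
#> 4     4 0.000 0.771
#> 5     5 0.045 0.729
#> 8     8 0.040 0.600

adjacent_layer_profile(ds$counts, ds$tree, mode = "merged",
                       n_null_bnti = 199, n_null_rc = 999, seed = 7)
#>  boundary  bnti   rc                 process
#>       1-2  0.02 0.15                   drift
#>       2-3  4.62 0.66 heterogeneous_selection
#>       3-4  2.99 0.81 heterogeneous_selection
#>       4-5  7.01 1.00 heterogeneous_selection
#>       5-6 -0.15 1.00    dispersal_limitation
#>       6-7 -0.56 1.00    dispersal_limitation
#>       7-8  0.54 1.00    dispersal_limitation
```

Free gas (VP(a) > 0) appears only below the horizon; βNTI spikes to 7.0
*at* the horizon (deterministic turnover where the environment steps) and
falls inside ±2 below it, where RC_bray = 1 flags dispersal limitation —
exactly the planted regime structure. The niche profile tells the same
story from a different angle:

```r
mm  <- merge_seasons(rarefy(ds$counts, seed = 7))
fit <- fit_mnb_depth(mean_niche_breadth(mm, levins_breadth(mm)))
#> MNB by layer: 1.04 1.08 1.14 1.12 1.68 1.51 1.53 1.38
```

Mean niche breadth jumps from ~1.1 (layer-specialists under strong
selection) to ~1.5 below the horizon, where turnover is stochastic.

`run_pipeline()` orchestrates all stages on generated or on-disk inputs
and writes every table, a `summary.json` and a `provenance.yaml` that
reproduces the run bit-for-bit; `inst/scripts/run-pipeline.R` wraps it
for the shell.

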