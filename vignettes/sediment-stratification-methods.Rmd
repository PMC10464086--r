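---
title: "Models and methods for stratified-sediment community assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for stratified-sediment community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sedistrat` analyses depth profiles of microbial communities in dated
lake-sediment cores, with a focus on systems where a historical event —
dam construction is the motivating case — left a stratigraphic horizon
that separates two regimes of community assembly. This vignette explains
the models behind each stage, the tunable parameters and their defaults,
the design choices made where the design was genuinely open, and what the
synthetic-data generator does and does not emulate.

## Interstitial-space physics

A sediment layer of total volume $V_T$ holds solids $V_s$, pore water
$V_w$ and free gas $V_a$ (in organic-rich lake sediments, predominantly
methane bubbles). Two water contents are measured on different bases: the
in-situ volumetric content $Moi_v = V_w / V_T$ (sensor, gas-inclusive
volume) and the mass content $Moi_m = M_w / (M_w + M_s)$ (oven drying).
The mixed-sediment density $\rho_{w\&s}$ is obtained by submerged
weighing of the degassed sample, so its volume basis is $V_w + V_s$.
Under these conventions

$$VP_a \;=\; 1 - \frac{Moi_v\,\rho_w}{Moi_m\,\rho_{w\&s}}
       \;=\; 1 - \frac{V_w + V_s}{V_T} \;=\; \frac{V_a}{V_T},$$

and the total interstitial space is $TIS = Moi_v + VP_a$. The volume
basis of $\rho_{w\&s}$ is load-bearing: if all quantities were measured
on the same gas-inclusive volume the ratio would be identically one and
the formula would carry no information. `gas_volume_percent()` is tested
against a forward-construction oracle that builds consistent
measurements from arbitrary $(V_w, V_s, V_a)$ triples and checks exact
recovery of $V_a / V_T$.

Measurement noise can push the raw value slightly negative in saturated
layers; because the quantity is a volume fraction, negative values are
clamped to zero and flagged (`physics_profile()` records per-row flags
instead of raising warnings). Raw values above one are impossible for
valid inputs and are treated as errors.

The age–depth model is piecewise linear through dated anchors (surface at
the sampling year, a radionuclide peak, a basal date). Depths below the
deepest anchor are extended at the terminal segment's rate — the simplest
defensible extension, and the one that keeps deposition-rate estimates
segment-wise constant. `deposition_rate()` is pure anchor arithmetic:
with anchors (0 cm, 2015), (21.4 cm, 1963), (55 cm, 1709) it returns
0.41 cm yr⁻¹ above the 21.4 cm horizon and 0.13 cm yr⁻¹ below it, a
greater-than-twofold post-damming acceleration.

## Community statistics

All community statistics operate on a `community_matrix` (taxa × samples
with layer and season labels) and, following standard practice, on
counts rarefied to the minimum sample total (`rarefy()`, seeded,
without replacement). Choices worth stating:

* **Chao1** uses the bias-corrected form
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ so that zero doubletons remain
  defined. **Pielou** is $H/\ln S_{obs}$ (natural log), reported as
  missing when $S_{obs} \le 1$.
* **Dissimilarities** default to counts after rarefaction; a `relative`
  flag switches Bray–Curtis to relative abundances. Binary Jaccard is
  $1 - |A \cap B| / |A \cup B|$.
* **PCoA** reports negative eigenvalues as they arise (no Lingoes or
  Cailliez correction); proportions explained are computed over the
  positive part only and the negative mass is returned alongside, so the
  user sees exactly how non-Euclidean the input was.
* **UPGMA** sorts samples lexicographically before agglomeration so ties
  in merge heights resolve deterministically; reported node heights use
  the ultrametric-tree convention (half the cophenetic dissimilarity).
* **ANOSIM** uses 999 permutations by default and the add-one rule
  $p = (\#\{R_{perm} \ge R\} + 1)/(n_{perm}+1)$; the permutation stream
  is seeded. Under the null its p-values are uniform (tested by a
  Kolmogorov–Smirnov check over 200 synthetic replicates).
* **Seasonal fluctuation** of a layer is Baselga's abundance-based
  multiple-site dissimilarity over its seasonal snapshots, partitioned
  into balanced-variation and abundance-gradient components. The
  implementation is written directly from the pairwise
  $\min/\max$ formulas (no dedicated package for this partition is a
  dependency) and is oracle-tested, including the exact $n=2$ reduction
  to pairwise Bray–Curtis.
* **Connection degree** applies the inclusive threshold
  $\log_{10}(x) \ge 1$, i.e. abundance ≥ 10, per taxon and layer on the
  seasonally merged matrix.

## Phylogenetic null models

For a community with patristic distance matrix $d$, MNTD is the
(abundance-weighted, by default) mean distance of each present taxon to
its nearest present neighbour; βMNTD is the between-community analogue,
where a taxon shared by both communities has nearest distance zero. The
unweighted variant averages the two directed means (mean-of-means, not a
pooled mean over all taxa). Standardized effect sizes against tip-label
randomization give NTI and βNTI:

$$\beta NTI = \frac{\beta MNTD_{obs} - \overline{\beta MNTD_{null}}}
  {sd(\beta MNTD_{null})}.$$

Null-model design choices:

* The randomization pool is **all tips of the supplied distance matrix**
  (metacommunity-wide shuffle); a `pool_present` flag restricts the
  shuffle to taxa present in the compared communities.
* Each βNTI replicate draws **one** permutation and applies it to both
  communities. This preserves the shared-taxon structure under the null:
  a taxon present in both communities remains shared after relabelling,
  so the SES is driven by the placement of non-shared taxa — without
  this, any pair with substantial overlap would be spuriously
  "clustered".
* Defaults are 999 randomizations for NTI/βNTI and 9999 for RC_bray,
  both overridable for desk-scale work.
* When the null distribution has zero variance (e.g. perfectly symmetric
  trees, or pairs sharing every taxon) the SES is undefined: the
  functions return `NA` with a warning, and `partition_processes()`
  leaves such pairs unclassified rather than inventing a label.
* Taxa present in the counts but absent from the tree are an error, not
  a silent drop.

RC_bray compares the observed Bray–Curtis dissimilarity (on relative
abundances) of a pair to dissimilarities of null pairs that preserve
each sample's richness and total abundance: taxa are drawn without
replacement with probability proportional to occurrence frequency in the
metacommunity, and remaining individuals are assigned proportionally to
metacommunity relative abundance. Ties count at half weight (mid-P), and
the rank probability is mapped onto $[-1, 1]$. Under self-generated
nulls the metric is calibrated: $|RC| > 0.95$ corresponds to a mid-P
outside $[0.025, 0.975]$ and therefore a ~5% two-tailed type-I rate
(±0.95 is the conventional 0.05-level cutoff for this metric), which is
what the calibration experiment in `scripts/acceptance.R` measures.

The five-way partition applies, per pair: βNTI > 2 heterogeneous
selection; βNTI < −2 homogeneous selection; otherwise RC > 0.95
dispersal limitation, RC < −0.95 homogenizing dispersal, $|RC| \le 0.95$
ecological drift. Fractions are reported over classified pairs.

Two sample treatments are supported by `adjacent_layer_profile()`:
per-season snapshots and seasonally merged layers. Pooling seasons before
computing βNTI is a *different estimator* (it averages out seasonal
turnover and multiplies read depth), and the two treatments can
legitimately disagree; the package reports both and asserts no direction
for their difference. Zone-level process fractions, when a core is split
into an above- and a below-horizon zone, are computed over **all**
within-zone pairwise comparisons with the full system as the Raup–Crick
metacommunity pool — nearest-taxon effect sizes saturate for single
adjacent pairs at small environmental contrast, whereas the all-pairs
fractions are the quantity the two-zone summary actually describes.

## Niche breadth

Levin's breadth of taxon $j$ over $N$ layers is
$B_j = 1 / \sum_i P_{ij}^2$ with $P_{ij}$ the share of the taxon's total
abundance in layer $i$; the community mean is
$\bar B_i = \sum_j Q_{ij} B_j$ with within-layer relative abundances
$Q_{ij}$. Because every $B_j \ge 1$, any abundance-weighted mean of them
is also $\ge 1$; MNB is therefore asserted to lie in $[1, N]$ even
though a lower bound of 0 is sometimes quoted for it. MNB is computed on
seasonally merged matrices by default (per-season profiles are obtained
by slicing). The quadratic OLS fit of MNB against layer index summarizes
the generalist bulge expected at an ecotone-like transition; its vertex
is the stationary layer.

## Damming-sensitivity screen

The screen follows the ensemble design of replicated random forests: 100
forests (1000 trees each by default; 2000 are appropriate for
class-rank features) classify pre- vs post-horizon samples from
per-sample relative abundances, typically aggregated to phylum or class
rank with `aggregate_taxa()`. Per-forest mean-decrease-Gini importances
are pooled by their arithmetic mean — combining forests is
order-insensitive, and the mean is the order-free pooling — and accuracy
is summarized by the mean out-of-bag error. Class imbalance (more
post- than pre-horizon layers, or vice versa) is handled by a stratified
per-tree bootstrap downsampled to the minority class; a flag disables
it. Other hyperparameters stay at the field's defaults
($\sqrt{p}$ features per split, unlimited depth).

The ranked importance curve is segmented by exact dynamic-programming
least squares with a minimum segment length of 2, the number of breaks
chosen by BIC up to `max_breaks`. Segments are piecewise-constant by
default; a `segment = "linear"` flag fits sloped segments instead — the
constant model asks "where does the importance level drop", which is the
question the sensitive-taxon cutoff poses, but the choice is exposed
rather than asserted. Taxa ranked before the first breakpoint form the
selected set. The DP is oracle-equivalent to exhaustive enumeration for
$n \le 12$ (tested).

Unsupervised validation trains a forest to separate the real samples
from a synthetic contrast class drawn from the product of feature
marginals, converts co-leaf proximities to distances, and cuts an
average-linkage tree at $k = 2$; agreement with the UPGMA split supports
the two-layer reading without using the labels.

## The synthetic-core generator

`generate_dataset()` emulates the *processed* data structure of a
bimonthly-sampled, 11-layer dam-impacted core: a coalescent phylogeny,
a lognormal species-abundance distribution, a depth-indexed environment
with a step at the damming horizon, per-(layer, season) physics rows and
age anchors, and a truth table naming the regime of every adjacent-layer
pair. Key modelling decisions:

* **Selection** zones: expected relative abundance of taxon $j$ in layer
  $l$ is $sad_j \exp(-(E_l - o_j)^2 / 2\sigma^2)$ with optima $o_j$
  evolved by Brownian motion along the tree and mapped monotonically
  onto the environmental range, so filtering is phylogenetically
  conserved at every depth.
* **Dispersal-limited** zones: per-taxon log-suitability follows a
  stationary AR(1) across layers (`walk_rho = 0.15`, `walk_sd = 2`)
  around a zone baseline. A non-reverting lognormal walk was rejected:
  its variance grows with depth, collapsing per-layer richness, which
  widens the Raup–Crick null and inverts the metric's sign — the
  stationary walk keeps richness stable while decorrelating adjacent
  layers, which is the planted dispersal-limitation signature. When such
  a zone is entered across the horizon, its baseline is founded by a
  broad ($2.5\sigma$) filter at the stepped environment: the horizon
  flips the coarse habitat (redox state), admitting a guild, after which
  drift dominates.
* **Neutral** zones: flat responses, i.e. the bare abundance
  distribution.
* Units: the environment is measured in niche tolerances ($\sigma = 1$).
  Adjacent layers differ by `gradient_per_layer = 4` tolerances within a
  selection zone — strongly stratified geochemical transitions — and the
  horizon adds `effect_size = 6`, so the step is the largest single
  contrast in the profile, as a dam-scale perturbation should be.
* Each seasonal sample multiplies the layer expectation by lognormal
  jitter (`seasonal_noise = 0.4`) and draws `library_size` reads
  (default 50 000, the order of a rarefied amplicon library)
  multinomially. An optional `dropout` list emulates incomplete designs.
* Physics rows are built from first principles on a unit volume with
  porosity declining 0.9 → 0.6 down-core; layers above the horizon are
  saturated, layers below carry a planted 2–8% gas fraction, so the
  geophysics stage must recover exactly the planted values.
* One master seed derives per-stage sub-streams, making every table
  bit-reproducible and stages independently reproducible.

What the generator does **not** emulate: sequence-level error and
chimeras (generation starts at the OTU table), taxonomy (the
sensitivity screen runs on OTU-level features unless a taxonomy map is
supplied), horizontal spatial replication, compositional covariance
between physics and counts beyond the shared horizon, and real-data
features such as overdispersed libraries or contaminant lineages.
Passing the recovery tests therefore demonstrates that the estimators
detect the processes they target under a faithful but idealized
stochastic model — not that any particular field system will show the
same effect sizes.

## Problem sizes, tolerances and degenerate inputs

The validation suite runs at deliberately reduced sizes chosen to keep
the statistical properties intact: null-model calibration uses 200
replicates at 199 (βNTI) and 999 (RC) randomizations on a 100-tip tree;
regime recovery uses 20 synthetic cores of 400 taxa × 10 layers × 2
seasons at 5 000 reads with 199/399 randomizations. Exact identities are
asserted at machine precision (gas-volume oracle, MNTD brute force,
multiple-site $n=2$ reduction at $10^{-12}$); stochastic recoveries at
the 70% seed-majority level. Degenerate inputs are handled explicitly:
zero-variance nulls return flagged `NA`s, all-zero taxa are excluded
from niche breadth with a warning, empty layers and singleton ANOSIM
groups are errors, and rarefaction names the sample that is too shallow.

## Known limitations

* βNTI assumes the phylogeny carries niche information; on trees without
  signal the selection classes lose meaning (the generator's neutral
  regime exists precisely to test this direction).
* RC_bray inherits the usual sensitivity to the metacommunity
  delimitation; the pool is an explicit argument everywhere.
* The unsupervised RF step is a heuristic cross-check, not an inference
  procedure; no uncertainty is attached to its partition.
* The pipeline treats layers as independent strata; it does not model
  vertical mixing (bioturbation) or time-depth smearing.
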