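---
title: "Methods: drug-occupancy calling and spatial niche analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-occupancy calling and spatial niche analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cpibind` implements a set of bespoke computations for tracking
checkpoint-inhibitor (CPI) bound T cells in multimodal single-cell and
spatial transcriptomics data, together with synthetic-data generators that
carry ground truth so that every stage can be verified without access to
patient data. Five components are covered:

1. hashed-pool demultiplexing of CITE-seq data (CLR normalization,
   per-tag negative-binomial thresholds, doublet and negative calling);
2. a quantile-regression-forest (QRF) caller that flags drug-bound cells
   from the discordance between measured PD-1 antibody-derived-tag (ADT)
   signal and its model-predicted conditional distribution;
3. a distance-weighted, locally smoothed receptor-ligand (RL)
   co-localization score with a permutation null, empirical p-values and
   Benjamini-Hochberg (BH) FDR control;
4. spatial niches from adjacent-neighbor cell-type composition;
5. crypt-top cluster adjacency networks and cell-type co-occurrence
   networks.

# The occupancy caller

## Model

Nivolumab occupies the PD-1 epitope recognized by the competing CITE-seq
antibody clone, so drug binding suppresses the measured ADT signal while
leaving *PDCD1* transcription untouched. The caller exploits this
asymmetry. On cells from untreated donors only, a quantile regression
forest learns the conditional distribution of CLR-normalized PD-1 ADT
signal given covariates that carry no information about drug exposure:
embedding components, cell-cycle scores and phase, reaction, total counts,
gene detection rate, mitochondrial and ribosomal percentages, and
normalized *PDCD1* mRNA. For a treated cell with features `x` and measured
signal `y`, the conditional CDF value `u = F(y | x)` is the probability
that an unbound cell with the same covariates would show signal at or
below `y`. A cell is called bound at confidence `alpha` iff `u < alpha`.

The test is one-sided in the lower tail by design: competitive epitope
blocking can only reduce the measured signal, never raise it. This
direction is recorded in the fitted model object. Bound sets are nested
across `alpha` by construction, and the four default levels
(0.01, 0.05, 0.10, 0.15) correspond to thresholding the measured signal at
the 0.99/0.95/0.90/0.85 conditional quantiles.

## The forest as a conditional-distribution estimator

The forest itself is fitted with \pkg{ranger}; the quantile machinery is
implemented in this package. At training time the response values falling
into every terminal node of every tree are indexed; at prediction time the
conditional distribution at `x` is the across-tree average of the
empirical distribution of training responses sharing `x`'s leaf. This
yields conditional quantiles (by inverting the CDF on a grid of training
response quantiles, 257 points by default, which makes quantile curves
monotone in the level by construction), the conditional CDF at arbitrary
values (weak `<=` convention, so a measurement tied with the conditional
minimum gets `u > 0` and is not automatically bound), and conditional
sampling (tree chosen uniformly, then a leaf response uniformly).

Terminal nodes are kept relatively large (`min_node_size = 50` by
default). Fully grown regression trees choose splits that chase the
realized noise, which narrows the leaf response distributions and
mis-calibrates tail probabilities; leaves of several dozen observations
keep the leaf populations honest samples of the conditional law. This is
the one numerical choice that materially matters for calibration of the
`u < alpha` rule.

## Feature selection and validation

Candidate features are reduced by recursive elimination: fit a forest,
rescale permutation importances (negatives floored at zero) to sum to 100,
drop the weakest feature, refit, and stop when every remaining feature
exceeds the threshold (default 5, i.e., five percent of total importance;
the threshold's scale is defined by this rescaling). A non-positive
threshold keeps everything.

Training uses untreated-donor cells only. One untreated donor is held out
entirely as an independent validation set and a random third of the
remaining untreated cells as a standard hold-out; on both, the Pearson
correlation between the conditional median and the measured signal is
reported and flagged if it falls below a configurable floor.

## Per-cluster bound fractions and their intervals

The per-cluster point estimate is the fraction of cells called bound at
`alpha`. The interval is *not* a binomial interval: in every Monte-Carlo
draw each cell's hypothetical measurement is resampled from its predicted
conditional distribution and re-called, and the 2.5/97.5 percentiles of
the resulting cluster fractions form the band. Because the conditional
law is discrete over the training responses, the per-draw re-call of a
cell is exactly Bernoulli with probability `P(F(Y*|x) < alpha)`, which the
implementation computes in closed form from the leaf index instead of
re-evaluating the forest per draw. The band is therefore the
model-implied range the cluster fraction would take if measurements were
regenerated under the drug-free conditional law — a reference band that
sits near `alpha` for every cluster and quantifies the calling noise
floor, not the sampling error of the point estimate.

# Hashed-pool demultiplexing

Tag counts are CLR-normalized per cell over the tag panel (natural log,
pseudocount 1), partitioned by clara k-medoids with `k = n_samples + 1`
(one cluster per sample plus one for negatives), and, for each tag, a
negative binomial is fitted to the *raw counts* of the tag's negative
population — thresholding a count distribution requires the count scale.
The negative population is every cluster whose mean CLR signal for the
tag falls in the lower half of the cluster-mean range: tag-positive and
tag-negative clusters separate by several CLR units, so the midpoint
splits them cleanly, and this rule is robust both to a sample being
split across two clusters (both halves stay excluded) and to the surplus
k-medoids cluster aligning with one tag's background noise tail (it is
pooled with the other negative clusters rather than fitted on its own,
either of which would bias the 99th-percentile threshold badly). The
positive threshold is the fitted distribution's 0.99 quantile by
default. Cells positive for exactly one tag are singlets, for two or
more are doublets, for none are negatives. If the negative population
holds fewer than 20 cells, all cells are used; an all-zero tag receives
an infinite threshold with a warning. The fitted parameters, thresholds and the
fit-scale convention are stored in the result object.

# The receptor-ligand co-localization score

For each location `i` the score is
`S_i = (sum_j d_ij L_j / n_i) * (sum_j d_ij R_j / n_i)`,
where the sums run over locations within the weight cutoff, `d_ij` is a
linear distance weight and `n_i` counts the locations with positive
weight. Dividing by `n_i` rather than the weight sum makes edge-of-tissue
locations comparable to interior ones. The formula is symmetric in ligand
and receptor.

Weights are `d = 1 - dist / (cutoff * (1 + 1e-6))`, 1 at the focal
location (the focal spot contributes: the smoothing exists because a
single spot under-detects), positive but tiny at the cutoff, 0 beyond.
The default cutoff is two lattice rings (`2 * pitch`), i.e., the two
immediately surrounding rings of a Visium array contribute, and on a hex
lattice an interior location has `n = 19`. Of the two readings of
"linear weight between 0 and 1" (unit weight at the focal spot vs at the
first ring), the focal-spot convention was chosen and is what
`compute_weights()` documents. Neighborhoods never cross slides. The
same operations serve segmented-cell data by passing a radius cutoff in
micrometers; surrounding cells then play the role of surrounding spots.

The null distribution shuffles the assignment of whole expression
profiles to coordinates within each slide (100 permutations by default)
and recomputes all scores. Shuffling profiles jointly preserves
gene-gene correlation, so a ligand and receptor co-expressed in the same
profile remain coupled under the null — only their *spatial* arrangement
is destroyed, which is precisely the hypothesis under test. Nulls are
pooled across locations into one empirical background per pair;
`p = (1 + #{null >= observed}) / (1 + N)` (the add-one correction keeps
p away from zero), BH correction is applied jointly across all
(location, pair) combinations, and positivity means FDR < 0.05.

Region- and condition-enrichment of scores uses a Gaussian linear model
`score ~ in_group + detection_rate` per pair and group, restricted to
pairs already positive somewhere in the tested group, with BH across
pairs x groups; blocking on per-location gene detection rate absorbs
permeabilization and recovery gradients. The model family is the
simplest member of the GLM class; scores are smoothed averages, so a
Gaussian error model is adequate.

# Niche, adjacency and co-occurrence analyses

**Neighbor composition.** For segmented-cell data, "immediately adjacent
neighbors" is operationalized as mutual k-nearest neighbors (k = 10) with
a 30 µm radius cap, per field of view, self excluded. A
triangulation-based (Delaunay) alternative was considered; no
triangulation backend is available to the package, so the kNN rule is the
single implemented convention and is recorded in the returned object.

**Niche clustering.** Composition rows are proportion-normalized,
projected on principal components and clustered by Louvain modularity
optimization at resolution 0.7, matching the resolution used for the
segmented-cell expression clustering this mirrors. The clustering graph
uses 50 nearest neighbors — larger than the 20 typical for expression
data on purpose: composition rows are small integer vectors, so many
cells share identical profiles, and if the graph neighborhood is smaller
than the typical duplicate-profile multiplicity, modularity optimization
returns one community per profile rather than one per niche.

**Crypt-top adjacency networks.** Spots with crypt-axis score above 1.0
(the score is consumed as an input column, not computed here) are
retained; per focal spot, adjacent spots are those with
`0 < dist < 4` in downscaled-image units; the per-spot cluster fractions
of adjacent spots are averaged over the focal spots of each source
cluster to give directed edge weights. Self-loops are kept, spots
without in-window neighbors contribute nothing, and when every neighbor
is labeled the outgoing weights of each node sum to one.

**Co-occurrence networks.** Within each condition, all pairwise Pearson
correlations of per-location cell-type probability scores are computed
(scores are consumed as input; deconvolution is out of scope); edges are
kept when positive, `r >= 0.15` and `p < 0.01` (t-distribution test),
diagonals dropped. Graph layout is a visualization concern and is left
to the caller.

# The synthetic-data generators

The generators define the conditions under which the package verifies
itself; their defaults are fixed and the verification suite does not
tune them.

**CITE-seq generator.** Each cell draws a latent PD-1 surface propensity
log-normally around its cluster mean; *PDCD1* mRNA is negative binomial
with mean equal to the propensity, and the PD-1 ADT tag is negative
binomial with mean `adt_gain x propensity`, multiplied by the blocking
factor (default 0.125) for bound cells. mRNA is thus identically
distributed for bound and unbound cells at fixed propensity — the
competition mechanism in its purest form. Treatment is assigned at donor
level and every reaction pools treated and untreated donors; bound labels
occur only among treated cells (30% by default). The embedding is
cluster centroids plus isotropic Gaussian noise with the first two
components linearly loaded on log propensity; in real data the
integrated components encode the activation phenotypes that drive PD-1
levels, and the loading makes hold-out validation of the fitted model
strong, as it is in practice. ADT counts use gain 60 and dispersion
(size) 8 — tens to hundreds of counts with mild overdispersion, the
regime of a well-staining antibody; mRNA uses size 2. QC covariates are
realized from the generated count matrix (mitochondrial and ribosomal
gene blocks are included), not drawn independently. Hashtag pools draw
singlets with one high tag; doublets are sums of two independent singlet
draws from distinct samples, which is what droplet physics implies for
threshold demultiplexing.

**Spatial generator.** Locations sit on a hex (offset rows,
center-to-center distance = pitch) or square lattice; baseline expression
is i.i.d. negative binomial per gene (default mean 10, size 25: a
well-detected signaling gene with mild overdispersion around a
homogeneous baseline); planted microdomains multiply the ligand and
receptor means of a chosen pair by the fold-change inside a disc, and
region labels are vertical bands. The niche generator places cells
uniformly in a square field of view, assigns niches by the Voronoi
regions of a fixed area-balanced center layout (a quincunx for five
niches), and draws each cell's type from its niche's composition profile;
default profiles give each niche a dominant type (50%) never used as
another niche's marker and a secondary type (20%) drawn from the types
not used as dominants.

**What the generators do not emulate.** Ambient RNA, index hopping,
batch chemistry, segmentation errors, spatially correlated baseline
expression, irregular tissue boundaries, and real cell-type abundance
gradients are all absent. Passing the verification suite therefore
shows that the algorithms are implemented correctly and behave as
designed under their own assumptions; it does not certify performance on
real tissue, where the untreated-reference model can be confounded by
covariates correlated with treatment.

# Verification design and problem sizes

The suite verifies, at fixed sizes chosen to keep a full run within a
few minutes on one CPU:

- exact agreement (1e-10) of the vectorized RL score with a naive
  O(n^2) double-loop reference on a 200-location hex map, and exact
  agreement of adjacency-network edge weights with a brute-force
  reference on an 8 x 8 two-cluster checkerboard;
- permutation-null calibration on i.i.d. expression at 500 locations x
  20 pairs x 100 permutations, averaged over 5 replicate simulations
  (the fraction of p < 0.05 must sit in [0.03, 0.07]), with FDR-positive
  counts within the BH budget;
- recovery of a planted 5-fold microdomain (a 7-location disc: center
  plus first ring) against a 3-pair candidate panel on a 500-spot slide,
  averaged over 3 replicate simulations. The panel is small because this
  study isolates recovery of a single planted interaction — with 100
  permutations the attainable FDR floor scales linearly with the panel
  size — while the joint-BH machinery at scale is exercised by the
  20-pair calibration study. Because two-ring smoothing genuinely
  elevates scores within one cutoff of the disc, false positives are
  counted only beyond that distance;
- conditional-CDF calibration of the occupancy model on ~2,000 held-out
  untreated cells after training on ~5,000 (fraction of `u < alpha`
  within `alpha +/- 0.02` for alpha in {0.05, 0.10, 0.15}), and
  sensitivity >= 0.7 / specificity >= 0.9 at alpha = 0.05 on 2,000
  treated cells with 30% bound at blocking factor 0.125, with exact
  nestedness across levels;
- >= 98% singlet accuracy and >= 80% doublet detection on a 4-sample
  2,000-cell pool at a 50-fold positive/negative tag ratio;
- adjusted Rand index >= 0.8 against the planted labels on three
  replicate 10,000-cell, 5-niche maps;
- closed-form identities: CLR rows sum to zero (1e-9), RL score symmetry
  under ligand-receptor swap, conditional-quantile monotonicity in the
  level for every cell, and a QRF interquantile range matching the
  closed-form normal value on simulated Gaussian data.

`scripts/acceptance.R` recomputes all of these quantities from scratch at
a caller-supplied seed and writes them as JSON.

# Known limitations

- The occupancy caller assumes the untreated cells span the covariate
  space of the treated cells; extrapolation outside the training support
  falls back on the nearest leaves and the conditional CDF loses
  calibration there.
- The conditional law is discrete over training responses, so `u` has a
  resolution floor of roughly one over the effective leaf population;
  with very small training sets the `u < 0.01` call is conservative.
- The pooled permutation null assumes locations are exchangeable within
  a slide under the null; strong global spatial trends in expression
  violate this and inflate the null tail. Per-location nulls would need
  far more than 100 permutations to be usable with BH at these scales.
- The enrichment model is Gaussian on smoothed scores; heavy-tailed
  score distributions at very low expression may warrant a rank-based
  alternative (`compare_scores_by_class` provides one for grouped
  comparisons).
- k-medoids demultiplexing needs the negative population of every tag to
  be represented; pools where some sample dominates extremely can leave
  a tag without a usable negative cluster, in which case the quintile
  fallback applies.
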