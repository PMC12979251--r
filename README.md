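# cpibind

Checkpoint-inhibitor (CPI) therapy works by drug molecules physically
occupying their target — for anti-PD-1 antibodies such as nivolumab, the
PD-1 epitope on T cells. In CITE-seq data this occupancy has a measurable
signature: the drug blocks binding of the competing PD-1 detection
antibody, so a drug-bound cell shows *less* antibody-derived-tag (ADT)
signal than its transcriptome says it should, while *PDCD1* mRNA is
untouched. `cpibind` implements the computational machinery for tracking
such cells and the spatial context they live in:

- **Hashed-pool demultiplexing** — CLR normalization of tag counts,
  clara k-medoids initialization with `k = n_samples + 1`, per-tag
  negative-binomial thresholds at the 99th percentile, singlet/doublet/
  negative calling.
- **Drug-occupancy calling** — a quantile regression forest (QRF)
  trained on untreated cells models the conditional distribution
  `F(ADT signal | covariates)`; a treated cell with conditional CDF
  value `u = F(measured | x) < alpha` is called bound at confidence
  `alpha` (levels 0.01/0.05/0.10/0.15, i.e., the 0.99/0.95/0.90/0.85
  conditional quantiles). Feature assembly, recursive importance-based
  selection (threshold 5 on a 0–100 scale), hold-out and held-out-donor
  validation, and per-cluster bound fractions with conditional-
  distribution Monte-Carlo intervals are included.
- **Spatial receptor–ligand co-localization** — the distance-weighted,
  locally smoothed product score
  `S_i = (Σ_j d_ij L_j / n_i) · (Σ_j d_ij R_j / n_i)` with a linear
  two-ring weight scheme, a 100-permutation profile-shuffling null,
  empirical p-values, joint Benjamini–Hochberg FDR (positive at
  FDR < 5%), region/condition enrichment with detection-rate blocking,
  and score comparisons by neighbor class. Works at spot (Visium) and
  segmented-cell (CosMx) resolution.
- **Spatial niches and networks** — adjacent-neighbor cell-type
  composition matrices, modularity-based niche clustering, crypt-top
  cluster adjacency networks (0 < dist < 4, self-loops kept), and
  cell-type co-occurrence networks (p < 0.01, r ≥ 0.15, positive edges).
- **Synthetic-data generators** with ground truth for all of the above,
  so every stage is testable without patient data.

## Worked example

Simulate a CITE-seq cohort (treated and untreated donors pooled across
reactions, 30% of treated cells drug-bound, ADT blocking factor 0.125),
fit the occupancy model on untreated cells, and score the treated cells:

```r
library(cpibind)

sim   <- simulate_citeseq(cite_sim_config(n_cells = 4000, seed = 1))
model <- fit_binding_model(sim$dataset, sel_num_trees = 50,
                           num_trees = 300, seed = 1)
model
#> Drug-occupancy calling model
#>   trained on 1699 untreated cells; 8 selected features
#>   hold-out r = 0.854 (random 33%), 0.862 (donor 3)
#>   test direction: one-sided lower tail (u < alpha): epitope blocking can only suppress measured signal

calls <- predict(model, sim$dataset)   # scores the treated cells
calls
#> Occupancy calls for 969 cells
#>   bound at alpha=0.01: 238 cells (24.6%)
#>   bound at alpha=0.05: 304 cells (31.4%)
#>   bound at alpha=0.10: 348 cells (35.9%)
#>   bound at alpha=0.15: 384 cells (39.6%)

treated <- which(sim$dataset$meta$treated)
cluster_bound_fractions(model, calls,
                        sim$dataset$meta$cluster[treated],
                        alpha = 0.05, seed = 1)
#>   cluster   n n_bound fraction  ci_lo  ci_hi
#> 1       1 247      76    0.308 0.0121 0.0607
#> 2       2 237      76    0.321 0.0210 0.0759
#> 3       3 263      76    0.289 0.0228 0.0760
#> 4       4 222      76    0.342 0.0225 0.0766
```

Reading the output: the model validates with hold-out correlation ≈ 0.85
on both the random 33% split and the fully held-out untreated donor. At
`alpha = 0.05` about 31% of treated cells are called bound — close to the
30% planted by the simulation — and the per-cluster fractions sit near
0.3 in all four clusters. The `ci` columns are the conditional-
distribution reference band: the range the cluster fraction would take if
every cell's measurement were resampled from the fitted drug-free
conditional law (hence it hovers near `alpha`, the calling noise floor —
observed fractions far above it indicate genuine occupancy).

The spatial side follows the same pattern: `simulate_spatial()` plants
ligand/receptor microdomains on a lattice, `rl_analysis()` computes
scores, permutation p-values and FDR-positive locations, and
`crosstalk_enrichment()` models region dependence. `simulate_niche_map()`,
`neighbor_composition()` and `cluster_niches()` cover niche recovery;
`crypt_adjacency_network()` and `cooccurrence_network()` build the two
network types. See the methods vignette
(`vignettes/occupancy-and-niches.Rmd`) for the models, conventions and
the verification design.

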