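#' Configuration for the CITE-seq simulator
#'
#' Builds a validated configuration object for [simulate_citeseq()]. The
#' simulator emulates the competition mechanism at the heart of the binding
#' caller: drug occupancy of PD-1 epitopes suppresses detection by the
#' competing antibody-derived tag (ADT) but leaves \emph{PDCD1} mRNA
#' untouched.
#'
#' @param n_cells Number of cells.
#' @param n_clusters Number of phenotypic T-cell clusters.
#' @param cluster_props Cluster mixing proportions (sums to 1). Default
#'   uniform.
#' @param n_embed_dims Number of reduced-dimension components to emit
#'   (default 30, matching a typical integrated embedding).
#' @param pdcd1_mu_by_cluster Mean \emph{PDCD1} mRNA UMI count per cluster;
#'   also the cluster mean of the latent PD-1 surface propensity.
#' @param adt_gain Expected ADT counts per unit propensity for an unbound
#'   cell. Real PD-1 ADT counts on T cells sit in the tens-to-hundreds.
#' @param adt_dispersion Negative-binomial size for ADT tag draws; tag
#'   counts after QC are less overdispersed than mRNA.
#' @param blocking_factor Multiplier in (0, 1] applied to the ADT mean of a
#'   drug-bound cell (epitope blocking); 1 means no suppression.
#' @param bound_prob_by_cluster Probability that a treated cell of each
#'   cluster is drug-bound.
#' @param frac_treated Fraction of donors that received checkpoint
#'   inhibitor; treatment is assigned at donor level, as in pooled designs.
#' @param nb_dispersion Negative-binomial size parameter shared by mRNA and
#'   ADT draws.
#' @param n_reactions Number of 10x reactions; every reaction mixes treated
#'   and untreated donors.
#' @param n_donors Number of donors.
#' @param n_genes Number of background genes (in addition to \emph{PDCD1},
#'   mitochondrial and ribosomal blocks).
#' @param n_adt Number of ADT tags in the panel (PD-1 plus bystanders);
#'   the CLR transform needs a panel, not a single tag.
#' @param propensity_sdlog Log-scale SD of within-cluster propensity
#'   heterogeneity.
#' @param seed Integer seed.
#'
#' @return An object of class `cite_sim_config`.
#' @export
cite_sim_config <- function(n_cells = 10000L,
                            n_clusters = 4L,
                            cluster_props = NULL,
                            n_embed_dims = 30L,
                            pdcd1_mu_by_cluster = NULL,
                            adt_gain = 60,
                            blocking_factor = 0.125,
                            bound_prob_by_cluster = NULL,
                            adt_dispersion = 8,
                            frac_treated = 0.25,
                            nb_dispersion = 2,
                            n_reactions = 4L,
                            n_donors = 8L,
                            n_genes = 200L,
                            n_adt = 10L,
                            propensity_sdlog = 0.5,
                            seed = 1L) {
  stop_if_not(n_clusters >= 1, "need at least one cluster")
  stop_if_not(n_cells >= 0, "n_cells must be non-negative")
  if (is.null(cluster_props)) cluster_props <- rep(1 / n_clusters, n_clusters)
  stop_if_not(length(cluster_props) == n_clusters,
              "cluster_props length must equal n_clusters")
  stop_if_not(abs(sum(cluster_props) - 1) < 1e-9, "cluster_props must sum to 1")
  if (is.null(pdcd1_mu_by_cluster)) {
    pdcd1_mu_by_cluster <- seq(0.5, 4, length.out = n_clusters)
  }
  stop_if_not(all(pdcd1_mu_by_cluster >= 0), "rates must be non-negative")
  if (is.null(bound_prob_by_cluster)) {
    bound_prob_by_cluster <- rep(0.3, n_clusters)
  }
  stop_if_not(all(bound_prob_by_cluster >= 0 & bound_prob_by_cluster <= 1),
              "bound probabilities must lie in [0,1]")
  stop_if_not(blocking_factor > 0 && blocking_factor <= 1,
              "blocking_factor must lie in (0,1]")
  stop_if_not(adt_gain > 0, "adt_gain must be positive")
  stop_if_not(nb_dispersion > 0, "nb_dispersion must be positive")
  stop_if_not(frac_treated >= 0 && frac_treated <= 1,
              "frac_treated must lie in [0,1]")
  cfg <- list(n_cells = as.integer(n_cells), n_clusters = as.integer(n_clusters),
              cluster_props = cluster_props, n_embed_dims = as.integer(n_embed_dims),
              pdcd1_mu_by_cluster = pdcd1_mu_by_cluster, adt_gain = adt_gain,
              adt_dispersion = adt_dispersion,
              blocking_factor = blocking_factor,
              bound_prob_by_cluster = bound_prob_by_cluster,
              frac_treated = frac_treated, nb_dispersion = nb_dispersion,
              n_reactions = as.integer(n_reactions), n_donors = as.integer(n_donors),
              n_genes = as.integer(n_genes), n_adt = as.integer(n_adt),
              propensity_sdlog = propensity_sdlog, seed = as.integer(seed))
  class(cfg) <- "cite_sim_config"
  cfg
}

#' Simulate a CITE-seq dataset with known drug-occupancy labels
#'
#' Generates a gene-by-cell UMI matrix, an ADT tag panel, a reduced-dimension
#' embedding and per-cell metadata, together with ground-truth bound labels.
#' Per cell, a latent PD-1 propensity is drawn around its cluster mean;
#' \emph{PDCD1} mRNA is negative binomial with mean equal to the propensity,
#' and the PD-1 ADT tag is negative binomial with mean
#' `adt_gain * propensity`, multiplied by `blocking_factor` for bound cells.
#' mRNA is thus identically distributed for bound and unbound cells at fixed
#' propensity — binding suppresses tag detection only. One embedding
#' component is linearly loaded on log propensity so that the regression
#' forest has signal beyond \emph{PDCD1} mRNA alone.
#'
#' @param config A [cite_sim_config()] object.
#' @return A list with elements `dataset` (class `citeseq_dataset`: `counts`
#'   genes x cells sparse matrix, `adt` cells x tags matrix, `meta`
#'   data.frame, `embedding` cells x dims matrix) and `truth` (data.frame
#'   with `bound`, `treated`, `propensity`, `cluster`, `donor`).
#' @export
simulate_citeseq <- function(config) {
  stopifnot(inherits(config, "cite_sim_config"))
  n <- config$n_cells
  set.seed(config$seed)

  gene_names <- c("PDCD1",
                  paste0("MT-G", seq_len(10)),
                  paste0("RPL", seq_len(10)), paste0("RPS", seq_len(10)),
                  paste0("GENE", seq_len(config$n_genes)))
  adt_names <- c("PD1", paste0("ADT", seq_len(max(config$n_adt - 1L, 0L))))

  if (n == 0L) {
    ds <- structure(list(
      counts = Matrix::Matrix(0, nrow = length(gene_names), ncol = 0,
                              dimnames = list(gene_names, NULL), sparse = TRUE),
      adt = matrix(0, 0, length(adt_names), dimnames = list(NULL, adt_names)),
      meta = data.frame(),
      embedding = matrix(0, 0, config$n_embed_dims)),
      class = "citeseq_dataset")
    return(list(dataset = ds,
                truth = data.frame(barcode = character(0), bound = logical(0),
                                   treated = logical(0), propensity = numeric(0),
                                   cluster = integer(0), donor = integer(0))))
  }

  barcodes <- sprintf("cell%06d", seq_len(n))
  cl <- sample.int(config$n_clusters, n, replace = TRUE,
                   prob = config$cluster_props)

  ## donor-level treatment assignment; every reaction pools both arms
  n_treated_donors <- round(config$frac_treated * config$n_donors)
  donor_treated <- c(rep(TRUE, n_treated_donors),
                     rep(FALSE, config$n_donors - n_treated_donors))
  donor <- sample.int(config$n_donors, n, replace = TRUE)
  treated <- donor_treated[donor]
  reaction <- sample.int(config$n_reactions, n, replace = TRUE)

  bound <- treated & (runif(n) < config$bound_prob_by_cluster[cl])

  ## latent surface propensity: lognormal around cluster mean (mean-preserving)
  sdl <- config$propensity_sdlog
  propensity <- config$pdcd1_mu_by_cluster[cl] *
    exp(rnorm(n, mean = -sdl^2 / 2, sd = sdl))

  size <- config$nb_dispersion
  pdcd1 <- rnbinom(n, size = size, mu = propensity)

  ## background genes: lognormal base means, mild cluster structure on a
  ## subset, cell-level library size factor
  ngene <- length(gene_names)
  base_mu <- exp(rnorm(ngene, meanlog_for_genes(gene_names), 0.8))
  cl_effect <- matrix(exp(rnorm(ngene * config$n_clusters, 0, 0.15)),
                      ngene, config$n_clusters)
  size_factor <- exp(rnorm(n, 0, 0.25))
  mu_mat <- base_mu * cl_effect[, cl, drop = FALSE]
  mu_mat <- sweep(mu_mat, 2, size_factor, "*")
  counts <- matrix(rnbinom(ngene * n, size = size, mu = mu_mat), ngene, n,
                   dimnames = list(gene_names, barcodes))
  counts["PDCD1", ] <- pdcd1
  counts <- Matrix::Matrix(counts, sparse = TRUE)

  ## ADT panel: PD-1 driven by propensity with epitope blocking; bystander
  ## tags with fixed lognormal means
  adt_mu <- matrix(rep(exp(rnorm(length(adt_names) - 1L, log(40), 0.6)),
                       each = n), n, length(adt_names) - 1L)
  pd1_mu <- config$adt_gain * propensity *
    ifelse(bound, config$blocking_factor, 1)
  adt <- cbind(rnbinom(n, size = config$adt_dispersion, mu = pd1_mu),
               matrix(rnbinom(n * (length(adt_names) - 1L),
                              size = config$adt_dispersion,
                              mu = adt_mu), n, length(adt_names) - 1L))
  dimnames(adt) <- list(barcodes, adt_names)

  ## embedding: cluster centroids + isotropic noise; dim 1 carries the
  ## propensity loading
  centroids <- matrix(rnorm(config$n_clusters * config$n_embed_dims, 0, 3),
                      config$n_clusters, config$n_embed_dims)
  emb <- centroids[cl, , drop = FALSE] +
    matrix(rnorm(n * config$n_embed_dims), n, config$n_embed_dims)
  lp <- log(propensity)
  z <- (lp - mean(lp)) / stats::sd(lp)
  emb[, 1] <- emb[, 1] + 2.5 * z
  emb[, 2] <- emb[, 2] + 1.2 * z
  dimnames(emb) <- list(barcodes, paste0("emb_", seq_len(config$n_embed_dims)))

  ## QC covariates realised from the count matrix
  total_counts <- Matrix::colSums(counts)
  detect_rate <- Matrix::colSums(counts > 0) / ngene
  mito_idx <- grep("^MT-", gene_names)
  ribo_idx <- grep("^RP[LS]", gene_names)
  mito_pct <- 100 * Matrix::colSums(counts[mito_idx, , drop = FALSE]) /
    pmax(total_counts, 1)
  ribo_pct <- 100 * Matrix::colSums(counts[ribo_idx, , drop = FALSE]) /
    pmax(total_counts, 1)

  s_score <- rnorm(n, 0, 0.25)
  g2m_score <- rnorm(n, 0, 0.25)
  phase <- c("G1", "S", "G2M")[max.col(cbind(0.15, s_score, g2m_score))]

  meta <- data.frame(barcode = barcodes, cluster = cl, donor = donor,
                     reaction = factor(reaction), treated = treated,
                     total_counts = total_counts, detect_rate = detect_rate,
                     mito_pct = mito_pct, ribo_pct = ribo_pct,
                     s_score = s_score, g2m_score = g2m_score,
                     phase = factor(phase, levels = c("G1", "S", "G2M")),
                     row.names = NULL, stringsAsFactors = FALSE)

  ds <- structure(list(counts = counts, adt = adt, meta = meta,
                       embedding = emb),
                  class = "citeseq_dataset")
  truth <- data.frame(barcode = barcodes, bound = bound, treated = treated,
                      propensity = propensity, cluster = cl, donor = donor,
                      stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth)
}

## house-expressed background genes get larger means than PDCD1-like genes;
## mito/ribo blocks are boosted so mito% / ribo% land in realistic ranges
meanlog_for_genes <- function(gene_names) {
  ml <- rep(log(0.5), length(gene_names))
  ml[grep("^MT-", gene_names)] <- log(8)
  ml[grep("^RP[LS]", gene_names)] <- log(6)
  ml[1] <- log(1)   # PDCD1 slot; overwritten by the propensity draw anyway
  ml
}

#' @export
print.citeseq_dataset <- function(x, ...) {
  cat("CITE-seq dataset:", ncol(x$counts), "cells,",
      nrow(x$counts), "genes,", ncol(x$adt), "ADT tags,",
      ncol(x$embedding), "embedding dims\n")
  invisible(x)
}

#' Simulate a hashed pool of cells with doublets
#'
#' Singlets carry one high hashtag; doublets are sums of two independent
#' singlet draws from distinct samples (droplet physics). All counts are
#' negative binomial.
#'
#' @param n_cells Number of droplets.
#' @param n_samples Number of hashed samples (tags); at least 2.
#' @param doublet_rate Fraction of droplets containing two cells.
#' @param mu_pos Mean tag count for a cell's own hashtag.
#' @param mu_neg Background mean for the other tags.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return A list with `counts` (cells x tags integer matrix) and `truth`
#'   (data.frame: `sample1`, `sample2` (NA for singlets), `doublet`).
#' @export
simulate_hashtags <- function(n_cells, n_samples, doublet_rate = 0.05,
                              mu_pos = 500, mu_neg = 10, dispersion = 10,
                              seed = 1L) {
  stop_if_not(n_samples >= 2, "need at least two hashed samples")
  stop_if_not(mu_pos > mu_neg, "mu_pos must exceed mu_neg")
  stop_if_not(doublet_rate >= 0 && doublet_rate <= 1,
              "doublet_rate must lie in [0,1]")
  set.seed(seed)
  tag_names <- paste0("HTO", seq_len(n_samples))
  barcodes <- sprintf("bc%06d", seq_len(n_cells))

  draw_singlet <- function(sample_id) {
    m <- matrix(rnbinom(length(sample_id) * n_samples, size = dispersion,
                        mu = mu_neg), length(sample_id), n_samples)
    pos <- rnbinom(length(sample_id), size = dispersion, mu = mu_pos)
    m[cbind(seq_along(sample_id), sample_id)] <- pos
    m
  }

  doublet <- runif(n_cells) < doublet_rate
  s1 <- sample.int(n_samples, n_cells, replace = TRUE)
  ## second cell from a different sample
  s2 <- ifelse(doublet,
               1L + (s1 - 1L + sample.int(n_samples - 1L, n_cells,
                                          replace = TRUE)) %% n_samples,
               NA_integer_)
  counts <- draw_singlet(s1)
  if (any(doublet)) {
    counts[doublet, ] <- counts[doublet, , drop = FALSE] +
      draw_singlet(s2[doublet])
  }
  dimnames(counts) <- list(barcodes, tag_names)
  list(counts = counts,
       truth = data.frame(barcode = barcodes, sample1 = s1, sample2 = s2,
                          doublet = doublet, stringsAsFactors = FALSE))
}
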