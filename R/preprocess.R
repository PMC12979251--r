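#' Centered log-ratio normalization of tag counts
#'
#' Per cell (row) and tag (column), computes
#' `y_ij = ln(x_ij + 1) - mean_k ln(x_ik + 1)`, the CLR transform as
#' standardly applied to antibody-derived tag and hashtag panels: each
#' cell's tag profile is centered on its own log-scale mean, so every row
#' sums to zero.
#'
#' @param counts Non-negative cells x tags matrix.
#' @return A numeric matrix of the same dimensions; rows sum to 0.
#' @export
clr_normalize <- function(counts) {
  counts <- as.matrix(counts)
  stop_if_not(length(counts) > 0, "empty tag matrix")
  stop_if_not(all(counts >= 0), "tag counts must be non-negative")
  lx <- log(counts + 1)
  out <- lx - rowMeans(lx)
  dimnames(out) <- dimnames(counts)
  out
}

#' Demultiplex a hashed pool by per-tag negative-binomial thresholds
#'
#' Reproduces threshold demultiplexing for hashed pools: (1) CLR-normalize
#' the tag counts; (2) partition cells by clara k-medoids with
#' `k = n_samples + 1` (one cluster per sample plus one for negatives);
#' (3) for each tag, take the cells of every cluster whose mean CLR signal
#' for the tag falls below the midpoint of the cluster-mean range (the
#' tag-negative clusters) and fit a negative binomial to that tag's raw
#' counts there;
#' (4) the positive threshold is the fitted distribution's
#' `positive_quantile` quantile; (5) cells above threshold are positive
#' for the tag; (6) cells positive for exactly one tag are singlets (that
#' tag is the sample of origin), for two or more are doublets, for none
#' are negatives.
#'
#' If the negative population holds fewer than `min_cluster_cells` cells,
#' all cells are used. An all-zero tag gets an infinite threshold with a
#' warning.
#'
#' @param counts Cells x tags count matrix (tags absent from the pool
#'   already removed).
#' @param n_samples Number of samples hashed into the pool.
#' @param positive_quantile Quantile of the fitted negative-count
#'   distribution used as the positive threshold (default 0.99).
#' @param seed Integer seed for the k-medoids initialization.
#' @param min_cluster_cells Minimum size of a usable negative cluster.
#' @return An object of class `demux_result`: data.frame `calls` (barcode,
#'   class, sample, n_positive), logical matrix `positive`, numeric
#'   `thresholds` per tag, list `nb_fits`, and the convention metadata
#'   (`fit_scale`, naming the raw-count scale and the negative-population rule).
#' @export
demux_hashtags <- function(counts, n_samples,
                           positive_quantile = 0.99, seed = 1L,
                           min_cluster_cells = 20L) {
  counts <- as.matrix(counts)
  stop_if_not(ncol(counts) >= n_samples,
              "fewer tags than samples in the pool")
  k <- n_samples + 1L
  stop_if_not(nrow(counts) > k, "fewer cells than k-medoids clusters")
  clr <- clr_normalize(counts)
  set.seed(seed)
  cl <- cluster::clara(clr, k = k,
                       samples = 5, pamLike = TRUE)$clustering

  tags <- colnames(counts)
  if (is.null(tags)) tags <- paste0("tag", seq_len(ncol(counts)))
  thresholds <- numeric(ncol(counts))
  names(thresholds) <- tags
  fits <- vector("list", ncol(counts))
  names(fits) <- tags
  for (j in seq_len(ncol(counts))) {
    if (all(counts[, j] == 0)) {
      warning("tag ", tags[j], " has all-zero counts; threshold set to +Inf")
      thresholds[j] <- Inf
      next
    }
    cl_means <- tapply(clr[, j], cl, mean)
    ## the tag's negative population: every cluster whose mean signal for
    ## the tag sits in the lower half of the cluster-mean range. Tag-
    ## positive clusters separate from negative ones by several CLR units,
    ## so the midpoint splits them cleanly; this tolerates both a sample
    ## split across two clusters (both halves stay excluded) and a surplus
    ## cluster aligned with one tag's background noise tail (it is pooled
    ## with the other negative clusters instead of fit on its own).
    pivot <- (min(cl_means) + max(cl_means)) / 2
    neg_cl <- as.integer(names(cl_means)[cl_means < pivot])
    neg_cells <- which(cl %in% neg_cl)
    if (length(neg_cells) < min_cluster_cells) neg_cells <- seq_len(nrow(counts))
    fits[[j]] <- fit_nb(counts[neg_cells, j])
    thresholds[j] <- nb_quantile(fits[[j]], positive_quantile)
  }

  positive <- sweep(counts, 2, thresholds, ">")
  n_pos <- rowSums(positive)
  class_ <- ifelse(n_pos == 0, "negative",
                   ifelse(n_pos == 1, "singlet", "doublet"))
  sample_id <- rep(NA_character_, nrow(counts))
  singl <- n_pos == 1
  sample_id[singl] <- tags[max.col(positive[singl, , drop = FALSE],
                                   ties.method = "first")]
  barcodes <- rownames(counts)
  if (is.null(barcodes)) barcodes <- sprintf("bc%06d", seq_len(nrow(counts)))
  res <- list(calls = data.frame(barcode = barcodes, class = class_,
                                 sample = sample_id, n_positive = n_pos,
                                 stringsAsFactors = FALSE),
              positive = positive, thresholds = thresholds, nb_fits = fits,
              n_samples = n_samples, positive_quantile = positive_quantile,
              fit_scale = "raw counts, clusters below the midpoint of per-tag cluster means",
              seed = seed)
  class(res) <- "demux_result"
  res
}

#' @export
print.demux_result <- function(x, ...) {
  tab <- table(factor(x$calls$class,
                      levels = c("singlet", "doublet", "negative")))
  cat("Hashtag demultiplexing of", nrow(x$calls), "cells over",
      x$n_samples, "samples\n")
  cat(sprintf("  singlets %d, doublets %d, negatives %d\n",
              tab["singlet"], tab["doublet"], tab["negative"]))
  cat("  thresholds:", paste(sprintf("%s>%.0f", names(x$thresholds),
                                     x$thresholds), collapse = ", "), "\n")
  invisible(x)
}

#' Filter cells by QC thresholds
#'
#' Removes cells failing any of the supplied thresholds and reports how
#' many each rule removed.
#'
#' @param dataset A `citeseq_dataset`.
#' @param min_total Minimum total UMI count (default `-Inf`, no filter).
#' @param max_mito Maximum mitochondrial percentage (default `Inf`).
#' @return The filtered `citeseq_dataset`, with an attribute `qc_report`
#'   (data.frame of cells removed per rule and cells retained).
#' @export
qc_filter <- function(dataset, min_total = -Inf, max_mito = Inf) {
  stopifnot(inherits(dataset, "citeseq_dataset"))
  for (col in c("total_counts", "mito_pct")) {
    if (!col %in% colnames(dataset$meta)) {
      stop("metadata column '", col, "' is missing", call. = FALSE)
    }
  }
  fail_total <- dataset$meta$total_counts < min_total
  fail_mito <- dataset$meta$mito_pct > max_mito
  keep <- !(fail_total | fail_mito)
  out <- dataset
  out$counts <- dataset$counts[, keep, drop = FALSE]
  out$adt <- dataset$adt[keep, , drop = FALSE]
  out$meta <- dataset$meta[keep, , drop = FALSE]
  out$embedding <- dataset$embedding[keep, , drop = FALSE]
  attr(out, "qc_report") <- data.frame(
    rule = c("min_total", "max_mito", "retained"),
    cells = c(sum(fail_total), sum(fail_mito), sum(keep)))
  out
}
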