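#' Assemble the per-cell feature table for PD-1 signal modeling
#'
#' Builds the predictor families used to model expected tag signal in the
#' absence of drug: the reduced-dimension embedding components, cell-cycle
#' scores and one-hot phase encoding, one-hot reaction encoding, total RNA
#' counts, gene detection rate, mitochondrial and ribosomal percentages,
#' and normalized \emph{PDCD1} mRNA (log1p of library-size-scaled counts).
#'
#' @param dataset A `citeseq_dataset` with embedding, metadata and counts.
#' @return A numeric data.frame, one row per cell, no missing values.
#' @export
assemble_features <- function(dataset) {
  stopifnot(inherits(dataset, "citeseq_dataset"))
  if (is.null(dataset$embedding) || ncol(dataset$embedding) == 0) {
    stop("dataset has no reduced-dimension embedding", call. = FALSE)
  }
  meta <- dataset$meta
  emb <- as.data.frame(dataset$embedding)
  if (is.null(colnames(dataset$embedding))) {
    colnames(emb) <- paste0("emb_", seq_len(ncol(emb)))
  }
  total <- Matrix::colSums(dataset$counts)
  detect <- Matrix::colSums(dataset$counts > 0) / nrow(dataset$counts)
  pd <- if ("PDCD1" %in% rownames(dataset$counts)) {
    as.numeric(dataset$counts["PDCD1", ])
  } else rep(0, ncol(dataset$counts))
  sf <- ifelse(total > 0, median(total[total > 0]) / total, 0)
  pdcd1 <- log1p(pd * sf)

  onehot <- function(f, prefix) {
    f <- factor(f)
    if (nlevels(f) <= 1) return(NULL)
    m <- stats::model.matrix(~ f - 1)
    colnames(m) <- paste0(prefix, "_", levels(f))
    as.data.frame(m[, -1, drop = FALSE])   # first level is the baseline
  }
  parts <- list(emb,
                data.frame(s_score = meta$s_score,
                           g2m_score = meta$g2m_score),
                onehot(meta$phase, "phase"),
                onehot(meta$reaction, "reaction"),
                data.frame(total_counts = total, detect_rate = detect,
                           mito_pct = meta$mito_pct,
                           ribo_pct = meta$ribo_pct, pdcd1 = pdcd1))
  out <- do.call(cbind, parts[!vapply(parts, is.null, logical(1))])
  rownames(out) <- meta$barcode
  stop_if_not(all(complete.cases(out)), "feature table has missing values")
  out
}

#' Measured PD-1 tag signal on the CLR scale
#'
#' @param dataset A `citeseq_dataset`.
#' @param tag Name of the PD-1 ADT tag (default `"PD1"`).
#' @return Numeric vector, one value per cell.
#' @export
measured_pd1 <- function(dataset, tag = "PD1") {
  stop_if_not(tag %in% colnames(dataset$adt),
              paste0("ADT tag '", tag, "' not found"))
  clr_normalize(dataset$adt)[, tag]
}

#' Recursive feature selection by rescaled permutation importance
#'
#' Repeatedly fits a random-forest regressor, rescales permutation
#' importances (negatives floored at zero) so they total 100, and drops the
#' weakest feature until every remaining feature exceeds
#' `importance_threshold` — i.e., contributes more than that percentage of
#' total importance. A non-positive threshold keeps all features.
#'
#' @param features Feature data.frame/matrix.
#' @param target Numeric response.
#' @param importance_threshold Retention threshold on the 0-100 importance
#'   scale (default 5).
#' @param num_trees Trees per selection fit (default 100; selection needs
#'   rankings, not converged predictions).
#' @param min_node_size Minimum node size for selection fits.
#' @param seed Integer seed.
#' @return List with `selected` (feature names), `importance` (final
#'   rescaled importances) and `n_dropped`.
#' @export
select_features <- function(features, target, importance_threshold = 5,
                            num_trees = 100L, min_node_size = 25L,
                            seed = 1L) {
  features <- as.data.frame(features)
  stop_if_not(ncol(features) >= 2, "need at least two candidate features")
  keep <- colnames(features)
  n_dropped <- 0L
  repeat {
    fit <- ranger::ranger(x = features[, keep, drop = FALSE], y = target,
                          num.trees = num_trees,
                          min.node.size = min_node_size,
                          importance = "permutation", seed = seed,
                          num.threads = 1L)
    imp <- pmax(fit$variable.importance, 0)
    if (importance_threshold <= 0) {
      return(list(selected = keep, importance = rescale100(imp),
                  n_dropped = n_dropped))
    }
    if (sum(imp) <= 0) {
      stop("no features carry importance; consider lowering the threshold",
           call. = FALSE)
    }
    imp_rs <- rescale100(imp)
    if (all(imp_rs > importance_threshold)) {
      return(list(selected = keep, importance = imp_rs,
                  n_dropped = n_dropped))
    }
    if (length(keep) == 1L) {
      stop("all features eliminated; consider lowering the threshold",
           call. = FALSE)
    }
    keep <- setdiff(keep, names(which.min(imp_rs)))
    n_dropped <- n_dropped + 1L
  }
}

rescale100 <- function(imp) {
  s <- sum(imp)
  if (s <= 0) imp * 0 else 100 * imp / s
}

#' Validate a quantile regression forest on held-out cells
#'
#' Pearson correlation between the conditional median prediction and the
#' measured values, compared with the trivial global-mean predictor.
#'
#' @param model A `qrf`.
#' @param newdata Held-out feature rows (disjoint from training).
#' @param measured Held-out measured values.
#' @param floor Correlation below which the model is flagged.
#' @return List with `r`, `flagged`, `n`.
#' @export
validate_qrf <- function(model, newdata, measured, floor = 0.3) {
  stop_if_not(nrow(as.data.frame(newdata)) > 0, "empty holdout set")
  med <- predict(model, newdata, type = "quantiles", quantiles = 0.5)[, 1]
  r <- if (sd(med) == 0 || sd(measured) == 0) 0 else cor(med, measured)
  list(r = r, flagged = r < floor, n = length(measured))
}

#' Fit the drug-occupancy calling model
#'
#' End-to-end trainer for the occupancy caller: assembles features, selects
#' them by recursive importance elimination, and fits a quantile regression
#' forest for PD-1 tag signal on cells from non-treated donors only — the
#' drug-free reference for what measured signal \emph{should} look like.
#' One untreated donor is set aside entirely as an independent validation
#' set, plus a random fraction of remaining untreated cells as a hold-out;
#' median-prediction correlations on both are reported.
#'
#' @param dataset A `citeseq_dataset`; `meta$treated` flags treated donors'
#'   cells.
#' @param importance_threshold Feature-selection threshold (default 5).
#' @param select Run feature selection (default TRUE).
#' @param num_trees,min_node_size Forest size for the final model.
#' @param sel_num_trees Trees per selection fit.
#' @param holdout_frac Random hold-out fraction of the untreated training
#'   pool (default 0.33).
#' @param holdout_donor Donor id to hold out entirely; default the first
#'   untreated donor.
#' @param alphas Confidence levels at which cells will be called bound.
#' @param seed Integer seed.
#' @return An object of class `binding_model`; the training, random
#'   hold-out and donor hold-out cell indices are stored for downstream
#'   calibration checks.
#' @export
fit_binding_model <- function(dataset, importance_threshold = 5,
                              select = TRUE, num_trees = 500L,
                              min_node_size = 50L, sel_num_trees = 100L,
                              holdout_frac = 0.33, holdout_donor = NULL,
                              alphas = c(0.01, 0.05, 0.10, 0.15),
                              seed = 1L) {
  stopifnot(inherits(dataset, "citeseq_dataset"))
  feats <- assemble_features(dataset)
  target <- measured_pd1(dataset)
  untreated <- !dataset$meta$treated
  stop_if_not(any(untreated), "no untreated cells to train on")
  donors <- dataset$meta$donor
  if (is.null(holdout_donor)) {
    holdout_donor <- min(donors[untreated])
  }
  pool <- which(untreated & donors != holdout_donor)
  donor_idx <- which(untreated & donors == holdout_donor)
  set.seed(derive_seed(seed, 1L))
  n_hold <- floor(holdout_frac * length(pool))
  hold_idx <- sample(pool, n_hold)
  train_idx <- setdiff(pool, hold_idx)

  if (select) {
    sel <- select_features(feats[train_idx, , drop = FALSE],
                           target[train_idx],
                           importance_threshold = importance_threshold,
                           num_trees = sel_num_trees,
                           seed = derive_seed(seed, 2L))
  } else {
    sel <- list(selected = colnames(feats), importance = NULL, n_dropped = 0L)
  }
  model <- train_qrf(feats[train_idx, sel$selected, drop = FALSE],
                     target[train_idx], num_trees = num_trees,
                     min_node_size = min_node_size,
                     seed = derive_seed(seed, 3L))
  val_random <- if (length(hold_idx)) {
    validate_qrf(model, feats[hold_idx, sel$selected, drop = FALSE],
                 target[hold_idx])
  } else NULL
  val_donor <- if (length(donor_idx)) {
    validate_qrf(model, feats[donor_idx, sel$selected, drop = FALSE],
                 target[donor_idx])
  } else NULL

  structure(list(qrf = model, selected = sel$selected,
                 importance = sel$importance,
                 validation = list(random_holdout = val_random,
                                   donor_holdout = val_donor,
                                   holdout_donor = holdout_donor),
                 alphas = sort(alphas), seed = seed,
                 n_train = length(train_idx),
                 train_idx = train_idx, holdout_idx = hold_idx,
                 donor_holdout_idx = donor_idx,
                 test_direction = "one-sided lower tail (u < alpha): epitope blocking can only suppress measured signal"),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat("Drug-occupancy calling model\n")
  cat("  trained on", x$n_train, "untreated cells;",
      length(x$selected), "selected features\n")
  v <- x$validation
  if (!is.null(v$random_holdout)) {
    cat(sprintf("  hold-out r = %.3f (random 33%%), %.3f (donor %s)\n",
                v$random_holdout$r,
                if (is.null(v$donor_holdout)) NA else v$donor_holdout$r,
                v$holdout_donor))
  }
  cat("  test direction:", x$test_direction, "\n")
  invisible(x)
}

#' @export
summary.binding_model <- function(object, ...) {
  print(object)
  if (!is.null(object$importance)) {
    cat("  importances (0-100):\n")
    imp <- sort(object$importance, decreasing = TRUE)
    for (nm in names(imp)) cat(sprintf("    %-14s %6.2f\n", nm, imp[nm]))
  }
  invisible(object)
}

#' Conditional CDF of measured signal under the drug-free model
#'
#' For each cell, `u = Fhat(measured | x)`: the leaf-weighted fraction of
#' drug-free training signals at or below the cell's measured value, given
#' its features. Low `u` marks measured signal far below the model's
#' expectation — the discordance signature of epitope blocking.
#'
#' @param model A `binding_model` or `qrf`.
#' @param features Feature rows for the cells to evaluate.
#' @param measured Measured CLR PD-1 values for those cells.
#' @return Numeric vector `u` in `[0, 1]`.
#' @export
conditional_cdf <- function(model, features, measured) {
  qrf <- if (inherits(model, "binding_model")) model$qrf else model
  stopifnot(inherits(qrf, "qrf"))
  predict(qrf, features, type = "cdf", y = measured)
}

#' Call drug-bound cells at nested confidence levels
#'
#' A cell is called bound at level `alpha` iff `u < alpha` (one-sided lower
#' tail; drug competition can only suppress the measured tag signal).
#' Bound sets are nested across `alphas` by construction.
#'
#' @param u Per-cell conditional CDF values in `[0, 1]`.
#' @param alphas Confidence levels, each in (0, 0.5).
#' @param barcodes Optional cell identifiers.
#' @return An object of class `binding_calls`: data.frame with `u` and one
#'   logical `bound_<alpha>` column per level.
#' @export
call_bound <- function(u, alphas = c(0.01, 0.05, 0.10, 0.15),
                       barcodes = NULL) {
  stop_if_not(all(u >= 0 & u <= 1), "u must lie in [0,1]")
  stop_if_not(all(alphas > 0 & alphas < 0.5),
              "alphas must lie in (0, 0.5)")
  alphas <- sort(alphas)
  bound <- vapply(alphas, function(a) u < a, logical(length(u)))
  bound <- matrix(bound, nrow = length(u))
  colnames(bound) <- paste0("bound_", alphas)
  df <- data.frame(barcode = if (is.null(barcodes))
    sprintf("cell%06d", seq_along(u)) else barcodes,
    u = u, bound, stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(calls = df, alphas = alphas), class = "binding_calls")
}

#' @export
print.binding_calls <- function(x, ...) {
  cat("Occupancy calls for", nrow(x$calls), "cells\n")
  for (a in x$alphas) {
    cat(sprintf("  bound at alpha=%.2f: %d cells (%.1f%%)\n", a,
                sum(x$calls[[paste0("bound_", a)]]),
                100 * mean(x$calls[[paste0("bound_", a)]])))
  }
  invisible(x)
}

#' Score treated cells with a fitted occupancy model
#'
#' @param object A `binding_model`.
#' @param dataset A `citeseq_dataset`; by default the treated cells are
#'   scored.
#' @param cells Optional logical/integer index of cells to score.
#' @param ... Unused.
#' @return A `binding_calls` object with the scored features attached (for
#'   downstream confidence intervals).
#' @export
predict.binding_model <- function(object, dataset, cells = NULL, ...) {
  stopifnot(inherits(dataset, "citeseq_dataset"))
  if (is.null(cells)) cells <- which(dataset$meta$treated)
  feats <- assemble_features(dataset)[cells, object$selected, drop = FALSE]
  measured <- measured_pd1(dataset)[cells]
  u <- conditional_cdf(object, feats, measured)
  calls <- call_bound(u, object$alphas,
                      barcodes = dataset$meta$barcode[cells])
  calls$features <- feats
  calls$measured <- measured
  calls
}

#' Per-cluster bound fractions with conditional-distribution CIs
#'
#' The point estimate per cluster is the fraction of its cells called bound
#' at `alpha`. The interval comes from the model's conditional
#' distributions rather than a plain binomial: in each Monte-Carlo draw,
#' every cell's hypothetical measurement is resampled from its predicted
#' conditional distribution and re-called, and the 2.5/97.5 percentiles of
#' the resulting cluster fractions form the CI. The per-draw re-call of a
#' cell is Bernoulli with probability `P(Fhat(Y*|x) < alpha)`, which is
#' computed exactly from the discrete conditional distribution, so draws
#' cost O(cells) each.
#'
#' @param model A `binding_model` or `qrf`.
#' @param calls A `binding_calls` object carrying the scored features
#'   (from [predict.binding_model()]).
#' @param clusters Per-cell cluster labels (same order as the calls).
#' @param alpha Confidence level for the point estimate (default 0.05).
#' @param n_draws Monte-Carlo draws (default 200).
#' @param seed Integer seed.
#' @return data.frame: cluster, n, n_bound, fraction, ci_lo, ci_hi.
#' @export
cluster_bound_fractions <- function(model, calls, clusters, alpha = 0.05,
                                    n_draws = 200L, seed = 1L) {
  stopifnot(inherits(calls, "binding_calls"))
  stop_if_not(!is.null(calls$features),
              "calls must carry features; use predict() on the model")
  stop_if_not(length(clusters) == nrow(calls$calls),
              "one cluster label per called cell is required")
  qrf <- if (inherits(model, "binding_model")) model$qrf else model
  col <- paste0("bound_", alpha)
  stop_if_not(col %in% colnames(calls$calls),
              paste0("alpha ", alpha, " was not among the called levels"))
  bound <- calls$calls[[col]]
  p_recall <- predict(qrf, calls$features, type = "recall_prob",
                      alpha = alpha)

  set.seed(derive_seed(seed, 7L))
  cl <- factor(clusters)
  res <- lapply(levels(cl), function(g) {
    i <- which(cl == g)
    if (!length(i)) {
      warning("cluster ", g, " is empty; skipped")
      return(NULL)
    }
    draws <- vapply(seq_len(n_draws), function(d) {
      mean(rbinom(length(i), 1L, p_recall[i]))
    }, numeric(1))
    data.frame(cluster = g, n = length(i), n_bound = sum(bound[i]),
               fraction = mean(bound[i]),
               ci_lo = unname(quantile(draws, 0.025)),
               ci_hi = unname(quantile(draws, 0.975)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
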