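#' Distance-based neighbor weights for a spatial map
#'
#' For each location, every other location on the same slide within the
#' cutoff radius receives a linear, distance-normalized weight
#' `d = 1 - dist / (cutoff + delta)` (so weights lie in (0, 1], reaching ~1
#' adjacent to the focal location and ~0 at the cutoff); locations beyond
#' the cutoff get weight zero and the focal location itself gets
#' `self_weight`. The default cutoff is two lattice rings (`2 * pitch`),
#' i.e., the two immediately surrounding rings of spots contribute.
#' Neighborhoods never cross slides.
#'
#' @param map A `spatial_map`.
#' @param cutoff Cutoff radius in coordinate units; default `2 * map$pitch`.
#' @param self_weight Weight of the focal location (default 1).
#' @param block Row-block size for the blocked distance search.
#' @return An object of class `rl_weights`: sparse weight matrix `W`
#'   (locations x locations), `n` (per location, the number of locations
#'   with positive weight, self included) and the cutoff.
#' @export
compute_weights <- function(map, cutoff = NULL, self_weight = 1,
                            block = 1024L) {
  stopifnot(inherits(map, "spatial_map"))
  co <- map$coords
  stop_if_not(all(is.finite(co$x)) && all(is.finite(co$y)),
              "non-finite coordinates")
  if (is.null(cutoff)) {
    stop_if_not(!is.null(map$pitch), "no pitch on map; supply a cutoff")
    cutoff <- 2 * map$pitch
  }
  denom <- cutoff * (1 + 1e-6)
  n_loc <- nrow(co)
  ii <- jj <- integer(0)
  vv <- numeric(0)
  for (s in unique(co$slide)) {
    idx <- which(co$slide == s)
    xy <- cbind(co$x[idx], co$y[idx])
    sq <- rowSums(xy^2)
    for (b0 in seq(1L, length(idx), by = block)) {
      b1 <- min(b0 + block - 1L, length(idx))
      rows <- b0:b1
      d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(xy[rows, , drop = FALSE], xy)
      d2[d2 < 0] <- 0
      ## candidate superset, then exact distances (the crossprod identity
      ## carries rounding error right at the cutoff)
      hit <- which(d2 <= cutoff^2 * (1 + 1e-7) + 1e-12, arr.ind = TRUE)
      a <- hit[, 1] + b0 - 1L
      d <- sqrt((xy[a, 1] - xy[hit[, 2], 1])^2 +
                (xy[a, 2] - xy[hit[, 2], 2])^2)
      ## tiny relative tolerance so membership of pairs sitting exactly
      ## at the cutoff is stable under coordinate translation
      ok <- d <= cutoff * (1 + 1e-9)
      hit <- hit[ok, , drop = FALSE]
      d <- d[ok]
      w <- pmin(1 - d / denom, 1)
      self <- hit[, 1] + b0 - 1L == hit[, 2]
      w[self] <- self_weight
      ii <- c(ii, idx[hit[, 1] + b0 - 1L])
      jj <- c(jj, idx[hit[, 2]])
      vv <- c(vv, w)
    }
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(n_loc, n_loc))
  structure(list(W = W, n = Matrix::rowSums(W > 0), cutoff = cutoff,
                 self_weight = self_weight),
            class = "rl_weights")
}

#' Distance-weighted receptor-ligand co-localization score
#'
#' Per location, `S = (sum_i d_i L_i / n) * (sum_i d_i R_i / n)`: the
#' product of the locally smoothed ligand and receptor expression, where
#' `d_i` are the neighbor weights and `n` counts the locations with
#' positive weight (so edge-of-tissue locations are normalized by their
#' actual neighborhood size). The formula is symmetric in ligand and
#' receptor.
#'
#' @param map A `spatial_map`.
#' @param pair Character vector `c(ligand, receptor)` of gene names.
#' @param weights An `rl_weights` object for the map.
#' @return Numeric score per location.
#' @export
rl_score <- function(map, pair, weights) {
  stopifnot(inherits(map, "spatial_map"), inherits(weights, "rl_weights"))
  for (g in pair) {
    if (!g %in% rownames(map$expr)) {
      stop("gene '", g, "' not found in the expression matrix",
           call. = FALSE)
    }
  }
  L <- as.numeric(map$expr[pair[1], ])
  R <- as.numeric(map$expr[pair[2], ])
  sl <- as.numeric(weights$W %*% L) / weights$n
  sr <- as.numeric(weights$W %*% R) / weights$n
  sl * sr
}

## smoothed expression for a set of genes at once: locations x genes
smoothed_expr <- function(expr, genes, weights, col_order = NULL) {
  E <- expr[genes, , drop = FALSE]
  if (!is.null(col_order)) E <- E[, col_order, drop = FALSE]
  A <- as.matrix(weights$W %*% t(E)) / weights$n
  colnames(A) <- genes
  A
}

#' Permutation null for receptor-ligand scores
#'
#' Shuffles the assignment of whole expression profiles to coordinates
#' within each slide independently (gene-gene correlation is preserved
#' under the null) and recomputes the score for every pair and location.
#' The nulls are pooled across locations into one empirical background
#' distribution per pair.
#'
#' @param map A `spatial_map`.
#' @param pairs data.frame with `ligand` and `receptor` columns.
#' @param weights An `rl_weights` for the map.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @return Matrix of null scores, `(n_perm * n_locations) x n_pairs`,
#'   columns sorted ascending.
#' @export
permutation_null <- function(map, pairs, weights, n_perm = 100L, seed = 1L) {
  stop_if_not(n_perm >= 1, "need at least one permutation")
  set.seed(derive_seed(seed, 11L))
  n_loc <- ncol(map$expr)
  genes <- unique(c(pairs$ligand, pairs$receptor))
  slides <- map$coords$slide
  null <- matrix(NA_real_, n_perm * n_loc, nrow(pairs))
  for (b in seq_len(n_perm)) {
    perm <- seq_len(n_loc)
    for (s in unique(slides)) {
      i <- which(slides == s)
      perm[i] <- i[sample.int(length(i))]
    }
    A <- smoothed_expr(map$expr, genes, weights, col_order = perm)
    null[((b - 1) * n_loc + 1):(b * n_loc), ] <-
      A[, pairs$ligand, drop = FALSE] * A[, pairs$receptor, drop = FALSE]
  }
  apply(null, 2, sort)
}

#' Empirical p-values, FDR and positivity for observed scores
#'
#' `p = (1 + #{null >= observed}) / (1 + N_null)` against the pooled null
#' of the pair (the add-one correction keeps p away from zero), followed by
#' Benjamini-Hochberg correction jointly across all (location, pair)
#' combinations; positivity is FDR < `fdr_threshold`.
#'
#' @param observed Locations x pairs matrix of observed scores.
#' @param null Null matrix from [permutation_null()] (columns aligned with
#'   `observed`, each sorted ascending).
#' @param fdr_threshold Positivity threshold (default 0.05).
#' @return List of matrices `p`, `fdr`, `positive` shaped like `observed`.
#' @export
empirical_pvalues <- function(observed, null, fdr_threshold = 0.05) {
  observed <- as.matrix(observed)
  stop_if_not(ncol(observed) == ncol(null),
              "null is missing for some pairs")
  N <- nrow(null)
  p <- observed
  for (j in seq_len(ncol(observed))) {
    ge <- N - findInterval(observed[, j], null[, j], left.open = TRUE)
    p[, j] <- (1 + ge) / (1 + N)
  }
  fdr <- matrix(p.adjust(as.vector(p), method = "BH"), nrow(p), ncol(p),
                dimnames = dimnames(p))
  list(p = p, fdr = fdr, positive = fdr < fdr_threshold)
}

#' Full receptor-ligand co-localization analysis
#'
#' Computes neighbor weights, the observed score for every pair and
#' location, the pooled permutation null, empirical p-values, joint BH FDR
#' and positivity flags.
#'
#' @param map A `spatial_map`.
#' @param pairs data.frame with `ligand`/`receptor` columns; defaults to
#'   `map$pairs`.
#' @param n_perm Number of permutations (default 100).
#' @param cutoff Weight cutoff; default two lattice rings.
#' @param fdr_threshold Positivity threshold (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `rl_score_table`: long data.frame `table`
#'   (slide, location, ligand, receptor, score, p, fdr, positive) plus the
#'   weights and call parameters.
#' @export
rl_analysis <- function(map, pairs = NULL, n_perm = 100L, cutoff = NULL,
                        fdr_threshold = 0.05, seed = 1L) {
  stopifnot(inherits(map, "spatial_map"))
  if (is.null(pairs)) pairs <- map$pairs
  stop_if_not(!is.null(pairs) && nrow(pairs) >= 1, "no pairs to test")
  weights <- compute_weights(map, cutoff = cutoff)
  A <- smoothed_expr(map$expr, unique(c(pairs$ligand, pairs$receptor)),
                     weights)
  observed <- A[, pairs$ligand, drop = FALSE] *
    A[, pairs$receptor, drop = FALSE]
  colnames(observed) <- paste(pairs$ligand, pairs$receptor, sep = ":")
  null <- permutation_null(map, pairs, weights, n_perm = n_perm,
                           seed = seed)
  pv <- empirical_pvalues(observed, null, fdr_threshold)
  n_loc <- nrow(observed)
  tab <- data.frame(
    slide = rep(map$coords$slide, nrow(pairs)),
    location = rep(map$coords$location, nrow(pairs)),
    ligand = rep(pairs$ligand, each = n_loc),
    receptor = rep(pairs$receptor, each = n_loc),
    score = as.vector(observed), p = as.vector(pv$p),
    fdr = as.vector(pv$fdr), positive = as.vector(pv$positive),
    stringsAsFactors = FALSE)
  structure(list(table = tab, observed = observed, weights = weights,
                 pairs = pairs, n_perm = n_perm,
                 fdr_threshold = fdr_threshold,
                 fdr_family = "joint across all locations x pairs",
                 seed = seed),
            class = "rl_score_table")
}

#' @export
print.rl_score_table <- function(x, ...) {
  cat("Receptor-ligand co-localization:", nrow(x$pairs), "pairs x",
      nrow(x$observed), "locations,", x$n_perm, "permutations\n")
  cat(sprintf("  positive (FDR < %.2f): %d of %d tests\n",
              x$fdr_threshold, sum(x$table$positive), nrow(x$table)))
  invisible(x)
}

#' Region- or condition-wise enrichment of co-localization scores
#'
#' For every pair already significantly co-localizing in at least one
#' location of the tested group, fits the linear model
#' `score ~ in_group + detection_rate` (group vs all other locations,
#' blocking for per-location gene detection rate) and BH-adjusts the group
#' coefficients jointly across pairs x groups.
#'
#' @param scores An `rl_score_table`.
#' @param map The `spatial_map` the scores were computed on.
#' @param grouping `"region"` or `"condition"` (column of `map$coords`).
#' @return data.frame: group, ligand, receptor, estimate, p, fdr.
#' @export
crosstalk_enrichment <- function(scores, map,
                                 grouping = c("region", "condition")) {
  stopifnot(inherits(scores, "rl_score_table"), inherits(map, "spatial_map"))
  grouping <- match.arg(grouping)
  g <- map$coords[[grouping]]
  stop_if_not(length(unique(g)) >= 2,
              "need at least two groups for enrichment")
  det <- as.numeric(Matrix::colMeans(map$expr > 0))
  pos <- matrix(scores$table$positive, nrow = nrow(scores$observed))
  rows <- list()
  for (grp in sort(unique(g))) {
    ing <- g == grp
    for (j in seq_len(nrow(scores$pairs))) {
      if (!any(pos[ing, j])) next
      s <- scores$observed[, j]
      if (var(s) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = grp, ligand = scores$pairs$ligand[j],
          receptor = scores$pairs$receptor[j], estimate = 0, p = 1,
          stringsAsFactors = FALSE)
        next
      }
      fit <- lm(s ~ ing + det)
      cf <- summary(fit)$coefficients
      est <- if ("ingTRUE" %in% rownames(cf)) cf["ingTRUE", ] else c(0, NA, NA, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, ligand = scores$pairs$ligand[j],
        receptor = scores$pairs$receptor[j],
        estimate = unname(est[1]), p = unname(est[4]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(group = character(0), ligand = character(0),
                      receptor = character(0), estimate = numeric(0),
                      p = numeric(0), fdr = numeric(0)))
  }
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}

#' Classify locations by the occupancy of their neighborhood
#'
#' A location is `"near_bound"` if any drug-bound flagged cell lies within
#' the weight cutoff (self excluded), otherwise `"near_tcell"` if any other
#' T cell does, otherwise `"other"`.
#'
#' @param weights An `rl_weights` object.
#' @param bound Logical flag per location: drug-bound T cell.
#' @param tcell Logical flag per location: T cell.
#' @return Factor with levels `near_bound`, `near_tcell`, `other`.
#' @export
neighbor_classes <- function(weights, bound, tcell) {
  A <- weights$W > 0
  Matrix::diag(A) <- FALSE
  nb <- as.numeric(A %*% bound) > 0
  nt <- as.numeric(A %*% (tcell & !bound)) > 0
  factor(ifelse(nb, "near_bound", ifelse(nt, "near_tcell", "other")),
         levels = c("near_bound", "near_tcell", "other"))
}

#' Compare score distributions across neighbor classes
#'
#' Per-class medians and interquartile ranges plus pairwise two-sided
#' Wilcoxon rank-sum tests between all non-empty classes; comparisons
#' involving an empty class are reported as skipped.
#'
#' @param score Numeric score per location.
#' @param classes Factor of neighbor classes per location.
#' @return List with `summary` (class, n, median, q25, q75) and `tests`
#'   (class1, class2, p or NA when skipped).
#' @export
compare_scores_by_class <- function(score, classes) {
  stop_if_not(length(score) == length(classes),
              "score and classes lengths disagree")
  classes <- as.factor(classes)
  summ <- do.call(rbind, lapply(levels(classes), function(l) {
    s <- score[classes == l]
    data.frame(class = l, n = length(s),
               median = if (length(s)) median(s) else NA_real_,
               q25 = if (length(s)) unname(quantile(s, 0.25)) else NA_real_,
               q75 = if (length(s)) unname(quantile(s, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  cmb <- utils::combn(levels(classes), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    a <- score[classes == cmb[1, k]]
    b <- score[classes == cmb[2, k]]
    p <- if (length(a) && length(b)) {
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    } else NA_real_
    data.frame(class1 = cmb[1, k], class2 = cmb[2, k], p = p,
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}
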