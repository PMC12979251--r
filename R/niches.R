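#' Neighbor cell-type composition matrix
#'
#' For every cell, counts the cell types of its immediately adjacent
#' neighbors, excluding the cell itself. Adjacency is mutual k-nearest
#' neighbors with a radius cap, computed within each field of view (two
#' cells are neighbors iff each is among the other's k nearest and they lie
#' within `radius` of each other).
#'
#' @param cells data.frame with columns `x`, `y`, `fov` and `type`.
#' @param k Number of nearest neighbors considered (default 10).
#' @param radius Radius cap in coordinate units (default 30, micrometers
#'   for segmented-cell data).
#' @return Integer matrix, cells x types; row sums equal each cell's
#'   neighbor count. The adjacency rule is recorded in attribute `rule`.
#' @export
neighbor_composition <- function(cells, k = 10L, radius = 30) {
  stop_if_not(all(c("x", "y", "fov", "type") %in% colnames(cells)),
              "cells needs columns x, y, fov, type")
  type <- factor(cells$type)
  n <- nrow(cells)
  comp <- matrix(0L, n, nlevels(type),
                 dimnames = list(cells$cell, levels(type)))
  for (f in unique(cells$fov)) {
    idx <- which(cells$fov == f)
    if (length(idx) < 2L) next
    xy <- cbind(cells$x[idx], cells$y[idx])
    nn <- knn_index(xy, k)
    kk <- ncol(nn)
    ## mutual kNN with radius cap
    src <- rep(seq_along(idx), kk)
    dst <- as.vector(nn)
    d2 <- rowSums((xy[src, , drop = FALSE] - xy[dst, , drop = FALSE])^2)
    ok <- d2 <= radius^2
    key <- paste(pmin(src, dst), pmax(src, dst))
    mutual <- key %in% key[duplicated(key)]
    keep <- ok & mutual
    src <- src[keep]; dst <- dst[keep]
    tt <- as.integer(type[idx])
    inc <- table(factor(src, levels = seq_along(idx)),
                 factor(tt[dst], levels = seq_len(nlevels(type))))
    comp[idx, ] <- comp[idx, ] + matrix(as.integer(inc), length(idx))
  }
  attr(comp, "rule") <- sprintf("mutual %d-NN, radius cap %g, per FOV",
                                k, radius)
  comp
}

#' Cluster cells into spatial niches from neighbor composition
#'
#' Rows of the composition matrix are proportion-normalized, reduced by
#' principal components, and clustered by modularity optimization (Louvain)
#' on a k-nearest-neighbor graph at the given resolution. Niche mean
#' composition profiles are reported for annotation.
#'
#' @param comp Composition matrix from [neighbor_composition()].
#' @param resolution Modularity resolution (default 0.7, the resolution
#'   used for the segmented-cell clustering this mirrors).
#' @param n_pcs Number of principal components (capped at the column
#'   count).
#' @param graph_k Neighbors in the clustering graph (default 50).
#'   Composition rows are discrete counts, so many cells share identical
#'   profiles; the graph neighborhood must exceed typical duplicate-profile
#'   multiplicities or modularity clustering fragments into one community
#'   per profile.
#' @param seed Integer seed.
#' @return An object of class `niche_map`: `niche` (integer label per
#'   cell), `profiles` (niche x type mean composition, rows sum to 1),
#'   `resolution`.
#' @export
cluster_niches <- function(comp, resolution = 0.7, n_pcs = 10L,
                           graph_k = 50L, seed = 1L) {
  stop_if_not(nrow(comp) >= 2, "need at least two cells")
  rs <- rowSums(comp)
  prop <- comp / pmax(rs, 1L)
  if (all(apply(prop, 2, var) == 0)) {
    niche <- rep(1L, nrow(comp))
  } else {
    n_pcs <- min(n_pcs, ncol(prop), nrow(prop) - 1L)
    pc <- prcomp(prop, rank. = n_pcs)$x
    nn <- knn_index(pc, graph_k)
    edges <- cbind(rep(seq_len(nrow(pc)), ncol(nn)), as.vector(nn))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(seed)
    niche <- igraph::cluster_louvain(g, resolution = resolution)$membership
  }
  profiles <- do.call(rbind, lapply(sort(unique(niche)), function(i) {
    m <- colSums(comp[niche == i, , drop = FALSE])
    m / max(sum(m), 1)
  }))
  rownames(profiles) <- paste0("niche", sort(unique(niche)))
  structure(list(niche = niche, profiles = profiles,
                 resolution = resolution, seed = seed),
            class = "niche_map")
}

#' @export
print.niche_map <- function(x, ...) {
  cat("Spatial niches:", length(unique(x$niche)), "niches over",
      length(x$niche), "cells (resolution", x$resolution, ")\n")
  invisible(x)
}

#' Crypt-top cluster adjacency network
#'
#' Subsets locations to crypt-top spots (crypt-axis score above the
#' threshold), finds each spot's directly adjacent spots
#' (`0 < dist < dist_window[2]` in the same coordinate units), computes the
#' per-spot fraction of adjacent spots occupied by each region cluster, and
#' averages those fractions over the focal spots of each source cluster to
#' form directed edge weights. Self-loops (same-cluster adjacency) are
#' kept. Spots with no in-window neighbors contribute nothing.
#'
#' @param spots data.frame with `x`, `y`, `cluster`, `crypt_score` and
#'   optionally `slide`.
#' @param crypt_axis_threshold Crypt-top selection threshold (default 1.0).
#' @param dist_window Open distance interval defining adjacency (default
#'   `c(0, 4)`, in the map's downscaled-image units).
#' @return An object of class `cluster_adjacency`: `edges` data.frame
#'   (from, to, weight), the igraph `graph`, and `n_focal` per cluster.
#' @export
crypt_adjacency_network <- function(spots, crypt_axis_threshold = 1.0,
                                    dist_window = c(0, 4)) {
  stop_if_not(all(c("x", "y", "cluster", "crypt_score") %in% colnames(spots)),
              "spots needs columns x, y, cluster, crypt_score")
  if (!"slide" %in% colnames(spots)) spots$slide <- "slide1"
  top <- spots[spots$crypt_score > crypt_axis_threshold, , drop = FALSE]
  stop_if_not(nrow(top) > 0, "no spots pass the crypt-axis threshold")
  cl <- factor(top$cluster)
  frac_sum <- matrix(0, nlevels(cl), nlevels(cl),
                     dimnames = list(levels(cl), levels(cl)))
  n_focal <- setNames(numeric(nlevels(cl)), levels(cl))
  for (s in unique(top$slide)) {
    i <- which(top$slide == s)
    D <- pair_dist(cbind(top$x[i], top$y[i]))
    adj <- D > dist_window[1] & D < dist_window[2]
    for (a in seq_along(i)) {
      nb <- which(adj[a, ])
      if (!length(nb)) next
      fr <- table(cl[i][nb]) / length(nb)
      src <- as.character(cl[i][a])
      frac_sum[src, ] <- frac_sum[src, ] + as.numeric(fr)
      n_focal[src] <- n_focal[src] + 1
    }
  }
  w <- frac_sum / pmax(n_focal, 1)
  edges <- data.frame(from = rep(rownames(w), ncol(w)),
                      to = rep(colnames(w), each = nrow(w)),
                      weight = as.vector(w), stringsAsFactors = FALSE)
  edges <- edges[edges$weight > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = levels(cl))
  structure(list(edges = edges, graph = g, n_focal = n_focal,
                 crypt_axis_threshold = crypt_axis_threshold,
                 dist_window = dist_window),
            class = "cluster_adjacency")
}

#' @export
print.cluster_adjacency <- function(x, ...) {
  cat("Cluster adjacency network:", length(x$n_focal), "clusters,",
      nrow(x$edges), "edges (self-loops kept)\n")
  invisible(x)
}

#' Cell-type co-occurrence network
#'
#' All pairwise Pearson correlations of per-location cell-type scores
#' within each condition; edges are retained only for significantly
#' (p < `p_max`) positively correlated pairs with `r >= r_min`, diagonals
#' dropped. Correlation p-values use the t-distribution test of
#' `cor.test`. Constant score columns are excluded with a warning.
#'
#' @param type_scores Locations x types numeric matrix of cell-type
#'   probability scores.
#' @param condition Condition label per location.
#' @param r_min Minimum retained correlation (default 0.15).
#' @param p_max Maximum p-value (default 0.01).
#' @return Named list (one element per condition) of class
#'   `cooccurrence_network` objects with `edges` (type1, type2, r, p) and
#'   the igraph `graph`.
#' @export
cooccurrence_network <- function(type_scores, condition, r_min = 0.15,
                                 p_max = 0.01) {
  type_scores <- as.matrix(type_scores)
  stop_if_not(nrow(type_scores) == length(condition),
              "one condition label per location is required")
  out <- list()
  for (cond in sort(unique(condition))) {
    sc <- type_scores[condition == cond, , drop = FALSE]
    stop_if_not(nrow(sc) >= 3, "need at least 3 locations per condition")
    const <- apply(sc, 2, function(v) var(v) == 0)
    if (any(const)) {
      warning("constant score columns excluded in condition ", cond, ": ",
              paste(colnames(sc)[const], collapse = ", "))
      sc <- sc[, !const, drop = FALSE]
    }
    types <- colnames(sc)
    cmb <- utils::combn(seq_along(types), 2)
    edges <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      ct <- cor.test(sc[, cmb[1, k]], sc[, cmb[2, k]])
      data.frame(type1 = types[cmb[1, k]], type2 = types[cmb[2, k]],
                 r = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }))
    keep <- edges$r > 0 & edges$r >= r_min & edges$p < p_max
    edges <- edges[keep, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$type1, to = edges$type2, weight = edges$r),
      directed = FALSE, vertices = types)
    out[[cond]] <- structure(list(edges = edges, graph = g,
                                  condition = cond, r_min = r_min,
                                  p_max = p_max),
                             class = "cooccurrence_network")
  }
  out
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network (", x$condition, "): ", nrow(x$edges),
      " edges (p < ", x$p_max, ", r >= ", x$r_min, ")\n", sep = "")
  invisible(x)
}
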