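## Independent brute-force references used across tests. These stay naive
## on purpose: double loops and direct formula evaluation, no shared code
## with the package internals they check.

naive_rl_score <- function(map, pair, cutoff, self_weight = 1) {
  co <- map$coords
  n <- nrow(co)
  denom <- cutoff * (1 + 1e-6)
  L <- as.numeric(map$expr[pair[1], ])
  R <- as.numeric(map$expr[pair[2], ])
  S <- numeric(n)
  for (i in seq_len(n)) {
    sl <- 0; sr <- 0; cnt <- 0
    for (j in seq_len(n)) {
      if (co$slide[j] != co$slide[i]) next
      d <- sqrt((co$x[i] - co$x[j])^2 + (co$y[i] - co$y[j])^2)
      if (d > cutoff * (1 + 1e-9)) next
      w <- if (i == j) self_weight else min(1 - d / denom, 1)
      sl <- sl + w * L[j]
      sr <- sr + w * R[j]
      cnt <- cnt + 1
    }
    S[i] <- (sl / cnt) * (sr / cnt)
  }
  S
}

naive_adjacency_weights <- function(spots, threshold = 1.0, win = c(0, 4)) {
  if (!"slide" %in% colnames(spots)) spots$slide <- "slide1"
  top <- spots[spots$crypt_score > threshold, , drop = FALSE]
  cl <- factor(top$cluster)
  acc <- matrix(0, nlevels(cl), nlevels(cl),
                dimnames = list(levels(cl), levels(cl)))
  nf <- setNames(numeric(nlevels(cl)), levels(cl))
  for (s in unique(top$slide)) {
    i <- which(top$slide == s)
    for (a in i) {
      d <- sqrt((top$x[i] - top$x[a])^2 + (top$y[i] - top$y[a])^2)
      nb <- i[d > win[1] & d < win[2]]
      if (!length(nb)) next
      fr <- table(factor(top$cluster[nb], levels = levels(cl))) / length(nb)
      acc[as.character(top$cluster[a]), ] <-
        acc[as.character(top$cluster[a]), ] + as.numeric(fr)
      nf[as.character(top$cluster[a])] <- nf[as.character(top$cluster[a])] + 1
    }
  }
  acc / pmax(nf, 1)
}

naive_neighbor_counts <- function(cells, k = 10L, radius = 30) {
  n <- nrow(cells)
  counts <- integer(n)
  for (f in unique(cells$fov)) {
    idx <- which(cells$fov == f)
    if (length(idx) < 2) next
    D <- as.matrix(dist(cbind(cells$x[idx], cells$y[idx])))
    diag(D) <- Inf
    kk <- min(k, length(idx) - 1L)
    nnsets <- lapply(seq_along(idx), function(i) order(D[i, ])[seq_len(kk)])
    for (i in seq_along(idx)) {
      nb <- nnsets[[i]]
      mutual <- vapply(nb, function(j) i %in% nnsets[[j]], logical(1))
      counts[idx[i]] <- sum(mutual & D[i, nb] <= radius)
    }
  }
  counts
}

edge_weight_matrix <- function(net) {
  cls <- names(net$n_focal)
  m <- matrix(0, length(cls), length(cls), dimnames = list(cls, cls))
  for (k in seq_len(nrow(net$edges))) {
    m[net$edges$from[k], net$edges$to[k]] <- net$edges$weight[k]
  }
  m
}

## textbook Benjamini-Hochberg, written independently of stats::p.adjust
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

skewed_checkerboard_spots <- function(nr = 8, nc = 8) {
  sp <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  sp$x <- sp$col
  sp$y <- sp$row
  sp$cluster <- ifelse((sp$row + sp$col) %% 2 == 0, "A", "B")
  sp$crypt_score <- 2
  sp
}
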