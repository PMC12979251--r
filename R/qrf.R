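#' Train a quantile regression forest
#'
#' Fits a random forest regression (via \pkg{ranger}) and indexes, for every
#' tree, the training response values falling in each terminal node. That
#' index is what turns the forest into a quantile regression forest: for a
#' new point x, the conditional distribution estimate is the average over
#' trees of the empirical distribution of training responses sharing x's
#' leaf, which yields conditional quantiles, the conditional CDF, and
#' conditional sampling — not just a mean.
#'
#' @param x Numeric feature matrix or data.frame (one row per cell).
#' @param y Numeric response (e.g., CLR-normalized PD-1 tag signal).
#' @param num_trees Number of trees (default 500).
#' @param min_node_size Minimum terminal node size (default 50; the leaf
#'   populations are the resolution of the conditional distributions, so
#'   leaves are kept a little larger than for mean prediction).
#' @param mtry Features tried per split (default `max(floor(p/3), 1)`, the
#'   regression-forest standard).
#' @param min_train Minimum number of training rows (default 50).
#' @param seed Integer seed.
#' @return An object of class `qrf`.
#' @export
train_qrf <- function(x, y, num_trees = 500L, min_node_size = 50L,
                      mtry = NULL, min_train = 50L, seed = 1L) {
  x <- as.data.frame(x)
  stop_if_not(nrow(x) == length(y), "x and y sizes disagree")
  stop_if_not(nrow(x) >= min_train,
              sprintf("need at least %d training cells", min_train))
  if (is.null(mtry)) mtry <- max(floor(ncol(x) / 3), 1L)
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        min.node.size = min_node_size, mtry = mtry,
                        seed = seed, num.threads = 1L,
                        respect.unordered.factors = "order")
  nodes <- predict(fit, x, type = "terminalNodes",
                   num.threads = 1L)$predictions
  index <- lapply(seq_len(num_trees), function(t) {
    o <- order(nodes[, t], y)
    r <- rle(nodes[o, t])
    list(leaves = r$values,
         len = r$lengths,
         off = cumsum(c(0L, r$lengths[-length(r$lengths)])),
         y = y[o])
  })
  structure(list(forest = fit, index = index, y = y,
                 feature_names = colnames(x), num_trees = num_trees,
                 min_node_size = min_node_size, mtry = mtry, seed = seed,
                 n_train = nrow(x)),
            class = "qrf")
}

#' @export
print.qrf <- function(x, ...) {
  cat("Quantile regression forest:", x$num_trees, "trees,",
      x$n_train, "training cells,", length(x$feature_names), "features\n")
  invisible(x)
}

qrf_nodes <- function(object, newdata) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss)) {
    stop("newdata is missing features: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  predict(object$forest, newdata[, object$feature_names, drop = FALSE],
          type = "terminalNodes", num.threads = 1L)$predictions
}

## Conditional CDF evaluated at per-row values: u_i = Fhat(y_i | x_i),
## the leaf-weighted fraction of training responses <= y_i (weak
## inequality, so ties at the conditional minimum give u > 0).
qrf_cdf_at <- function(object, nodes, values) {
  m <- nrow(nodes)
  u <- numeric(m)
  for (t in seq_len(object$num_trees)) {
    it <- object$index[[t]]
    pos <- match(nodes[, t], it$leaves)
    for (p in unique(pos)) {
      i <- which(pos == p)
      seg <- it$y[(it$off[p] + 1L):(it$off[p] + it$len[p])]
      u[i] <- u[i] + findInterval(values[i], seg) / it$len[p]
    }
  }
  u / object$num_trees
}

## Conditional CDF on a fixed grid of response values; returns m x K matrix
## with non-decreasing rows. The grid spans the training response range, so
## the last column is exactly 1.
qrf_cdf_grid <- function(object, nodes, grid) {
  m <- nrow(nodes)
  K <- length(grid)
  FF <- matrix(0, m, K)
  for (t in seq_len(object$num_trees)) {
    it <- object$index[[t]]
    pos <- match(nodes[, t], it$leaves)
    ul <- unique(pos)
    leafF <- matrix(0, length(ul), K)
    for (j in seq_along(ul)) {
      p <- ul[j]
      seg <- it$y[(it$off[p] + 1L):(it$off[p] + it$len[p])]
      leafF[j, ] <- findInterval(grid, seg) / it$len[p]
    }
    FF <- FF + leafF[match(pos, ul), , drop = FALSE]
  }
  FF / object$num_trees
}

default_grid <- function(y, grid_size = 257L) {
  g <- unique(as.numeric(quantile(y, seq(0, 1, length.out = grid_size),
                                  type = 1)))
  sort(unique(c(min(y), g, max(y))))
}

#' Predict from a quantile regression forest
#'
#' @param object A `qrf` model.
#' @param newdata Feature data.frame/matrix with the training columns.
#' @param type One of:
#'   \describe{
#'     \item{`"quantiles"`}{conditional quantiles at `quantiles`; a matrix
#'       with one column per tau, monotone non-decreasing in tau by
#'       construction.}
#'     \item{`"cdf"`}{the conditional CDF evaluated at the per-row values
#'       `y` (weak `<=` convention).}
#'     \item{`"recall_prob"`}{per row, the probability that a fresh draw
#'       Y* from the conditional distribution satisfies
#'       `Fhat(Y* | x) < alpha` — the re-call probability used by
#'       Monte-Carlo confidence intervals on bound fractions.}
#'     \item{`"sample"`}{`ndraws` draws per row from the conditional
#'       distribution (tree chosen uniformly, then a training response
#'       uniformly within the row's leaf).}
#'   }
#' @param quantiles Numeric vector of quantile levels for
#'   `type = "quantiles"`.
#' @param y Per-row evaluation values for `type = "cdf"` (recycled if
#'   length 1).
#' @param alpha Tail level for `type = "recall_prob"`.
#' @param ndraws Number of draws for `type = "sample"`.
#' @param grid_size Resolution of the response grid backing quantile and
#'   re-call-probability evaluation.
#' @param seed Seed for `type = "sample"`.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.qrf <- function(object, newdata,
                        type = c("quantiles", "cdf", "recall_prob", "sample"),
                        quantiles = c(0.1, 0.5, 0.9), y = NULL, alpha = 0.05,
                        ndraws = 200L, grid_size = 257L, seed = 1L, ...) {
  type <- match.arg(type)
  nodes <- qrf_nodes(object, newdata)
  m <- nrow(nodes)
  if (type == "cdf") {
    stop_if_not(!is.null(y), "type='cdf' needs evaluation values y")
    values <- rep_len(as.numeric(y), m)
    return(qrf_cdf_at(object, nodes, values))
  }
  if (type == "sample") {
    return(qrf_sample(object, nodes, ndraws, seed))
  }
  g <- default_grid(object$y, grid_size)
  FF <- qrf_cdf_grid(object, nodes, g)
  if (type == "quantiles") {
    stop_if_not(all(quantiles > 0 & quantiles <= 1),
                "quantile levels must lie in (0,1]")
    Q <- vapply(quantiles, function(tau) {
      g[max.col(FF >= tau - 1e-12, ties.method = "first")]
    }, numeric(m))
    Q <- matrix(Q, nrow = m)
    colnames(Q) <- paste0("q", quantiles)
    return(Q)
  }
  ## recall_prob: largest attainable CDF value strictly below alpha
  p <- numeric(m)
  for (k in seq_along(g)) {
    fk <- FF[, k]
    p <- pmax(p, fk * (fk < alpha))
  }
  p
}

qrf_sample <- function(object, nodes, ndraws, seed) {
  set.seed(seed)
  m <- nrow(nodes)
  S <- matrix(NA_real_, m, ndraws)
  tr <- matrix(sample.int(object$num_trees, m * ndraws, replace = TRUE),
               m, ndraws)
  for (t in sort(unique(as.vector(tr)))) {
    entries <- which(tr == t)
    cells <- (entries - 1L) %% m + 1L
    it <- object$index[[t]]
    pos <- match(nodes[cells, t], it$leaves)
    len <- it$len[pos]
    pick <- pmin(floor(runif(length(entries)) * len) + 1L, len)
    S[entries] <- it$y[it$off[pos] + pick]
  }
  S
}
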