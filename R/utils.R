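#' @importFrom stats rnbinom rnorm runif rbinom quantile median var sd
#'   p.adjust lm wilcox.test cor cor.test qnbinom qpois prcomp complete.cases
#'   coef predict setNames
#' @importFrom utils head write.table
#' @importFrom methods as
NULL

## Blocked k-nearest-neighbour search via the crossprod distance identity.
## Returns index matrix (n x k) excluding self. Exact, O(n^2) work but
## BLAS-bound, fine up to a few tens of thousands of points.
knn_index <- function(x, k, block = 1024L) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- min(k, n - 1L)
  if (n <= 1L || k < 1L) {
    return(matrix(integer(0), nrow = n, ncol = max(k, 0L)))
  }
  sq <- rowSums(x^2)
  idx <- matrix(NA_integer_, n, k)
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, n)
    rows <- s:e
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(x[rows, , drop = FALSE], x)
    d2[cbind(seq_along(rows), rows)] <- Inf   # exclude self
    for (i in seq_along(rows)) {
      v <- d2[i, ]
      th <- sort.int(v, partial = k)[k]
      cand <- which(v <= th)
      idx[rows[i], ] <- cand[order(v[cand])][seq_len(k)]
    }
  }
  idx
}

## Pairwise Euclidean distances between rows of a coordinate matrix.
pair_dist <- function(xy) {
  as.matrix(stats::dist(xy))
}

## Moment/ML negative binomial fit on non-negative integer counts.
## Returns list(mu, size); size = Inf marks the Poisson limit
## (sample variance <= mean).
fit_nb <- function(x) {
  x <- as.numeric(x)
  m <- mean(x)
  v <- var(x)
  if (!is.finite(m) || m <= 0) {
    return(list(mu = m, size = Inf))
  }
  if (is.na(v) || v <= m) {
    return(list(mu = m, size = Inf))
  }
  size <- m^2 / (v - m)
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(x, "negative binomial",
                                    start = list(size = size, mu = m),
                                    lower = c(1e-6, 1e-6))),
    error = function(e) NULL
  )
  if (!is.null(fit) && all(is.finite(fit$estimate))) {
    return(list(mu = unname(fit$estimate["mu"]),
                size = unname(fit$estimate["size"])))
  }
  list(mu = m, size = size)
}

## Upper quantile of the fitted count distribution.
nb_quantile <- function(fit, p) {
  if (!is.finite(fit$mu) || fit$mu <= 0) return(Inf)
  if (is.infinite(fit$size)) qpois(p, lambda = fit$mu) else {
    qnbinom(p, size = fit$size, mu = fit$mu)
  }
}

## Draw a sub-seed deterministically from a base seed (kept < 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 12347) %% 2147483587)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
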