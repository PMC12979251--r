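make_small_dataset <- function(n = 600, seed = 1) {
  simulate_citeseq(cite_sim_config(n_cells = n, seed = seed))
}

test_that("feature assembly produces the expected families, no NAs", {
  sim <- make_small_dataset(300, 2)
  f <- assemble_features(sim$dataset)
  expect_true(all(paste0("emb_", 1:30) %in% colnames(f)))
  expect_true(all(c("s_score", "g2m_score", "total_counts", "detect_rate",
                    "mito_pct", "ribo_pct", "pdcd1") %in% colnames(f)))
  expect_true(any(grepl("^phase_", colnames(f))))
  expect_true(any(grepl("^reaction_", colnames(f))))
  expect_false(anyNA(f))
  ## detection rate is the fraction of genes with count > 0
  i <- 5
  expect_equal(f$detect_rate[i],
               sum(sim$dataset$counts[, i] > 0) / nrow(sim$dataset$counts))
  ## zero PDCD1 counts map to a zero normalized feature
  z <- which(sim$dataset$counts["PDCD1", ] == 0)[1]
  expect_equal(f$pdcd1[z], 0)

  noemb <- sim$dataset
  noemb$embedding <- NULL
  expect_error(assemble_features(noemb), "embedding")
})

test_that("quantile forest handles a constant target degenerately", {
  set.seed(3)
  x <- data.frame(a = rnorm(120), b = rnorm(120))
  m <- train_qrf(x, rep(2.5, 120), num_trees = 50, seed = 1)
  q <- predict(m, x[1:10, ], type = "quantiles",
               quantiles = c(0.01, 0.5, 0.99))
  expect_true(all(q == 2.5))
  ## measured equal to the constant: u = 1 under the <= convention
  u <- predict(m, x[1:10, ], type = "cdf", y = 2.5)
  expect_equal(u, rep(1, 10))
  ## measured below every training value: u = 0
  expect_equal(predict(m, x[1:5, ], type = "cdf", y = 0), rep(0, 5))
})

test_that("quantile forest approaches closed-form normal quantiles", {
  set.seed(4)
  n <- 4000
  x <- data.frame(x = rnorm(n))
  y <- rnorm(n, x$x, 1)
  m <- train_qrf(x, y, num_trees = 300, seed = 4)
  xt <- data.frame(x = rnorm(800))
  q <- predict(m, xt, type = "quantiles", quantiles = c(0.1, 0.9))
  ## N(x, 1): q90 - q10 = 2 * 1.2816 = 2.563
  expect_equal(mean(q[, 2] - q[, 1]), 2.563, tolerance = 0.15)
  ## u at the conditional center is near 1/2
  u <- predict(m, xt, type = "cdf", y = xt$x)
  expect_equal(mean(u), 0.5, tolerance = 0.03)
})

test_that("quantiles are monotone in tau for every cell and reruns agree", {
  set.seed(5)
  x <- data.frame(a = rnorm(300), b = runif(300))
  y <- rnorm(300, x$a)
  m <- train_qrf(x, y, num_trees = 80, seed = 7)
  taus <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  q <- predict(m, x, type = "quantiles", quantiles = taus)
  expect_true(all(diff(t(q)) >= 0))
  m2 <- train_qrf(x, y, num_trees = 80, seed = 7)
  expect_identical(predict(m2, x, type = "quantiles", quantiles = taus), q)
  expect_error(train_qrf(x[1:10, ], y[1:10]), "at least")
})

test_that("conditional sampling draws from the leaf distributions", {
  set.seed(6)
  x <- data.frame(x = rnorm(2000))
  y <- rnorm(2000, x$x, 1)
  m <- train_qrf(x, y, num_trees = 200, seed = 2)
  xt <- data.frame(x = c(-1, 0, 1))
  s <- predict(m, xt, type = "sample", ndraws = 4000, seed = 9)
  expect_equal(dim(s), c(3, 4000))
  expect_equal(rowMeans(s), xt$x, tolerance = 0.2)
  expect_equal(apply(s, 1, sd), rep(1, 3), tolerance = 0.2)
})

test_that("recursive selection keeps informative features, drops noise", {
  set.seed(8)
  n <- 1500
  f <- as.data.frame(matrix(rnorm(n * 13), n,
                            dimnames = list(NULL, paste0("f", 1:13))))
  target <- f$f1   # exact copy of one feature
  sel <- select_features(f, target, num_trees = 60, seed = 1)
  expect_true("f1" %in% sel$selected)
  expect_lte(length(sel$selected), 3)

  ## linear in 3 features + noise, the rest distractors
  target2 <- f$f1 + f$f2 + f$f3 + rnorm(n, 0, 0.3)
  sel2 <- select_features(f, target2, num_trees = 120, seed = 2)
  expect_true(all(c("f1", "f2", "f3") %in% sel2$selected))

  ## threshold 0 keeps everything
  sel0 <- select_features(f, target2, importance_threshold = 0,
                          num_trees = 40, seed = 3)
  expect_equal(sort(sel0$selected), sort(colnames(f)))

  ## pure-noise target cannot satisfy a positive threshold
  expect_error(select_features(f[, 1:3], rnorm(n), num_trees = 40,
                               importance_threshold = 60, seed = 4),
               "threshold")
})

test_that("bound calls follow the one-sided rule and nest across levels", {
  u <- c(0.5, 0.02, 0.005, 0.12, 1, 0)
  calls <- call_bound(u)
  expect_false(any(as.matrix(calls$calls[1, paste0("bound_",
    c(0.01, 0.05, 0.1, 0.15))])))      # u = 0.5 unbound everywhere
  expect_equal(unname(unlist(calls$calls[2, paste0("bound_",
    c(0.01, 0.05, 0.1, 0.15))])), c(FALSE, TRUE, TRUE, TRUE))
  ## nestedness is exact
  b <- as.matrix(calls$calls[, paste0("bound_", c(0.01, 0.05, 0.1, 0.15))])
  for (k in 1:3) expect_true(all(b[, k] <= b[, k + 1]))
  expect_error(call_bound(u, alphas = c(0.05, 0.7)), "alphas")
  expect_error(call_bound(c(-0.1, 0.5)), "0,1")
})

test_that("validation reports correlation and flags weak models", {
  set.seed(10)
  x <- data.frame(x = runif(800))
  y <- 3 * x$x   # noiseless deterministic target
  m <- train_qrf(x, y, num_trees = 100, min_node_size = 5, seed = 1)
  xt <- data.frame(x = runif(200))
  v <- validate_qrf(m, xt, 3 * xt$x)
  expect_gt(v$r, 0.97)
  expect_false(v$flagged)
  v2 <- validate_qrf(m, xt, rnorm(200), floor = 0.9)
  expect_true(v2$flagged)
})

test_that("fitted occupancy model validates on both hold-out designs", {
  sim <- simulate_citeseq(cite_sim_config(n_cells = 3000, seed = 21))
  bm <- fit_binding_model(sim$dataset, select = FALSE, num_trees = 150,
                          seed = 3)
  expect_s3_class(bm, "binding_model")
  ## the design includes an entirely held-out untreated donor
  expect_false(is.null(bm$validation$donor_holdout))
  expect_false(sim$dataset$meta$treated[
    sim$dataset$meta$donor == bm$validation$holdout_donor][1])
  ## model beats the global-mean predictor (r = 0) on both sets
  expect_gt(bm$validation$random_holdout$r, 0.5)
  expect_gt(bm$validation$donor_holdout$r, 0.5)
})

test_that("cluster bound fractions: zero-bound clusters and CI structure", {
  sim <- simulate_citeseq(cite_sim_config(n_cells = 2500, seed = 22))
  bm <- fit_binding_model(sim$dataset, select = FALSE, num_trees = 150,
                          seed = 5)
  calls <- predict(bm, sim$dataset)
  treated <- which(sim$dataset$meta$treated)
  cl <- sim$dataset$meta$cluster[treated]
  cf <- cluster_bound_fractions(bm, calls, cl, alpha = 0.05,
                                n_draws = 100, seed = 2)
  expect_equal(sort(unique(cf$cluster)), sort(unique(as.character(cl))))
  expect_true(all(cf$ci_lo <= cf$ci_hi))
  expect_true(all(cf$fraction >= 0 & cf$fraction <= 1))
  ## a cluster with no bound cells has fraction 0; its CI floor is 0
  fake_cl <- cl
  fake_cl[calls$calls$bound_0.05] <- "hasbound"
  cf2 <- cluster_bound_fractions(bm, calls, fake_cl, alpha = 0.05,
                                 n_draws = 50, seed = 2)
  clean <- cf2[cf2$cluster != "hasbound", ]
  expect_true(all(clean$fraction == 0))
  expect_true(all(clean$ci_lo >= 0))
})
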