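test_that("weights follow the linear two-ring scheme", {
  ## 3 collinear spots at unit spacing, cutoff 2: hand-computed weights
  map <- structure(list(
    coords = data.frame(location = c("a", "b", "c"), x = c(0, 1, 2),
                        y = 0, slide = "s1", stringsAsFactors = FALSE),
    expr = matrix(1, 1, 3, dimnames = list("g1", c("a", "b", "c"))),
    pitch = 1, units = "u"), class = "spatial_map")
  w <- compute_weights(map)
  W <- as.matrix(w$W)
  denom <- 2 * (1 + 1e-6)
  expect_equal(W[2, 1], 1 - 1 / denom)
  expect_equal(W[2, 3], 1 - 1 / denom)
  expect_equal(W[1, 3], 1 - 2 / denom)   # exactly at the cutoff: tiny, > 0
  expect_gt(W[1, 3], 0)
  expect_equal(diag(W), rep(1, 3))
  expect_equal(w$n, c(3, 3, 3))

  ## isolated location: only itself
  map$coords <- rbind(map$coords,
                      data.frame(location = "far", x = 100, y = 0,
                                 slide = "s1"))
  map$expr <- cbind(map$expr, far = 1)
  w2 <- compute_weights(map)
  expect_equal(w2$n[4], 1)
  expect_equal(sum(as.matrix(w2$W)[4, ]), 1)

  ## hex lattice: anything beyond two rings (2 * pitch) gets zero weight
  sim <- simulate_spatial(spatial_sim_config(n_rows = 9, n_cols = 9,
                                             seed = 1))
  wh <- compute_weights(sim$map)
  co <- sim$map$coords
  D <- as.matrix(dist(cbind(co$x, co$y)))
  expect_true(all(as.matrix(wh$W)[D > 2 * (1 + 1e-6)] == 0))
  expect_true(all(as.matrix(wh$W)[D <= 2] > 0))
})

test_that("vectorized score equals the naive O(n^2) oracle", {
  sim <- simulate_spatial(spatial_sim_config(n_rows = 10, n_cols = 20,
                                             seed = 4))
  w <- compute_weights(sim$map)
  for (pr in list(c("g1", "g2"), c("g5", "g6"))) {
    fast <- rl_score(sim$map, pr, w)
    slow <- naive_rl_score(sim$map, pr, cutoff = 2)
    expect_lt(max(abs(fast - slow)), 1e-10)
  }
  ## symmetry under ligand <-> receptor swap
  expect_equal(rl_score(sim$map, c("g1", "g2"), w),
               rl_score(sim$map, c("g2", "g1"), w))
  ## all-zero ligand: zero scores
  z <- sim$map
  z$expr["g1", ] <- 0
  expect_true(all(rl_score(z, c("g1", "g2"), w) == 0))
  expect_error(rl_score(sim$map, c("nope", "g2"), w), "nope")
})

test_that("scores are invariant to coordinate translation", {
  sim <- simulate_spatial(spatial_sim_config(n_rows = 8, n_cols = 8,
                                             seed = 5))
  w1 <- compute_weights(sim$map)
  shifted <- sim$map
  shifted$coords$x <- shifted$coords$x + 50
  shifted$coords$y <- shifted$coords$y - 20
  w2 <- compute_weights(shifted)
  expect_equal(rl_score(sim$map, c("g1", "g2"), w1),
               rl_score(shifted, c("g1", "g2"), w2))
})

test_that("permutation machinery: degenerate null, p-value floor, BH", {
  sim <- simulate_spatial(spatial_sim_config(n_rows = 5, n_cols = 5,
                                             seed = 6))
  sim$map$expr[] <- 3   # constant expression
  w <- compute_weights(sim$map)
  pairs <- sim$map$pairs[1, , drop = FALSE]
  null <- permutation_null(sim$map, pairs, w, n_perm = 5, seed = 1)
  obs <- rl_score(sim$map, c(pairs$ligand, pairs$receptor), w)
  ## constant profiles: every permutation reproduces the observed score
  ## multiset exactly (scores vary by location only through the lattice
  ## edge geometry, which shuffling cannot change)
  expect_equal(as.numeric(null), sort(rep(obs, 5)))
  pv <- empirical_pvalues(matrix(obs), null)
  expect_equal(sum(pv$positive), 0)
  ## the smallest observed score is at or below all of the null: p = 1
  expect_equal(max(pv$p), 1)
  ## single location: the null is degenerate at the observed value
  one <- simulate_spatial(spatial_sim_config(n_rows = 1, n_cols = 1,
                                             n_genes = 4, n_rl_pairs = 1,
                                             seed = 6))
  w1 <- compute_weights(one$map)
  o1 <- rl_score(one$map, c("g1", "g2"), w1)
  n1 <- permutation_null(one$map, one$map$pairs, w1, n_perm = 7, seed = 1)
  expect_true(all(n1 == o1))
  expect_equal(as.numeric(empirical_pvalues(matrix(o1), n1)$p), 1)

  ## observed score of 0 against a positive null: p = 1
  pv0 <- empirical_pvalues(matrix(0), matrix(sort(runif(100) + 1)))
  expect_equal(as.numeric(pv0$p), 1)
  expect_error(permutation_null(sim$map, pairs, w, n_perm = 0), "one")
})

test_that("BH adjustment agrees exactly with an independent implementation", {
  set.seed(7)
  p <- runif(400)^2
  expect_equal(p.adjust(p, method = "BH"), naive_bh(p))
  ## and the table path uses the same joint correction
  sim <- simulate_spatial(spatial_sim_config(n_rows = 6, n_cols = 6,
                                             n_rl_pairs = 3, n_genes = 10,
                                             seed = 8))
  ra <- rl_analysis(sim$map, n_perm = 20, seed = 8)
  expect_equal(ra$table$fdr, naive_bh(ra$table$p))
})

test_that("default analysis uses 100 permutations and flags FDR positives", {
  sim <- simulate_spatial(spatial_sim_config(n_rows = 6, n_cols = 6,
                                             n_rl_pairs = 2, n_genes = 8,
                                             seed = 9))
  ra <- rl_analysis(sim$map, seed = 9)
  expect_equal(ra$n_perm, 100)
  expect_equal(ra$table$positive, ra$table$fdr < 0.05)
  expect_true(all(ra$table$p >= 1 / (1 + 100 * nrow(sim$map$coords))))
})

test_that("different permutation seeds give consistent p-value rates", {
  sim <- simulate_spatial(spatial_sim_config(n_rows = 12, n_cols = 15,
                                             n_rl_pairs = 5, n_genes = 14,
                                             seed = 10))
  r1 <- rl_analysis(sim$map, n_perm = 50, seed = 1)
  r2 <- rl_analysis(sim$map, n_perm = 50, seed = 99)
  expect_false(identical(r1$table$p, r2$table$p))
  expect_lt(abs(mean(r1$table$p < 0.05) - mean(r2$table$p < 0.05)), 0.03)
})

test_that("enrichment finds a planted region effect and survives degeneracy", {
  sim <- simulate_spatial(spatial_sim_config(n_rows = 16, n_cols = 20,
                                             n_rl_pairs = 4, n_genes = 12,
                                             n_regions = 2, seed = 12,
    planted_pairs = list(list(pair = 1, center = c(3, 4), radius = 3.2,
                              fold = 3))))
  ## the disc sits inside region1 (left band)
  ra <- rl_analysis(sim$map, n_perm = 100, seed = 12)
  enr <- crosstalk_enrichment(ra, sim$map, grouping = "region")
  hit <- enr[enr$group == "region1" & enr$ligand == "g1", ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$estimate, 0)
  expect_lt(hit$fdr, 0.05)

  ## zero-variance scores are handled without a crash
  flat <- ra
  flat$observed[, 1] <- 0
  flat$table$positive[seq_len(nrow(sim$map$coords))] <- TRUE
  enr2 <- crosstalk_enrichment(flat, sim$map, grouping = "region")
  row1 <- enr2[enr2$ligand == "g1" & enr2$group == "region1", ]
  expect_equal(row1$estimate, 0)
  expect_equal(row1$p, 1)
  one <- sim$map
  one$coords$region <- "only"
  expect_error(crosstalk_enrichment(ra, one, grouping = "region"), "two")
})

test_that("neighbor-class comparison summarizes and detects planted shifts", {
  sim <- simulate_spatial(spatial_sim_config(n_rows = 10, n_cols = 15,
                                             seed = 13))
  w <- compute_weights(sim$map)
  n <- nrow(sim$map$coords)
  set.seed(13)
  bound <- runif(n) < 0.08
  tcell <- bound | runif(n) < 0.2
  cls <- neighbor_classes(w, bound, tcell)
  expect_true(all(levels(cls) == c("near_bound", "near_tcell", "other")))

  ## identical distributions: rank test should not reject at tiny p
  score0 <- rnorm(n)
  cmp0 <- compare_scores_by_class(score0, cls)
  expect_true(all(cmp0$tests$p > 1e-4, na.rm = TRUE))

  ## planted +1 shift near bound cells is detected
  score1 <- rnorm(n) + (cls == "near_bound")
  cmp1 <- compare_scores_by_class(score1, cls)
  expect_lt(cmp1$tests$p[cmp1$tests$class1 == "near_bound" &
                           cmp1$tests$class2 == "near_tcell"], 0.01)
  expect_equal(cmp1$summary$n, as.vector(table(cls)))

  ## a single non-empty class: summaries only, comparisons skipped
  cmp2 <- compare_scores_by_class(score1[cls == "other"],
                                  factor(rep("other", sum(cls == "other")),
                                         levels = levels(cls)))
  expect_true(all(is.na(cmp2$tests$p)))
})
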