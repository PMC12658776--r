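test_that("permutation p has the add-one form, bounds and null behaviour", {
  set.seed(1)
  # predictions that beat every shuffle: p = 1/1001 < 0.001
  pred <- rep(c(0, 1), each = 50)
  res <- permutation_test_acc(pred, pred, n_perm = 1000, rng_seed = 2)
  expect_equal(res$observed, 1)
  expect_equal(res$p, 1 / 1001)
  expect_lt(res$p, 0.001)
  # chance-level predictions on balanced labels: p near 0.5
  res2 <- permutation_test_acc(sample(pred), pred, n_perm = 1000,
                               rng_seed = 3)
  expect_gt(res2$p, 0.2); expect_lt(res2$p, 0.8)
  # n_perm = 1, observed below the permuted value: p = 1
  res3 <- permutation_test_acc(c(0, 1), c(1, 0), n_perm = 1, rng_seed = 4)
  expect_equal(res3$p, 1)
  expect_gte(res3$p, 1 / 2)
})

test_that("permutation p is near-uniform under a random classifier", {
  set.seed(5)
  pvals <- vapply(1:200, function(r) {
    truth <- rbinom(40, 1, 0.5)
    pred <- rbinom(40, 1, 0.5)
    permutation_test_acc(pred, truth, n_perm = 99, rng_seed = 100 + r)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
  # validity: P(p <= alpha) does not exceed alpha by more than noise
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / 200))
})

test_that("voxelwise group test reduces to the pooled t and finds effects", {
  set.seed(6)
  nA <- 12; nB <- 15; V <- 200
  maps <- rbind(matrix(rnorm(nA * V), nA, V), matrix(rnorm(nB * V), nB, V))
  group <- rep(c("MSP", "SSP"), c(nA, nB))
  sm <- voxelwise_group_ttest(maps, group, covariate_table = NULL,
                              params = stat_params(covariates = character(0)))
  expect_equal(sm$df, nA + nB - 2)
  # closed-form pooled two-sample t oracle
  for (v in c(1, 50, 200)) {
    a <- maps[group == "MSP", v]; b <- maps[group == "SSP", v]
    sp2 <- ((nA - 1) * var(a) + (nB - 1) * var(b)) / (nA + nB - 2)
    oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / nA + 1 / nB))
    expect_equal(sm$t[v], oracle, tolerance = 1e-10)
  }
  # identical groups, no covariate effect: t ~ 0 everywhere
  maps0 <- rbind(maps[1:12, ], maps[1:12, ])
  sm0 <- voxelwise_group_ttest(maps0, rep(c("MSP", "SSP"), each = 12),
                               params = stat_params(covariates = character(0)))
  expect_lt(max(abs(sm0$t)), 1e-8)
  # with covariates: df = n - 5 and NA rows are dropped
  covs <- data.frame(age_years = rnorm(nA + nB, 50, 10),
                     sex = sample(c("male", "female"), nA + nB, TRUE),
                     duration_months = runif(nA + nB, 3, 24))
  maps_na <- maps; maps_na[3, ] <- NA
  sm2 <- voxelwise_group_ttest(maps_na, group, covs)
  expect_equal(sm2$df, nA + nB - 1 - 5)
  expect_equal(sm2$n_dropped, 1)
  covs$dup <- covs$age_years
  expect_error(
    voxelwise_group_ttest(maps, group, covs,
                          stat_params(covariates = c("age_years", "dup"))),
    "collinear")
})

test_that("null false-positive rate at |t| > 2 matches the analytic tail", {
  set.seed(7)
  nA <- 32; nB <- 32; V <- 20000
  maps <- matrix(rnorm((nA + nB) * V), nA + nB, V)
  group <- rep(c("MSP", "SSP"), c(nA, nB))
  covs <- data.frame(age_years = rnorm(nA + nB, 50, 10),
                     sex = sample(c("male", "female"), nA + nB, TRUE),
                     duration_months = runif(nA + nB, 3, 24))
  sm <- voxelwise_group_ttest(maps, group, covs)
  expect_equal(sm$df, 59)
  fpr <- mean(abs(sm$t) > 2)
  expected <- 2 * pt(-2, df = 59)
  expect_lt(abs(fpr - expected), 4 * sqrt(expected * (1 - expected) / V))
})

test_that("cluster labelling agrees with an independent graph oracle", {
  skip_if_no("igraph")
  set.seed(8)
  for (i in 1:50) {
    mask <- array(runif(12^3) < 0.22, c(12, 12, 12))
    conn <- sample(c(6L, 18L, 26L), 1)
    got <- label_components(mask, conn)
    oracle <- igraph_components(mask, conn)
    expect_true(same_partition(got, oracle))
  }
  # two blobs joined by one face-adjacent voxel are one component at 6
  m <- array(FALSE, c(9, 5, 5))
  m[1:3, 1:2, 1:2] <- TRUE; m[5:7, 1:2, 1:2] <- TRUE; m[4, 1, 1] <- TRUE
  expect_equal(max(label_components(m, 6L)), 1)
  m[4, 1, 1] <- FALSE
  expect_equal(max(label_components(m, 6L)), 2)
})

test_that("cluster-extent filtering enforces the 50-voxel rule", {
  spec <- acq_canonical()
  d <- spec$grid_dims
  tvol <- array(0, d)
  # a 49-voxel suprathreshold blob and a 50-voxel one
  tvol[1:7, 1:7, 1] <- 3        # 49 voxels
  tvol[20:29, 30:34, 10] <- 3   # 50 voxels
  tvol[40:49, 40:49, 30:31] <- -4  # 200 voxels, negative direction
  tab <- cluster_extent_filter(as.vector(tvol), spec,
                               stat_params(min_cluster_voxels = 50))
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$cluster_voxels, c(50, 200))
  expect_equal(tab$direction[tab$peak_t < 0], "MSP < SSP")
  expect_equal(attr(tab, "correction"), "uncorrected")
  # peak coordinate maps through the affine
  neg <- tab[tab$direction == "MSP < SSP", ]
  ijk <- mm_to_voxel(spec, c(neg$peak_x, neg$peak_y, neg$peak_z))
  expect_true(all(round(ijk[1:2]) %in% 40:49))
})

test_that("significant clusters overlap the planted effect region", {
  spec <- acq_tiny(n_volumes = 114)  # longer runs tame estimation noise
  des <- cohort_design(n_msp = 20, n_ssp = 20, effect_z = 0.8,
                       noise_sd = 0.4, subject_sd = 0.15,
                       signature_sd = 0.1, n_states_true = 1,
                       state_dwell_mean = 1e9, rng_seed = 31)
  co <- generate_cohort(spec, des)
  V <- prod(spec$grid_dims)
  maps <- matrix(NA_real_, 40, V)
  for (i in 1:40) {
    s <- co$subjects[[i]]
    masks <- co$masks; masks$lesion <- s$lesion
    pre <- preprocess_pipeline(s$bold, s$motion, masks,
                               s$record$lesion_side,
                               preprocess_params(fwhm_mm = 0))
    dfc <- compute_dfc_series(pre$run, pre$masks)
    maps[i, ] <- rowMeans(dfc$maps)
  }
  sm <- voxelwise_group_ttest(maps, co$metadata$group, co$metadata)
  # the planted target regions span only ~2 voxels each on this grid
  params <- stat_params(min_cluster_voxels = 2)
  tab <- cluster_extent_filter(sm$t, spec, params)
  tvol <- array(sm$t, spec$grid_dims)
  sig <- abs(tvol) > params$t_threshold
  labs <- label_components(sig & tvol > 0, params$connectivity)
  keep <- labs > 0
  for (cid in seq_len(max(labs)))
    if (sum(labs == cid) < params$min_cluster_voxels) keep[labs == cid] <- FALSE
  truth <- co$truth$effect_map > 0
  dice <- 2 * sum(keep & truth) / (sum(keep) + sum(truth))
  expect_gte(dice, 0.5)
})

test_that("summary t-test matches raw-data oracles and published rows", {
  # severity scores: 31.4 +/- 7.84 (n = 29) vs 8.85 +/- 4.49 (n = 40)
  res <- summary_ttest(31.4, 7.84, 29, 8.85, 4.49, 40)
  expect_lt(res$p, 1e-4)
  expect_equal(res$df, 67)
  expect_gt(res$t, 10)
  same <- summary_ttest(5, 2, 10, 5, 2, 12)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  degenerate <- summary_ttest(5, 0, 5, 5, 0, 5)
  expect_equal(degenerate$t, 0); expect_equal(degenerate$p, 1)
  # agreement with t.test on raw samples
  set.seed(9)
  a <- rnorm(14, 1); b <- rnorm(19)
  ref <- t.test(a, b, var.equal = TRUE)
  got <- summary_ttest(mean(a), sd(a), 14, mean(b), sd(b), 19)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("pearson correlation p-values come from the t transform", {
  x <- 1:10
  expect_equal(pearson_with_p(x, 2 * x + 3)$r, 1)
  set.seed(10)
  a <- rnorm(10); b <- rnorm(10)
  got <- pearson_with_p(a, b)
  ref <- cor.test(a, b)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  # direct covariance formula oracle
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_direct, tolerance = 1e-12)
  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), "variance")
  # independence: p roughly uniform across replicates
  p <- vapply(1:200, function(i) pearson_with_p(rnorm(500), rnorm(500))$p,
              numeric(1))
  expect_gt(mean(p > 0.5), 0.35); expect_lt(mean(p > 0.5), 0.65)
})

test_that("2x2 chi-square is the uncorrected Pearson statistic", {
  res <- chi_square_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$chisq, 20)
  expect_equal(res$df, 1)
  prop <- chi_square_2x2(matrix(c(10, 20, 5, 10), 2))
  expect_equal(prop$chisq, 0, tolerance = 1e-12)
  expect_equal(prop$p, 1, tolerance = 1e-12)
  # closed form n (ad - bc)^2 / (r1 r2 c1 c2)
  m <- matrix(c(12, 7, 9, 16), 2)
  got <- chi_square_2x2(m)
  n <- sum(m)
  oracle <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    (prod(rowSums(m)) * prod(colSums(m)))
  expect_equal(got$chisq, oracle, tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("demographics table summarizes a cohort with the right tests", {
  spec <- acq_tiny(n_volumes = 30)
  co <- generate_cohort(spec, cohort_design(n_msp = 8, n_ssp = 9,
                                            rng_seed = 12))
  tab <- demographics_table(co$metadata)
  expect_true("ulfma" %in% tab$characteristic)
  # severity differs by construction; other rows are exchangeable draws
  expect_lt(tab$p_value[tab$characteristic == "ulfma"], 0.01)
  expect_equal(nrow(tab), 6)
})
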