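test_that("window variance series matches a two-pass oracle", {
  spec <- acquisition_spec(grid_dims = c(4L, 4L, 3L), n_volumes = 50,
                           n_dummy = 0)
  set.seed(9)
  run <- run_from_matrix(matrix(rnorm(50 * 48), 50, 48), spec)
  masks <- list(brain = array(TRUE, spec$grid_dims))
  dfc <- compute_dfc_series(run, masks,
                            dfc_params(window_len_tr = 10, seed_radius_mm = 0))
  v <- window_variance_series(dfc)
  for (w in c(1, 5, nrow(dfc$windows))) {
    x <- dfc$maps[dfc$valid, w]
    expect_equal(v[w], sum((x - mean(x))^2) / (length(x) - 1),
                 tolerance = 1e-12)
  }
  # constant maps give zero variance; scaling one map scales its variance
  dfc$maps[, 2] <- 3 * dfc$maps[, 1]
  v2 <- window_variance_series(dfc)
  expect_equal(v2[2], 9 * v2[1], tolerance = 1e-10)
})

test_that("exemplar selection finds interior local maxima, plateaus once", {
  expect_equal(select_exemplars(1:10), integer(0))
  expect_equal(select_exemplars(10:1), integer(0))
  v <- rep(0, 11); v[7] <- 2
  expect_equal(select_exemplars(v), 7L)
  # plateau at 4-5 contributes its first index
  expect_equal(select_exemplars(c(0, 1, 2, 5, 5, 2, 1, 0)), 4L)
  # endpoint plateaus and maxima never qualify
  expect_equal(select_exemplars(c(5, 5, 1, 1, 6)), integer(0))
  # exhaustive scan oracle on random series
  set.seed(2)
  for (i in 1:50) {
    v <- sample(0:6, 30, replace = TRUE)
    got <- select_exemplars(v)
    oracle <- integer(0)
    w <- 2L
    while (w <= 29L) {
      if (v[w] > v[w - 1]) {
        e <- w
        while (e < 30 && v[e + 1] == v[w]) e <- e + 1L
        if (e < 30 && v[e + 1] < v[w]) oracle <- c(oracle, w)
        w <- e + 1L
      } else w <- w + 1L
    }
    expect_equal(got, oracle)
  }
})

test_that("L1 k-means: median centroid, exact recovery, descent", {
  set.seed(41)
  X <- matrix(rnorm(60 * 7), 60, 7)
  m1 <- kmeans_l1(X, 1, state_params(n_init = 2, rng_seed = 1))
  expect_equal(as.vector(m1$centroids), apply(X, 2, median),
               tolerance = 1e-12)
  # two well-separated blobs in 2-D: exact planted partition
  blob <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
                matrix(rnorm(20, 5, 0.1), 10, 2))
  truth <- rep(1:2, each = 10)
  m2 <- kmeans_l1(blob, 2, state_params(rng_seed = 3))
  expect_true(all(table(m2$labels, truth) %in% c(0, 10)))
  expect_true(all(diff(m2$objective_trace) < 1e-9))  # monotone descent
  # final objective never exceeds the first-assignment objective
  expect_lte(m2$objective, m2$objective_trace[1])
  # label permutation invariance of the objective
  perm <- c(2, 1)
  relabeled <- perm[m2$labels]
  obj <- sum(vapply(seq_len(nrow(blob)), function(i)
    sum(abs(blob[i, ] - m2$centroids[m2$labels[i], ])), numeric(1)))
  obj_perm <- sum(vapply(seq_len(nrow(blob)), function(i)
    sum(abs(blob[i, ] - m2$centroids[perm, ][relabeled[i], ])), numeric(1)))
  expect_equal(obj, obj_perm, tolerance = 1e-10)
  expect_error(kmeans_l1(blob, 21, state_params()), "exceeds")
})

test_that("participation-rate arithmetic reproduces the 1/69 pattern", {
  # 69 subjects, 30 windows each; subject 1 alone visits state 1,
  # subject 2 never visits state 2
  subjects <- rep(sprintf("s%02d", 1:69), each = 30)
  labels <- integer(69 * 30)
  set.seed(8)
  for (i in 1:69) {
    rows <- ((i - 1) * 30 + 1):(i * 30)
    labels[rows] <- sample(2:3, 30, replace = TRUE)
    if (i == 1) labels[rows[1:5]] <- 1L
    if (i == 2) labels[rows] <- 3L
  }
  pr <- participation_rate(labels, subjects, k = 3)
  expect_equal(pr, c(1 / 69, 68 / 69, 69 / 69))
  expect_equal(participation_rate(c(1, 1, 2), c("a", "a", "a"), k = 3)[3], 0)
})

test_that("k selection isolates a planted near-singleton state", {
  spec <- acq_tiny(n_volumes = 81)  # 60 windows of 22 TR
  des <- cohort_design(n_msp = 4, n_ssp = 3, effect_z = 0.3,
                       n_states_true = 2, state_dwell_mean = 35,
                       noise_sd = 0.3, drift_amp = 0, motion_amp = 0,
                       subject_sd = 0.1, signature_sd = 0.15,
                       rare_state_subject = 1, rng_seed = 17)
  co <- generate_cohort(spec, des)
  dfc_list <- lapply(co$subjects, function(s) {
    masks <- co$masks; masks$lesion <- s$lesion
    pre <- preprocess_pipeline(s$bold, s$motion, masks,
                               s$record$lesion_side,
                               preprocess_params(fwhm_mm = 0))
    compute_dfc_series(pre$run, pre$masks)
  })
  pooled <- pool_dfc_features(dfc_list)
  sel <- select_k_and_retain(pooled$X, pooled$subject_of_window,
                             state_params(k_range = 2:5, n_init = 5,
                                          rng_seed = 4),
                             pooled$exemplar_idx)
  # the population pattern: at least the two common states retained with
  # broad participation, every dropped state a near-singleton
  expect_gte(sel$k, 3)
  expect_length(sel$retained, 2)
  expect_true(all(sel$participation[sel$retained] >= 5 / 7))
  dropped <- setdiff(seq_len(sel$k), sel$retained)
  expect_true(all(round(sel$participation[dropped] * 7) <= 1))
  # pr_threshold = 0 retains everything
  sel0 <- select_k_and_retain(pooled$X, pooled$subject_of_window,
                              state_params(k_range = 3, n_init = 3,
                                           pr_threshold = 0, rng_seed = 4),
                              pooled$exemplar_idx, fix_k = 3)
  expect_length(sel0$retained, 3)
  expect_equal(state_params()$k_range, 2:8)
})

test_that("planted two-state structure is recovered almost perfectly", {
  skip_if_no("mclust")
  spec <- acq_tiny(n_volumes = 80)
  des <- cohort_design(n_msp = 3, n_ssp = 3, effect_z = 0.4,
                       n_states_true = 2, state_dwell_mean = 40,
                       noise_sd = 0.2, drift_amp = 0, motion_amp = 0,
                       subject_sd = 0.05, signature_sd = 0, rng_seed = 23)
  co <- generate_cohort(spec, des)
  dfc_list <- list()
  win_truth <- list()
  for (i in seq_along(co$subjects)) {
    s <- co$subjects[[i]]
    run <- s$bold
    masks <- co$masks; masks$lesion <- s$lesion
    if (s$record$lesion_side == "right") {
      run <- flip_midsagittal(run, "right")
      masks <- lapply(masks, flip_midsagittal, lesion_side = "right")
    }
    dfc <- compute_dfc_series(run, masks, dfc_params(window_len_tr = 22))
    dfc_list[[i]] <- dfc
    st <- co$truth$state_seq[[i]]
    win_truth[[i]] <- apply(dfc$windows, 1, function(w) {
      seg <- st[w[1]:w[2]]
      if (length(unique(seg)) == 1) seg[1] else NA_integer_
    })
  }
  pooled <- pool_dfc_features(dfc_list)
  model <- kmeans_l1(pooled$X, 2, state_params(n_init = 5, rng_seed = 6),
                     pooled$exemplar_idx)
  truth <- unlist(win_truth)
  pure <- !is.na(truth)
  ari <- mclust::adjustedRandIndex(model$labels[pure], truth[pure])
  expect_gte(ari, 0.9)
})

test_that("subject-state mean maps equal a group-by average oracle", {
  set.seed(77)
  X <- matrix(rnorm(40 * 6), 40, 6)
  subj <- rep(c("a", "b", "c", "d"), each = 10)
  labels <- sample(1:3, 40, replace = TRUE)
  labels[subj == "d"] <- 1L  # subject d never visits states 2, 3
  res <- subject_state_mean_maps(X, labels, subj, retained = c(2L, 3L))
  for (s in c("2", "3")) {
    for (who in c("a", "b", "c")) {
      rows <- which(subj == who & labels == as.integer(s))
      if (length(rows) > 0)
        expect_equal(res$maps[[s]][who, ], colMeans(X[rows, , drop = FALSE]),
                     tolerance = 1e-12, ignore_attr = TRUE)
    }
    expect_true("d" %in% res$missing[[s]])
    expect_true(all(is.na(res$maps[[s]]["d", ])))
  }
  # a subject with all windows in one state: that state's mean is the
  # subject's overall mean map
  one <- subject_state_mean_maps(X, rep(1L, 40), subj, retained = 1L)
  expect_equal(one$maps[["1"]]["a", ], colMeans(X[subj == "a", ]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
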