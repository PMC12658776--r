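test_that("the canonical architecture matches the published layer plan", {
  cfg <- cnn_config(rng_seed = 1)
  m <- build_model(cfg)
  convs <- Filter(function(l) l$type == "conv", m$layers)
  expect_length(convs, 13)
  expect_equal(vapply(convs, `[[`, 0L, "cout"),
               c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512,
                 512))
  pools <- Filter(function(l) l$type == "pool", m$layers)
  expect_length(pools, 5)
  expect_equal(vapply(pools, `[[`, 0L, "stride"), c(2L, 2L, 2L, 2L, 1L))
  fcs <- Filter(function(l) l$type == "fc", m$layers)
  expect_equal(vapply(fcs, `[[`, 0L, "dout"), c(4096L, 4096L, 2L))
  # width scaling: 1/8 shrinks every channel plan entry
  m8 <- build_model(cnn_config_desk(rng_seed = 1))
  convs8 <- Filter(function(l) l$type == "conv", m8$layers)
  expect_equal(vapply(convs8, `[[`, 0L, "cout"),
               c(8, 8, 16, 16, 32, 32, 32, 64, 64, 64, 64, 64, 64))
})

test_that("He initialization has the advertised standard deviation", {
  m <- build_model(cnn_config_desk(rng_seed = 42))
  # a conv layer with >= 1e4 weights: empirical sd within 5% of
  # sqrt(2 / fan_in), mean near 0
  big <- Filter(function(l) l$type == "conv" && length(l$W) >= 1e4,
                m$layers)[[1]]
  target <- sqrt(2 / (big$cin * 27))
  expect_lt(abs(sd(big$W) - target) / target, 0.05)
  expect_lt(abs(mean(big$W)), 0.05 * target)
  fc <- Filter(function(l) l$type == "fc", m$layers)[[1]]
  expect_lt(abs(sd(fc$W) - sqrt(2 / fc$din)) / sqrt(2 / fc$din), 0.05)
  expect_true(all(vapply(m$layers, function(l)
    l$type != "conv" || all(l$b == 0), logical(1))))
})

test_that("learning rate halves every ten epochs from 0.001", {
  cfg <- cnn_config()
  expect_equal(lr_at_epoch(0, cfg), 0.001)
  expect_equal(lr_at_epoch(10, cfg), 0.0005)
  expect_equal(lr_at_epoch(25, cfg), 0.00025)
  ep <- 0:200
  expect_equal(lr_at_epoch(ep, cfg), 0.001 * 0.5^(ep %/% 10))
})

test_that("stratified folds partition the data at both granularities", {
  set.seed(1)
  y <- rep(c(0, 1), c(400, 600))
  folds <- make_folds(y, 10, "window", rng_seed = 2)
  test_sets <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), 1:1000)
  expect_equal(lengths(test_sets), rep(100L, 10))
  for (f in folds) {
    expect_length(intersect(f$test, f$val), 0)
    expect_length(intersect(f$test, f$train), 0)
    expect_equal(sort(c(f$train, f$val, f$test)), 1:1000)
    # stratification: class ratio preserved within one sample
    expect_lte(abs(sum(y[f$test] == 1) - 60), 1)
  }
  subj <- rep(sprintf("s%02d", 1:20), each = 50)
  ys <- rep(rep(c(0, 1), each = 10), each = 50)
  sf <- make_folds(ys, 10, "subject", subject_of_sample = subj, rng_seed = 3)
  for (f in sf) {
    parts <- list(f$train, f$val, f$test)
    for (a in 1:2) for (b in (a + 1):3)
      expect_length(intersect(unique(subj[parts[[a]]]),
                              unique(subj[parts[[b]]])), 0)
  }
  expect_error(make_folds(rep(0:1, c(995, 5)), 10, "window", rng_seed = 1),
               "absent")
})

test_that("backpropagation matches finite differences layer by layer", {
  set.seed(4)
  dims <- c(4L, 4L, 3L); V <- prod(dims); B <- 6
  X <- matrix(rnorm(V * B), V, B); y <- rep(0:1, 3)
  he <- function(r, c, f) matrix(rnorm(r * c, sd = sqrt(2 / f)), r, c)
  layers <- list(
    list(type = "conv", cin = 1L, cout = 2L, dims = dims,
         W = he(2, 27, 27), b = rnorm(2) * 0.1),
    list(type = "bn", channels = 2L, gamma = runif(2, 0.5, 1.5),
         beta = rnorm(2) * 0.2, running_mean = rep(0, 2),
         running_var = rep(1, 2)),
    list(type = "relu"),
    list(type = "conv", cin = 2L, cout = 3L, dims = dims,
         W = he(3, 54, 54), b = rnorm(3) * 0.1),
    list(type = "pool", dims = dims, stride = 2L),
    list(type = "flatten"),
    list(type = "fc", din = 3L * 8L, dout = 4L, W = he(4, 24, 24),
         b = rnorm(4) * 0.1),
    list(type = "relu"),
    list(type = "dropout", rate = 0.3),
    list(type = "fc", din = 4L, dout = 2L, W = he(2, 4, 4),
         b = rnorm(2) * 0.1))
  g <- strokedfc:::cnn_loss_grad_cpp(layers, X, y, seed = 11)
  h <- 1e-3
  for (li in c(1, 2, 4, 7, 10)) {
    l <- layers[[li]]
    par <- if (l$type == "bn") "gamma" else "W"
    gname <- if (l$type == "bn") "dgamma" else "dW"
    for (j in sample(length(l[[par]]), min(4, length(l[[par]])))) {
      lp <- layers; lp[[li]][[par]][j] <- lp[[li]][[par]][j] + h
      lm <- layers; lm[[li]][[par]][j] <- lm[[li]][[par]][j] - h
      fd <- (strokedfc:::cnn_loss_grad_cpp(lp, X, y, seed = 11)$loss -
             strokedfc:::cnn_loss_grad_cpp(lm, X, y, seed = 11)$loss) /
        (2 * h)
      an <- g$grads[[li]][[gname]][j]
      expect_lt(abs(fd - an) / max(abs(fd) + abs(an), 1e-3), 0.05)
    }
  }
})

test_that("uniform softmax output carries a cross-entropy of log 2", {
  dims <- c(4L, 4L, 3L); V <- prod(dims)
  set.seed(3)
  m <- build_model(cnn_config(input_dims = dims, width_multiplier = 1 / 32,
                              rng_seed = 5))
  # zero the output layer: logits are identically 0, softmax is uniform
  fc_idx <- max(which(vapply(m$layers, function(l) l$type == "fc",
                             logical(1))))
  m$layers[[fc_idx]]$W[] <- 0
  m$layers[[fc_idx]]$b[] <- 0
  X <- matrix(rnorm(V * 8), V, 8)
  p <- predict_cnn(m, X)
  expect_equal(as.vector(p), rep(0.5, 16), tolerance = 1e-7)
  expect_equal(-mean(log(p[2, ])), log(2), tolerance = 1e-6)
})

test_that("a tiny network reaches 100% training accuracy on separable maps", {
  set.seed(6)
  dims <- c(8L, 8L, 8L); V <- prod(dims); n <- 20
  X <- matrix(rnorm(V * n), V, n)
  y <- rep(0:1, each = 10)
  X[1:128, y == 1] <- X[1:128, y == 1] + 2
  cfg <- cnn_config(input_dims = dims, width_multiplier = 1 / 16,
                    epochs = 50, dropout = 0.3, rng_seed = 7)
  model <- train_fold(build_model(cfg), X, y, seq_len(n), integer(0),
                      seed = 8)
  expect_equal(max(model$train_log$train_acc), 1)
  p <- predict_cnn(model, X)
  expect_equal(as.integer(p[2, ] >= p[1, ]), y)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(2)
  dims <- c(6L, 6L, 6L); V <- prod(dims); n <- 24
  X <- matrix(rnorm(V * n), V, n); y <- rep(0:1, 12)
  cfg <- cnn_config(input_dims = dims, width_multiplier = 1 / 16,
                    epochs = 3, rng_seed = 4)
  m1 <- train_fold(build_model(cfg), X, y, 1:20, 21:24, seed = 5)
  m2 <- train_fold(build_model(cfg), X, y, 1:20, 21:24, seed = 5)
  expect_identical(m1$train_log, m2$train_log)
  expect_identical(predict_cnn(m1, X), predict_cnn(m2, X))
})

test_that("metric identities hold on random confusion matrices", {
  met <- classification_metrics(c(rep(1, 10), rep(0, 10)),
                                c(rep(1, 9), 0, rep(0, 8), 1, 1))
  expect_equal(met$sensitivity, 0.9)
  expect_equal(met$specificity, 0.8)
  expect_equal(met$balanced_accuracy, 0.85)
  expect_equal(met$f_score, 2 * 9 / (2 * 9 + 2 + 1), tolerance = 1e-12)
  set.seed(10)
  ok_bac <- ok_acc <- ok_f <- ok_range <- logical(0)
  for (i in 1:1000) {
    tp <- sample(0:30, 1); fn <- sample(0:30, 1)
    tn <- sample(0:30, 1); fp <- sample(0:30, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    truth <- c(rep(1, tp + fn), rep(0, tn + fp))
    pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
    m <- classification_metrics(truth, pred)
    ok_bac <- c(ok_bac, isTRUE(all.equal(
      m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)))
    ok_acc <- c(ok_acc, isTRUE(all.equal(m$accuracy,
                                         (tp + tn) / length(truth))))
    f_ref <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
      else NA_real_
    ok_f <- c(ok_f, isTRUE(all.equal(m$f_score, f_ref)))
    ok_range <- c(ok_range, all(unlist(m) >= 0 & unlist(m) <= 1,
                                na.rm = TRUE))
  }
  expect_true(all(ok_bac)); expect_true(all(ok_acc))
  expect_true(all(ok_f)); expect_true(all(ok_range))
})

test_that("rank AUC agrees with an independent implementation", {
  skip_if_no("pROC")
  set.seed(12)
  for (i in 1:20) {
    truth <- rbinom(40, 1, 0.5)
    if (length(unique(truth)) < 2) next
    score <- rnorm(40) + truth
    m <- classification_metrics(truth, as.integer(score > 0.5), score)
    ref <- suppressMessages(as.numeric(pROC::auc(truth, score,
                                                 direction = "<")))
    expect_equal(m$auc, ref, tolerance = 1e-12)
  }
  expect_error(classification_metrics(rep(1, 5), rep(1, 5), rnorm(5)),
               "single class")
  perfect <- classification_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1),
                                    c(0.1, 0.2, 0.8, 0.9))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1, balanced_accuracy = 1,
                                  f_score = 1, auc = 1))
})
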