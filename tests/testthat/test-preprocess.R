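tiny_spec <- acquisition_spec(grid_dims = c(5L, 3L, 3L), voxel_mm = c(3, 3, 3),
                              n_volumes = 240, n_dummy = 10)

test_that("dummy-volume discard keeps exactly the right frames", {
  T <- 240
  mat <- matrix(rnorm(45 * T), T, 45)
  run <- run_from_matrix(mat, tiny_spec)
  out <- discard_initial(run, 10)
  expect_equal(dim(out$data)[4], 230)
  expect_identical(out$data[, , , 1], run$data[, , , 11])
  expect_identical(discard_initial(run, 0), run)
  short <- run_from_matrix(mat[1:50, ], tiny_spec)
  expect_equal(dim(discard_initial(short, 10)$data)[4], 40)
  expect_error(discard_initial(short, 50), "smaller")
})

test_that("midsagittal flip is an exact involution with correct index map", {
  arr <- array(seq_len(5 * 3 * 3), c(5, 3, 3))
  f <- flip_midsagittal(arr, "right")
  # 1-based: x-index 3 (0-based 2) must land at 0-based X-3, i.e. index 3
  for (j in 1:3) for (k in 1:3) {
    expect_identical(f[5 - 3 + 1, j, k], arr[3, j, k])
    expect_identical(f[1, j, k], arr[5, j, k])
  }
  expect_identical(flip_midsagittal(f, "right"), arr)
  expect_identical(flip_midsagittal(arr, "left"), arr)
  run <- run_from_matrix(matrix(rnorm(45 * 20), 20, 45), tiny_spec)
  expect_identical(flip_midsagittal(flip_midsagittal(run, "right"),
                                    "right")$data, run$data)
})

test_that("24-parameter motion expansion follows the standard convention", {
  T <- 30
  motion <- matrix(rnorm(T * 6), T, 6)
  X <- build_motion_regressors(motion)
  expect_equal(ncol(X), 24)
  expect_equal(X[, 1:6], motion, ignore_attr = TRUE)
  expect_equal(unname(X[1, 7:12]), rep(0, 6))
  expect_equal(X[2:T, 7:12], diff(motion), ignore_attr = TRUE)
  expect_equal(X[, 13:18], motion^2, ignore_attr = TRUE)
  expect_equal(unname(build_motion_regressors(matrix(0, 10, 6))),
               matrix(0, 10, 24))
  const <- build_motion_regressors(matrix(rep(1:6, each = 10), 10, 6))
  expect_true(all(const[, 7:12] == 0))
  expect_error(build_motion_regressors(motion[1, , drop = FALSE]), "two")
})

test_that("nuisance regression produces exact OLS residuals", {
  set.seed(7)
  T <- 40
  X <- cbind(1, rnorm(T), rnorm(T), rnorm(T), rnorm(T))
  colnames(X) <- paste0("c", 1:5)
  mat <- matrix(rnorm(T * 45), T, 45)
  run <- run_from_matrix(mat, tiny_spec)
  out <- regress_nuisance(run, X)
  # explicit normal-equations oracle
  beta <- solve(crossprod(X)) %*% crossprod(X, mat)
  expect_lt(max(abs(t(matrix(out$data, 45, T)) - (mat - X %*% beta))), 1e-10)
  # residuals orthogonal to every design column
  res <- t(matrix(out$data, 45, T))
  expect_lt(max(abs(crossprod(X, res))) / max(colSums(res^2)), 1e-6)
  # a voxel equal to a design column vanishes
  mat2 <- mat; mat2[, 1] <- X[, 3]
  out2 <- regress_nuisance(run_from_matrix(mat2, tiny_spec), X)
  expect_lt(max(abs(out2$data[1, 1, 1, ])), 1e-10)
  # intercept only = demeaning
  out3 <- regress_nuisance(run, X[, 1, drop = FALSE])
  expect_equal(t(matrix(out3$data, 45, T)), sweep(mat, 2, colMeans(mat)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # rank deficiency is reported with the offending column
  Xbad <- cbind(X, dup = X[, 2])
  expect_error(regress_nuisance(run, Xbad), "collinear")
})

test_that("gaussian smoothing has the right width, mass and invariances", {
  expect_equal(6 / (2 * sqrt(2 * log(2))) / 3, 0.84932, tolerance = 1e-4)
  spec <- acquisition_spec(grid_dims = c(15L, 15L, 15L), voxel_mm = c(3, 3, 3))
  const <- bold_run(array(3.7, c(15, 15, 15, 2)), spec)
  out <- smooth_gaussian(const, 6)
  expect_equal(out$data, const$data, tolerance = 1e-10)
  delta <- array(0, c(15, 15, 15, 1)); delta[8, 8, 8, 1] <- 1
  sm <- smooth_gaussian(bold_run(delta, spec), 6)
  expect_equal(sum(sm$data), 1, tolerance = 1e-10)  # kernel normalization
  # sigma check: the impulse response matches dnorm with sigma = 0.8493 vox
  prof <- sm$data[, 8, 8, 1]
  expect_equal(prof / max(prof),
               dnorm(-7:7, sd = 0.84932) / dnorm(0, sd = 0.84932),
               tolerance = 1e-3)
  expect_identical(smooth_gaussian(const, 0), const)
})

test_that("linear detrending removes trends and nothing else", {
  T <- 100
  t_idx <- seq_len(T)
  ramp <- matrix(rep(2 + 0.3 * t_idx, 45), T, 45)
  out <- detrend_linear(run_from_matrix(ramp, tiny_spec))
  expect_lt(max(abs(out$data)), 1e-9)
  sine <- sin(2 * pi * 0.05 * t_idx * 2)
  mixed <- matrix(rep(5 - 0.1 * t_idx, 45), T, 45) + sine
  out2 <- detrend_linear(run_from_matrix(mixed, tiny_spec))
  # fit-and-subtract oracle for the sinusoid component
  fit <- lm.fit(cbind(1, t_idx), sine)
  expect_lt(max(abs(t(matrix(out2$data, 45, T)) - fit$residuals)), 1e-8)
  twice <- detrend_linear(out2)
  expect_equal(twice$data, out2$data, tolerance = 1e-9)
  expect_error(detrend_linear(run_from_matrix(ramp[1:2, ], tiny_spec)),
               "3 time points")
})

test_that("band-pass filter passes the band and kills DC and high f", {
  spec <- acquisition_spec(grid_dims = c(5L, 3L, 3L), n_volumes = 1024,
                           n_dummy = 0)
  T <- 1024
  t_s <- seq_len(T) * 2
  amp_ratio <- function(f) {
    x <- sin(2 * pi * f * t_s)
    run <- run_from_matrix(matrix(rep(x, 45), T, 45), spec)
    y <- bandpass(run, 0.01, 0.1)$data[1, 1, 1, ]
    core <- 200:824  # avoid edge transients when measuring amplitude
    max(abs(y[core])) / max(abs(x[core]))
  }
  expect_gt(amp_ratio(0.05), 0.9)
  expect_gt(amp_ratio(0.03), 0.9)
  expect_lt(amp_ratio(0.2), 0.1)
  dc <- bandpass(run_from_matrix(matrix(1, T, 45), spec), 0.01, 0.1)
  expect_lt(max(abs(dc$data[, , , 200:824])), 0.02)
  expect_error(bandpass(run_from_matrix(matrix(1, 50, 45), spec), 0.01, 0.3),
               "Nyquist")
})

test_that("measured frequency response matches the analytic Butterworth", {
  spec <- acquisition_spec(grid_dims = c(5L, 3L, 3L), n_volumes = 2048,
                           n_dummy = 0)
  T <- 2048
  bf <- signal::butter(4, c(0.01, 0.1) / 0.25, type = "pass")
  # analytic transfer function H(e^{i w}) evaluated directly
  H_at <- function(f_hz) {
    w <- 2 * pi * f_hz * 2  # radians per sample at TR = 2 s
    num <- sum(bf$b * exp(-1i * w * (seq_along(bf$b) - 1)))
    den <- sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
    Mod(num / den)
  }
  freqs <- exp(seq(log(0.004), log(0.22), length.out = 20))
  for (f in freqs) {
    x <- sin(2 * pi * f * seq_len(T) * 2)
    run <- run_from_matrix(matrix(x, T, 1),
                           acquisition_spec(grid_dims = c(1L, 1L, 1L),
                                            n_volumes = T, n_dummy = 0))
    y <- bandpass(run, 0.01, 0.1)$data[1, 1, 1, ]
    core <- 400:1648
    measured <- sqrt(mean(y[core]^2) / mean(x[core]^2))
    expect_lt(abs(measured - H_at(f)^2), 0.05)  # fwd-bwd squares |H|
  }
  # zero phase: the lag maximizing the cross-correlation with the input
  # is no more than one sample
  f <- 0.05
  x <- sin(2 * pi * f * seq_len(T) * 2)
  run <- run_from_matrix(matrix(x, T, 1),
                         acquisition_spec(grid_dims = c(1L, 1L, 1L),
                                          n_volumes = T, n_dummy = 0))
  y <- bandpass(run, 0.01, 0.1)$data[1, 1, 1, ]
  core <- 400:1600
  lags <- -3:3
  cc <- vapply(lags, function(l) cor(x[core], y[core + l]), numeric(1))
  expect_lte(abs(lags[which.max(cc)]), 1)
})

test_that("the full preprocessing chain runs in order and confines power", {
  spec <- acq_tiny(n_volumes = 240, n_dummy = 10)
  co <- generate_cohort(spec, cohort_design(n_msp = 1, n_ssp = 1,
                                            rng_seed = 21))
  s <- co$subjects[[1]]
  masks <- co$masks; masks$lesion <- s$lesion
  pre <- preprocess_pipeline(s$bold, s$motion, masks, s$record$lesion_side)
  expect_equal(dim(pre$run$data)[4], 230)
  stages <- vapply(pre$log, `[[`, "", "stage")
  expect_equal(stages[1], "discard_initial")
  expect_equal(tail(stages, 1), "bandpass")
  expect_true(which(stages == "regress_nuisance") <
                which(stages == "smooth_gaussian"))
  # spectral mass outside 0.01-0.1 Hz is small
  mat <- t(matrix(pre$run$data, prod(spec$grid_dims), 230))
  v <- mat[, which(as.vector(co$masks$brain))[10]]
  spec_p <- Mod(fft(v - mean(v)))^2
  freq <- (seq_along(v) - 1) / (length(v) * 2)
  freq[freq > 0.25] <- 0.5 - freq[freq > 0.25]  # fold about Nyquist
  inband <- freq >= 0.008 & freq <= 0.105
  expect_lt(sum(spec_p[!inband]) / sum(spec_p), 0.05)
  # all stages disabled = identity
  id <- preprocess_pipeline(
    s$bold, s$motion, masks, "left",
    preprocess_params(n_dummy = 0, flip = FALSE, nuisance = FALSE,
                      fwhm_mm = 0, detrend = FALSE, f_low = NULL,
                      f_high = NULL))
  expect_identical(id$run$data, s$bold$data)
})
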