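#' Configuration of the VGG-style 3D convolutional classifier
#'
#' Thirteen 3x3x3 convolutions in the pre-activation pattern
#' "Batchnorm + ReLU + Conv" (the first layer a plain convolution), five
#' 2x2x2 max-pool stages, and a three-layer fully connected head with
#' dropout, softmax output and two classes. The canonical channel plan is
#' (64, 64 | 128, 128 | 256 x3 | 512 x3 | 512 x3) with 4096-unit hidden FC
#' layers; `width_multiplier` scales every channel and hidden-FC count
#' (minimum 1 channel / 2 units), which is how the desk-scale preset
#' shrinks the network by 8x without changing its shape.
#'
#' Unusual architecture details are kept behind flags. The final max-pool
#' uses stride 1 (`final_pool_stride_1`, on by default). `output_relu`
#' inserts a ReLU between the 2-unit output layer and the softmax; it is
#' off by default because a rectified two-logit head admits a
#' zero-gradient collapse — once both logits clamp at zero for every
#' input, the cross-entropy sits at log 2 permanently and training cannot
#' recover (see the methods vignette) — but the flag reproduces that
#' variant exactly when wanted. Pool stages
#' whose input is thinner than 4 voxels in any direction are automatically
#' demoted to stride 1 (recorded in the model log) so small grids remain
#' usable.
#'
#' Training uses Adam (epsilon `adam_epsilon`), cross-entropy loss,
#' mini-batches of `batch`, dropout `dropout` on the hidden FC layers, and
#' an initial learning rate `lr0` halved every `lr_half_period` epochs.
#'
#' @param input_dims spatial dims of the input volume.
#' @param width_multiplier in (0, 1]; 1 reproduces the canonical plan.
#' @param epochs,batch,lr0,lr_half_period,adam_epsilon,dropout see above.
#' @param final_pool_stride_1,output_relu architecture flags (see above).
#' @param rng_seed seed for weight initialization and training shuffles.
#' @export
cnn_config <- function(input_dims = c(61L, 73L, 61L),
                       width_multiplier = 1,
                       epochs = 50L, batch = 32L,
                       lr0 = 0.001, lr_half_period = 10L,
                       adam_epsilon = 0.001, dropout = 0.7,
                       final_pool_stride_1 = TRUE, output_relu = FALSE,
                       rng_seed = 1L) {
  stopifnot(width_multiplier > 0, width_multiplier <= 1,
            epochs >= 1, batch >= 1, lr0 > 0, lr_half_period >= 1,
            dropout >= 0, dropout < 1)
  structure(as.list(environment()), class = "cnn_config")
}

#' Desk-scale preset: width-1/8 network, 10 epochs
#'
#' @param input_dims spatial dims (default the 20 x 24 x 20 desk grid).
#' @param ... overrides passed to [cnn_config()].
#' @export
cnn_config_desk <- function(input_dims = c(20L, 24L, 20L), epochs = 10L, ...) {
  cnn_config(input_dims = input_dims, width_multiplier = 1 / 8,
             epochs = epochs, ...)
}

cnn_base_channels <- c(64, 64, 128, 128, 256, 256, 256,
                       512, 512, 512, 512, 512, 512)
cnn_pool_after <- c(2, 4, 7, 10, 13)
cnn_base_fc <- c(4096, 4096)

#' Learning rate at a given (0-based) epoch
#'
#' `lr = lr0 * 0.5 ^ floor(epoch / lr_half_period)`.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param config a [cnn_config()].
#' @export
lr_at_epoch <- function(epoch, config = cnn_config()) {
  stopifnot(all(epoch >= 0))
  config$lr0 * 0.5^(epoch %/% config$lr_half_period)
}

#' Build and He-initialize the 3D-CNN
#'
#' Weights are zero-mean Gaussian with standard deviation sqrt(2 / fan_in)
#' per layer; batch-norm scales start at 1, offsets at 0.
#'
#' @param config a [cnn_config()].
#' @return object of class `cnn_model`: `config`, `layers` (ordered layer
#'   descriptors consumed by the C++ trainer), `log` (pooling-plan notes),
#'   `n_parameters`.
#' @export
build_model <- function(config = cnn_config()) {
  set.seed(config$rng_seed)
  wm <- config$width_multiplier
  ch <- pmax(1L, as.integer(round(cnn_base_channels * wm)))
  fc <- pmax(2L, as.integer(round(cnn_base_fc * wm)))
  dims <- as.integer(config$input_dims)
  layers <- list()
  log <- character(0)
  he_mat <- function(nrow, ncol, fan_in) {
    matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
  }
  add <- function(l) layers[[length(layers) + 1]] <<- l
  cin <- 1L
  pool_no <- 0L
  for (j in seq_along(ch)) {
    if (j > 1) {
      add(list(type = "bn", channels = cin,
               gamma = rep(1, cin), beta = rep(0, cin),
               running_mean = rep(0, cin), running_var = rep(1, cin)))
      add(list(type = "relu"))
    }
    add(list(type = "conv", cin = cin, cout = ch[j], dims = dims,
             W = he_mat(ch[j], cin * 27L, cin * 27L), b = rep(0, ch[j])))
    cin <- ch[j]
    if (j %in% cnn_pool_after) {
      pool_no <- pool_no + 1L
      stride <- 2L
      if (pool_no == length(cnn_pool_after) && config$final_pool_stride_1)
        stride <- 1L
      if (stride == 2L && min(dims) < 4L) {
        stride <- 1L
        log <- c(log, sprintf(
          "pool %d demoted to stride 1 (input %s too small)", pool_no,
          paste(dims, collapse = "x")))
      }
      add(list(type = "pool", dims = dims, stride = stride))
      if (stride == 2L) dims <- as.integer(ceiling(dims / 2))
    }
  }
  add(list(type = "flatten"))
  din <- prod(dims) * cin
  for (h in fc) {
    add(list(type = "fc", din = din, dout = h,
             W = he_mat(h, din, din), b = rep(0, h)))
    add(list(type = "relu"))
    add(list(type = "dropout", rate = config$dropout))
    din <- h
  }
  add(list(type = "fc", din = din, dout = 2L,
           W = he_mat(2L, din, din), b = rep(0, 2)))
  if (config$output_relu) add(list(type = "relu"))
  n_par <- sum(vapply(layers, function(l) {
    if (l$type %in% c("conv", "fc")) length(l$W) + length(l$b)
    else if (l$type == "bn") 2 * l$channels else 0
  }, numeric(1)))
  structure(list(config = config, layers = layers, log = log,
                 n_parameters = n_par),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  nconv <- sum(vapply(x$layers, function(l) l$type == "conv", logical(1)))
  cat(sprintf("<cnn_model> %d conv layers, %.3g M parameters, input %s\n",
              nconv, x$n_parameters / 1e6,
              paste(x$config$input_dims, collapse = "x")))
  for (m in x$log) cat(" note:", m, "\n")
  invisible(x)
}

# class labels: the positive class (severe impairment, SSP) codes as 1
label_to_int <- function(labels, positive = "SSP") {
  as.integer(labels == positive)
}

#' Stratified cross-validation folds
#'
#' Per fold: one fold of the data is the test set (~10%), the next fold is
#' the validation set (~10%), the rest trains (~80%); stratification keeps
#' the class ratio in every fold. At `granularity = "subject"` the fold
#' unit is the subject, so no subject's windows ever span two partitions
#' of the same fold; at `"window"` individual dFC windows are dealt out
#' independently of their subject — the design whose leakage the
#' classification experiment quantifies.
#'
#' @param y per-sample class labels.
#' @param n_folds number of folds (default 10).
#' @param granularity "window" or "subject".
#' @param subject_of_sample per-sample subject ids (required for subject
#'   granularity).
#' @param rng_seed integer seed.
#' @return list of folds, each with `train`, `val`, `test` index vectors,
#'   plus attributes `granularity` and `n_folds`.
#' @export
make_folds <- function(y, n_folds = 10L, granularity = c("window", "subject"),
                       subject_of_sample = NULL, rng_seed = 1L) {
  granularity <- match.arg(granularity)
  stopifnot(n_folds >= 2)
  set.seed(rng_seed)
  n <- length(y)
  if (granularity == "subject") {
    if (is.null(subject_of_sample))
      stop("subject granularity needs subject_of_sample")
    subjects <- unique(subject_of_sample)
    sub_class <- y[match(subjects, subject_of_sample)]
    unit_fold <- integer(length(subjects))
    for (cl in unique(sub_class)) {
      idx <- sample(which(sub_class == cl))
      unit_fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold_of_sample <- unit_fold[match(subject_of_sample, subjects)]
  } else {
    fold_of_sample <- integer(n)
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_of_sample[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  }
  folds <- lapply(seq_len(n_folds), function(f) {
    vf <- f %% n_folds + 1L
    test <- which(fold_of_sample == f)
    val <- which(fold_of_sample == vf)
    train <- which(!fold_of_sample %in% c(f, vf))
    for (part in list(test = test, val = val, train = train)) {
      if (length(unique(y[part])) < length(unique(y)))
        stop("a class is absent from one cross-validation partition; ",
             "use fewer folds or more data")
    }
    list(train = train, val = val, test = test)
  })
  attr(folds, "granularity") <- granularity
  attr(folds, "n_folds") <- n_folds
  folds
}

#' Train the network on one fold
#'
#' Adam with the halving learning-rate schedule, cross-entropy loss,
#' dropout active only in training; the final-epoch weights are returned
#' (validation is monitored, not used for early stopping). Inputs are
#' z-scored voxelwise against the training set — a standard input
#' normalization of volumetric image-input layers — with the maps stored
#' on the model and reapplied by [predict_cnn()].
#'
#' @param model a [build_model()] object.
#' @param X features x samples matrix (flattened volumes in columns).
#' @param y01 integer 0/1 labels (1 = positive class).
#' @param train_idx,val_idx sample indices.
#' @param seed training-shuffle / dropout seed.
#' @return the model with trained `layers` and a per-epoch `train_log`.
#' @export
train_fold <- function(model, X, y01, train_idx, val_idx = integer(0),
                       seed = model$config$rng_seed) {
  cfg <- model$config
  stopifnot(nrow(X) == prod(cfg$input_dims))
  # per-voxel z-scoring on the training set (the stronger of the two
  # standard input normalizations of volumetric image-input layers; it
  # also conditions the optimization, see the methods vignette); the
  # normalization maps travel with the model
  model$input_mean <- rowMeans(X[, train_idx, drop = FALSE])
  model$input_sd <- pmax(apply(X[, train_idx, drop = FALSE], 1, stats::sd),
                         1e-6)
  X <- (X - model$input_mean) / model$input_sd
  res <- cnn_train_cpp(model$layers, X, as.integer(y01),
                       as.integer(train_idx), as.integer(val_idx),
                       list(epochs = as.integer(cfg$epochs),
                            batch = as.integer(cfg$batch),
                            lr0 = cfg$lr0,
                            lr_half_period = as.integer(cfg$lr_half_period),
                            adam_epsilon = cfg$adam_epsilon,
                            seed = as.integer(seed) %% .Machine$integer.max))
  model$layers <- res$layers
  model$train_log <- res$log
  model
}

#' Class probabilities of the fitted network
#'
#' @param model trained `cnn_model`.
#' @param X features x samples matrix.
#' @return 2 x n matrix; row 2 is P(positive class).
#' @export
predict_cnn <- function(model, X) {
  if (!is.null(model$input_mean))
    X <- (X - model$input_mean) / model$input_sd
  cnn_predict_cpp(model$layers, X, as.integer(model$config$batch))
}

#' Cross-validated training and evaluation
#'
#' Runs the full stratified k-fold protocol: a freshly He-initialized
#' network per fold (seeded from `config$rng_seed` plus the fold number),
#' training on ~80% of samples, monitoring ~10%, testing on the held-out
#' ~10%, then the confusion-matrix metric suite and (optionally) a
#' label-shuffling permutation test of the test accuracy.
#'
#' @param X features x samples matrix.
#' @param labels per-sample class labels.
#' @param config a [cnn_config()].
#' @param granularity "window" or "subject" (see [make_folds()]).
#' @param subject_of_sample per-sample subject ids.
#' @param n_folds number of folds.
#' @param n_perm permutation count for the per-fold test (0 = skip).
#' @param monitor_val record validation loss/accuracy each epoch (TRUE by
#'   default; heavy scaled experiments may disable the per-epoch pass).
#' @param positive label of the positive class (severe group).
#' @return object of class `cv_report`: `folds` (per-fold metrics,
#'   proportions in [0, 1]), `summary` (mean and SD), `manifest`,
#'   `granularity`, `positive`.
#' @export
cross_validate <- function(X, labels, config, granularity = "window",
                           subject_of_sample = NULL, n_folds = 10L,
                           n_perm = 0L, monitor_val = TRUE,
                           positive = "SSP") {
  y01 <- label_to_int(labels, positive)
  folds <- make_folds(y01, n_folds, granularity, subject_of_sample,
                      rng_seed = config$rng_seed)
  rows <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    cfg_f <- config
    cfg_f$rng_seed <- config$rng_seed + 1000L * f
    model <- build_model(cfg_f)
    model <- train_fold(model, X, y01, fold$train,
                        if (monitor_val) fold$val else integer(0),
                        seed = cfg_f$rng_seed)
    probs <- predict_cnn(model, X[, fold$test, drop = FALSE])
    pred01 <- as.integer(probs[2, ] >= probs[1, ])
    met <- classification_metrics(y01[fold$test], pred01, probs[2, ])
    met$train_acc <- model$train_log$train_acc[nrow(model$train_log)]
    met$fold <- f
    if (n_perm > 0) {
      met$permutation_p <- permutation_test_acc(
        pred01, y01[fold$test], n_perm = n_perm,
        rng_seed = config$rng_seed + 2000L + f)$p
    }
    rows[[f]] <- as.data.frame(met)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("train_acc", "accuracy", "auc", "specificity",
                   "sensitivity", "f_score", "balanced_accuracy")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_fold[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_fold[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(folds = per_fold, summary = summary,
                 manifest = lapply(folds, function(f) f["test"]),
                 fold_assignment = folds,
                 granularity = granularity, positive = positive),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_report> %d folds (%s granularity, positive class %s)\n",
              nrow(x$folds), x$granularity, x$positive))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %6.2f%% +/- %.2f%%\n", s$metric[i],
                100 * s$mean[i], 100 * s$sd[i]))
  if (!is.null(x$folds$permutation_p))
    cat(sprintf("  max permutation p: %.4g\n", max(x$folds$permutation_p)))
  invisible(x)
}

#' Format a cross-validation report as a percentage table
#'
#' One row per fold plus a Mean +/- SD row, columns in percent.
#'
#' @param report a `cv_report`.
#' @export
cv_report_table <- function(report) {
  pf <- report$folds
  pc <- function(v) sprintf("%.2f", 100 * v)
  tab <- data.frame(
    fold = as.character(pf$fold),
    train_acc = pc(pf$train_acc),
    test_acc = pc(pf$accuracy),
    p_value = if (!is.null(pf$permutation_p))
      format.pval(pf$permutation_p, digits = 3) else "",
    auc = sprintf("%.4f", pf$auc),
    specificity = pc(pf$specificity),
    sensitivity = pc(pf$sensitivity),
    f_score = pc(pf$f_score),
    balanced_accuracy = pc(pf$balanced_accuracy),
    stringsAsFactors = FALSE)
  s <- report$summary
  msd <- function(m) sprintf("%.2f +/- %.2f", 100 * s$mean[s$metric == m],
                             100 * s$sd[s$metric == m])
  rbind(tab, data.frame(
    fold = "Mean +/- SD", train_acc = msd("train_acc"),
    test_acc = msd("accuracy"), p_value = "",
    auc = sprintf("%.4f +/- %.4f", s$mean[s$metric == "auc"],
                  s$sd[s$metric == "auc"]),
    specificity = msd("specificity"), sensitivity = msd("sensitivity"),
    f_score = msd("f_score"),
    balanced_accuracy = msd("balanced_accuracy"),
    stringsAsFactors = FALSE))
}
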