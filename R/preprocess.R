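#' A 4D BOLD run
#'
#' Thin container for one subject's BOLD series: a rank-4 array
#' (x, y, z, t) plus its [acquisition_spec()] and subject id. All
#' preprocessing stages take and return this type.
#'
#' @param data rank-4 numeric array.
#' @param spec an [acquisition_spec()] (its grid must match `data`).
#' @param subject_id character scalar.
#' @export
bold_run <- function(data, spec, subject_id = "sub-01") {
  stopifnot(length(dim(data)) == 4, all(dim(data)[1:3] == spec$grid_dims))
  if (!all(is.finite(data))) stop("BOLD data contain non-finite values")
  structure(list(data = data, spec = spec, subject_id = subject_id),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %s: %s voxels x %d volumes\n", x$subject_id,
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4]))
  invisible(x)
}

n_timepoints <- function(run) dim(run$data)[4]

# run data as a t x V matrix (and back)
run_as_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4]))
}
matrix_as_run <- function(mat, run) {
  d <- dim(run$data)
  run$data <- array(t(mat), dim = c(d[1:3], nrow(mat)))
  run
}

#' Discard initial (dummy) volumes
#'
#' @param run a [bold_run()].
#' @param n_dummy number of leading volumes to drop.
#' @export
discard_initial <- function(run, n_dummy = run$spec$n_dummy) {
  stopifnot(inherits(run, "bold_run"), n_dummy >= 0)
  if (n_dummy >= n_timepoints(run))
    stop("n_dummy must be smaller than the run length")
  if (n_dummy == 0) return(run)
  run$data <- run$data[, , , -(seq_len(n_dummy)), drop = FALSE]
  run
}

#' Flip a run or mask across the midsagittal plane
#'
#' Applied only for right-hemisphere lesions so that the lesioned
#' hemisphere sits on one standard side for every subject: voxel x-index i
#' maps to X - 1 - i (0-based). The operation is an involution.
#'
#' @param x a [bold_run()] or a 3D array (mask/volume).
#' @param lesion_side "left" (no-op) or "right" (flip).
#' @export
flip_midsagittal <- function(x, lesion_side = "right") {
  if (identical(lesion_side, "left")) return(x)
  if (inherits(x, "bold_run")) {
    nx <- dim(x$data)[1]
    x$data <- x$data[nx:1, , , , drop = FALSE]
    return(x)
  }
  stopifnot(length(dim(x)) == 3)
  x[dim(x)[1]:1, , , drop = FALSE]
}

#' Expand 6 motion parameters to the 24-parameter model
#'
#' Columns: the 6 parameters, their backward-difference temporal
#' derivatives (first row zero), and the squares of all 12.
#'
#' @param motion t x 6 matrix (3 translations mm, 3 rotations degrees).
#' @return t x 24 matrix.
#' @export
build_motion_regressors <- function(motion) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  if (nrow(motion) < 2) stop("need at least two time points")
  deriv <- rbind(0, diff(motion))
  out <- cbind(motion, deriv, motion^2, deriv^2)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_d"),
                     paste0("mp", 1:6, "_sq"), paste0("mp", 1:6, "_dsq"))
  out
}

#' Assemble the nuisance design matrix
#'
#' 24 motion-derived regressors, mean white-matter and CSF signals
#' (computed over the masks eroded by one voxel), a linear trend and an
#' intercept: 28 columns before rank-deficiency pruning. All-zero columns
#' (e.g. derivatives of constant motion) are pruned with a message.
#'
#' @param run a [bold_run()] (post-discard).
#' @param motion t x 6 motion table matching the run length.
#' @param masks list with `wm` and `csf` logical arrays.
#' @return t x m design matrix with column names.
#' @export
build_nuisance_design <- function(run, motion, masks) {
  tlen <- n_timepoints(run)
  if (nrow(motion) != tlen)
    stop("motion table length does not match the run")
  mat <- run_as_matrix(run)
  wm <- erode_mask(masks$wm)
  csf <- erode_mask(masks$csf)
  if (!any(wm)) wm <- masks$wm
  if (!any(csf)) csf <- masks$csf
  X <- cbind(build_motion_regressors(motion),
             wm_mean = rowMeans(mat[, as.vector(wm), drop = FALSE]),
             csf_mean = rowMeans(mat[, as.vector(csf), drop = FALSE]),
             trend = seq_len(tlen) - (tlen + 1) / 2,
             intercept = 1)
  zero <- apply(X, 2, function(col) all(abs(col) < 1e-12))
  if (any(zero)) {
    message("pruning all-zero nuisance columns: ",
            paste(colnames(X)[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  X
}

# one-voxel 6-connected erosion
erode_mask <- function(mask) {
  d <- dim(mask)
  m <- mask
  shift_and <- function(a, dim, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    rng <- seq_len(d[dim] - abs(by))
    idx_dst[[dim]] <- rng + max(0, by); idx_src[[dim]] <- rng + max(0, -by)
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (dim in 1:3) for (by in c(-1, 1)) m <- m & shift_and(mask, dim, by)
  m
}

#' Regress nuisance signals out of every voxel time series
#'
#' Ordinary-least-squares residuals; afterwards every voxel series is
#' orthogonal to every design column (up to solver tolerance).
#'
#' @param run a [bold_run()].
#' @param design t x m design matrix, full column rank.
#' @export
regress_nuisance <- function(run, design) {
  design <- as.matrix(design)
  if (nrow(design) != n_timepoints(run))
    stop("design rows must equal the run length")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  mat <- run_as_matrix(run)
  resid <- qr.resid(qrX, mat)
  matrix_as_run(resid, run)
}

#' Isotropic Gaussian spatial smoothing
#'
#' Separable convolution along each axis with sigma (in voxels) equal to
#' `fwhm_mm / (2 sqrt(2 log 2)) / voxel_mm`; boundaries use nearest
#' (replicate) extension so edge voxels are not darkened. `fwhm_mm = 0` is
#' the identity.
#'
#' @param run a [bold_run()].
#' @param fwhm_mm kernel full width at half maximum, mm.
#' @export
smooth_gaussian <- function(run, fwhm_mm = 6) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(run)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / run$spec$voxel_mm
  d <- dim(run$data)
  x <- run$data
  for (ax in 1:3) {
    K <- gaussian_boundary_matrix(d[ax], sigma_vox[ax])
    if (is.null(K)) next
    perm <- c(ax, setdiff(1:4, ax))
    x <- aperm(x, perm)
    dims_p <- dim(x)
    x <- K %*% matrix(x, dims_p[1])
    dim(x) <- dims_p
    x <- aperm(x, order(perm))
  }
  run$data <- x
  run
}

# D x D convolution matrix for a 1D Gaussian with replicate boundaries;
# NULL when the kernel is effectively a delta.
gaussian_boundary_matrix <- function(D, sigma) {
  if (sigma < 1e-8) return(NULL)
  r <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, D, D)
  for (oi in seq_along(w)) {
    o <- oi - r - 1L
    src <- pmin(pmax(seq_len(D) + o, 1L), D)
    K[cbind(seq_len(D), src)] <- K[cbind(seq_len(D), src)] + w[oi]
  }
  K
}

#' Remove a per-voxel least-squares linear trend
#'
#' @param run a [bold_run()].
#' @export
detrend_linear <- function(run) {
  tlen <- n_timepoints(run)
  if (tlen < 3) stop("detrending needs at least 3 time points")
  X <- cbind(1, seq_len(tlen))
  matrix_as_run(qr.resid(qr(X), run_as_matrix(run)), run)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth applied forward and backward (zero phase), with
#' odd-mirror padding at both ends to suppress filter transients. The
#' squared magnitude response passes 0.01-0.1 Hz and removes DC and
#' frequencies at or above twice the upper edge.
#'
#' @param run a [bold_run()].
#' @param f_low,f_high band edges in Hz; `f_high` must not exceed the
#'   Nyquist frequency `1 / (2 TR)`.
#' @export
bandpass <- function(run, f_low = 0.01, f_high = 0.1) {
  tr <- run$spec$tr_seconds
  nyq <- 1 / (2 * tr)
  if (!(f_low >= 0 && f_low < f_high)) stop("need 0 <= f_low < f_high")
  if (f_high > nyq) stop(sprintf("f_high (%.4g) exceeds Nyquist (%.4g)",
                                 f_high, nyq))
  bf <- signal::butter(4, c(f_low, f_high) / nyq, type = "pass")
  mat <- run_as_matrix(run)
  matrix_as_run(filtfilt_mirror(bf$b, bf$a, mat), run)
}

# forward-backward IIR filtering of the columns of a (t x V) matrix with
# odd-mirror padding; vectorized across columns
filtfilt_mirror <- function(b, a, x) {
  tlen <- nrow(x)
  p <- min(tlen - 1L, 3L * (length(a) - 1L) * 3L)
  pad <- function(m) {
    top <- 2 * m[rep(1, p), , drop = FALSE] - m[p:1 + 1, , drop = FALSE]
    bot <- 2 * m[rep(tlen, p), , drop = FALSE] -
      m[tlen - (1:p), , drop = FALSE]
    rbind(top, m, bot)
  }
  core <- function(m) {
    y <- iir_cols(b, a, pad(m))
    y <- y[(p + 1):(p + tlen), , drop = FALSE]
    y <- iir_cols(b, a, pad(y[tlen:1, , drop = FALSE]))
    y[(p + tlen):(p + 1), , drop = FALSE]
  }
  core(x)
}

# direct-form-I IIR across all columns at once
iir_cols <- function(b, a, x) {
  n <- nrow(x); nc <- ncol(x)
  nb <- length(b); na <- length(a)
  y <- matrix(0, n, nc)
  for (t in seq_len(n)) {
    acc <- b[1] * x[t, ]
    if (t > 1) {
      for (k in 2:min(nb, t)) acc <- acc + b[k] * x[t - k + 1, ]
      for (k in 2:min(na, t)) acc <- acc - a[k] * y[t - k + 1, ]
    }
    y[t, ] <- acc / a[1]
  }
  y
}

#' Default preprocessing parameters
#'
#' @param n_dummy volumes to discard (NULL: take from the run's spec).
#' @param flip apply the midsagittal flip for right-sided lesions.
#' @param nuisance regress out the 24-parameter motion model plus WM/CSF
#'   means, trend and intercept.
#' @param fwhm_mm smoothing kernel FWHM (0 disables).
#' @param detrend remove per-voxel linear trends.
#' @param f_low,f_high band-pass edges in Hz (NULL disables filtering).
#' @export
preprocess_params <- function(n_dummy = NULL, flip = TRUE, nuisance = TRUE,
                              fwhm_mm = 6, detrend = TRUE,
                              f_low = 0.01, f_high = 0.1) {
  list(n_dummy = n_dummy, flip = flip, nuisance = nuisance,
       fwhm_mm = fwhm_mm, detrend = detrend, f_low = f_low, f_high = f_high)
}

#' Run the full preprocessing chain on one subject
#'
#' Stages in order: dummy-volume discard, midsagittal flip (right-lesion
#' subjects only, applied to the run and to all masks), nuisance
#' regression, spatial smoothing, linear detrend, band-pass filter. A
#' provenance log records each stage with its parameters.
#'
#' @param run a [bold_run()].
#' @param motion full-length t x 6 motion table (trimmed with the run).
#' @param masks list of 3D masks (`brain`, `wm`, `csf`, ...).
#' @param lesion_side "left" or "right".
#' @param params a [preprocess_params()] list.
#' @return list with `run` (processed), `masks` (flip-consistent),
#'   `lesion_side`, and `log` (list of stage records).
#' @export
preprocess_pipeline <- function(run, motion, masks, lesion_side = "left",
                                params = preprocess_params()) {
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- c(list(stage = stage), list(...))
  }
  n_dummy <- if (is.null(params$n_dummy)) run$spec$n_dummy else params$n_dummy
  if (n_dummy > 0) {
    run <- discard_initial(run, n_dummy)
    motion <- motion[-(seq_len(n_dummy)), , drop = FALSE]
    note("discard_initial", n_dummy = n_dummy)
  }
  if (isTRUE(params$flip) && identical(lesion_side, "right")) {
    run <- flip_midsagittal(run, "right")
    masks <- lapply(masks, function(m)
      if (is.array(m) && length(dim(m)) == 3) flip_midsagittal(m, "right") else m)
    note("flip_midsagittal", lesion_side = "right")
  }
  if (isTRUE(params$nuisance)) {
    X <- build_nuisance_design(run, motion, masks)
    run <- regress_nuisance(run, X)
    note("regress_nuisance", n_columns = ncol(X))
  }
  if (params$fwhm_mm > 0) {
    run <- smooth_gaussian(run, params$fwhm_mm)
    note("smooth_gaussian", fwhm_mm = params$fwhm_mm)
  }
  if (isTRUE(params$detrend)) {
    run <- detrend_linear(run)
    note("detrend_linear")
  }
  if (!is.null(params$f_low) && !is.null(params$f_high)) {
    run <- bandpass(run, params$f_low, params$f_high)
    note("bandpass", f_low = params$f_low, f_high = params$f_high)
  }
  list(run = run, masks = masks, lesion_side = lesion_side, log = log)
}
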