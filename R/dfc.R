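#' Parameters of the sliding-window seed connectivity analysis
#'
#' The seed is a sphere (default radius 6 mm) around a left primary motor
#' cortex coordinate, MNI (-38, -22, 56); radius 0 selects the single
#' nearest voxel. Windows cover `window_len_tr` volumes (default 22 TR,
#' i.e. 44 s at TR = 2 s) and advance by `step_tr` (default 1 TR).
#'
#' The window length is conventionally kept below `0.5 / f_lower`
#' (50 s at the default 0.01 Hz high-pass edge); [window_length_check()]
#' reports this bound but it is not enforced.
#'
#' @param seed_mni_mm seed center, mm.
#' @param seed_radius_mm sphere radius, mm (0 = single voxel).
#' @param window_len_tr window length L, in TR (>= 3).
#' @param step_tr window step s, in TR (>= 1).
#' @param f_lower,f_upper analysis band, Hz (documentation of the band the
#'   series were filtered to; used only by the window-length check).
#' @export
dfc_params <- function(seed_mni_mm = c(-38, -22, 56), seed_radius_mm = 6,
                       window_len_tr = 22L, step_tr = 1L,
                       f_lower = 0.01, f_upper = 0.1) {
  stopifnot(window_len_tr >= 3, step_tr >= 1, seed_radius_mm >= 0,
            f_lower < f_upper)
  structure(list(seed_mni_mm = as.numeric(seed_mni_mm),
                 seed_radius_mm = seed_radius_mm,
                 window_len_tr = as.integer(window_len_tr),
                 step_tr = as.integer(step_tr),
                 f_lower = f_lower, f_upper = f_upper),
            class = "dfc_params")
}

#' Window-duration bookkeeping
#'
#' @param params a [dfc_params()].
#' @param tr_seconds repetition time.
#' @return list with the window duration `window_s = L * TR` and the
#'   conventional upper bound `bound_s = 0.5 / f_lower`, plus a logical
#'   `within_bound`.
#' @export
window_length_check <- function(params, tr_seconds = 2) {
  window_s <- params$window_len_tr * tr_seconds
  bound_s <- 0.5 / params$f_lower
  list(window_s = window_s, bound_s = bound_s,
       within_bound = window_s <= bound_s)
}

#' Voxels forming the seed region
#'
#' @param spec an [acquisition_spec()].
#' @param brain_mask logical 3D array.
#' @param params a [dfc_params()].
#' @return integer vector of linear voxel indices.
#' @export
seed_voxels <- function(spec, brain_mask, params = dfc_params()) {
  mm <- grid_mm_coords(spec)
  ctr <- params$seed_mni_mm
  d2 <- (mm[, 1] - ctr[1])^2 + (mm[, 2] - ctr[2])^2 + (mm[, 3] - ctr[3])^2
  inb <- as.vector(brain_mask)
  if (params$seed_radius_mm == 0) {
    d2[!inb] <- Inf
    idx <- which.min(d2)
    if (!is.finite(d2[idx])) stop("seed sphere does not intersect the brain mask")
    return(idx)
  }
  idx <- which(inb & d2 <= params$seed_radius_mm^2)
  if (length(idx) == 0) {
    # sphere smaller than voxel spacing: fall back to the nearest in-mask voxel
    d2[!inb] <- Inf
    idx <- which.min(d2)
    if (!is.finite(d2[idx])) stop("seed sphere does not intersect the brain mask")
  }
  idx
}

#' Mean time series of the seed region
#'
#' @inheritParams seed_voxels
#' @param run a preprocessed [bold_run()].
#' @export
seed_timeseries <- function(run, params = dfc_params(),
                            brain_mask = NULL) {
  if (is.null(brain_mask))
    brain_mask <- array(TRUE, dim = run$spec$grid_dims)
  idx <- seed_voxels(run$spec, brain_mask, params)
  mat <- run_as_matrix(run)
  rowMeans(mat[, idx, drop = FALSE])
}

#' Sliding-window index ranges
#'
#' Half-open windows of length `L` stepped by `s` over `T` time points;
#' the count is `floor((T - L) / s) + 1`. Returned as a matrix of 1-based
#' inclusive `[start, end]` rows.
#'
#' @param T series length. @param L window length. @param s step.
#' @export
sliding_windows <- function(T, L, s = 1L) {
  stopifnot(L >= 1, s >= 1)
  if (T < L) stop("series shorter than one window")
  starts <- seq(1L, T - L + 1L, by = s)
  cbind(start = starts, end = starts + L - 1L)
}

#' Pearson correlation map for one window
#'
#' Correlation between the seed series and every valid voxel over the
#' window's samples. Voxels with (numerically) constant series get r = 0 so
#' downstream maps stay finite; a constant seed is an error.
#'
#' @param run a [bold_run()].
#' @param seed_series length-T numeric vector.
#' @param window length-2 integer (start, end), 1-based inclusive.
#' @param valid_mask logical 3D array (brain minus lesion); NULL = all.
#' @return numeric vector of r over all grid voxels (0 outside the mask).
#' @export
window_corr_map <- function(run, seed_series, window, valid_mask = NULL) {
  mat <- run_as_matrix(run)
  rows <- window[1]:window[2]
  s <- seed_series[rows]
  sc <- s - mean(s)
  s_ss <- sum(sc^2)
  if (s_ss < 1e-24)
    stop(sprintf("seed series is constant in window [%d, %d]",
                 window[1], window[2]))
  X <- mat[rows, , drop = FALSE]
  if (!is.null(valid_mask)) {
    vm <- as.vector(valid_mask)
  } else vm <- rep(TRUE, ncol(X))
  Xc <- sweep(X, 2, colMeans(X))
  num <- as.vector(crossprod(Xc, sc))
  den <- sqrt(colSums(Xc^2) * s_ss)
  r <- ifelse(den < 1e-24, 0, num / pmax(den, 1e-300))
  r[!vm] <- 0
  pmin(pmax(r, -1), 1)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)` with r clipped to `1 - 1e-7` in magnitude so the result
#' stays finite (|z| <= ~8.4); values with |r| > 1 + 1e-9 are rejected.
#'
#' @param r numeric vector/array of correlations.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Sliding-window seed connectivity series of one subject
#'
#' Computes the seed time series, the W = floor((T - L) / s) + 1 windowed
#' Pearson correlation maps against all valid voxels (brain minus lesion),
#' and applies the Fisher r-to-z transform. Lesion voxels are identically 0
#' and flagged invalid.
#'
#' @param run a preprocessed [bold_run()].
#' @param masks list with `brain` and optionally `lesion` 3D masks (use the
#'   flip-consistent masks returned by [preprocess_pipeline()]).
#' @param params a [dfc_params()].
#' @return an object of class `dfc_series`: list with `maps` (V x W matrix
#'   of Fisher-z values over all grid voxels, zeros outside the valid
#'   mask), `windows`, `valid` (logical vector), `grid_dims`, `params`,
#'   `subject_id`.
#' @export
compute_dfc_series <- function(run, masks, params = dfc_params()) {
  valid <- masks$brain
  if (!is.null(masks$lesion)) valid <- valid & !masks$lesion
  seed <- seed_timeseries(run, params, masks$brain)
  win <- sliding_windows(n_timepoints(run), params$window_len_tr,
                         params$step_tr)
  W <- nrow(win)
  mat <- run_as_matrix(run)
  vm <- as.vector(valid)
  V <- ncol(mat)
  maps <- matrix(0, V, W)
  for (w in seq_len(W)) {
    rows <- win[w, 1]:win[w, 2]
    s <- seed[rows]
    sc <- s - mean(s)
    s_ss <- sum(sc^2)
    if (s_ss < 1e-24)
      stop(sprintf("seed series is constant in window [%d, %d]",
                   win[w, 1], win[w, 2]))
    X <- mat[rows, vm, drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    num <- as.vector(crossprod(Xc, sc))
    den <- sqrt(colSums(Xc^2) * s_ss)
    r <- ifelse(den < 1e-24, 0, num / pmax(den, 1e-300))
    maps[vm, w] <- fisher_z(pmin(pmax(r, -1), 1))
  }
  structure(list(maps = maps, windows = win, valid = vm,
                 grid_dims = run$spec$grid_dims, params = params,
                 subject_id = run$subject_id),
            class = "dfc_series")
}

#' @export
print.dfc_series <- function(x, ...) {
  cat(sprintf("<dfc_series> %s: %d windows of %d TR, %d valid voxels\n",
              x$subject_id, nrow(x$windows), x$params$window_len_tr,
              sum(x$valid)))
  invisible(x)
}

#' One window's map as a 3D volume
#'
#' @param dfc a `dfc_series`. @param w window index (1-based).
#' @export
dfc_window_volume <- function(dfc, w) {
  array(dfc$maps[, w], dim = dfc$grid_dims)
}
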