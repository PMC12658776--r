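#' Parameters of the voxelwise group statistics
#'
#' Defaults mirror the analysis conventions of the pipeline: a voxelwise
#' two-sample comparison adjusted for age, sex and illness duration,
#' thresholded at |t| > 2.0 with a minimum cluster extent of 50 voxels
#' under 26-connectivity, uncorrected for multiple comparisons (and
#' labelled as such in every report).
#'
#' @param n_perm label permutations for the accuracy test.
#' @param t_threshold voxelwise |t| threshold.
#' @param min_cluster_voxels minimum contiguous suprathreshold extent.
#' @param alpha nominal significance level.
#' @param connectivity 6, 18 or 26 neighbour connectivity.
#' @param covariates covariate columns used by the group model.
#' @param rng_seed integer seed.
#' @export
stat_params <- function(n_perm = 1000L, t_threshold = 2.0,
                        min_cluster_voxels = 50L, alpha = 0.05,
                        connectivity = c(26L, 18L, 6L),
                        covariates = c("age_years", "sex", "duration_months"),
                        rng_seed = 1L) {
  connectivity <- as.integer(connectivity)[1]
  stopifnot(n_perm >= 1, t_threshold > 0, min_cluster_voxels >= 1,
            connectivity %in% c(6L, 18L, 26L))
  structure(as.list(environment()), class = "stat_params")
}

#' Voxelwise covariate-adjusted two-sample t-test
#'
#' Per voxel, the linear model `value ~ intercept + group + covariates` is
#' fitted across subjects and the t statistic of the group coefficient
#' returned, with group coded so that positive t means the MSP
#' (mild/moderate) adjusted mean exceeds the SSP (severe) one. With the
#' default three covariates the degrees of freedom are n - 5; with no
#' covariates the statistic reduces exactly to the pooled two-sample t.
#' Subjects with missing maps (no window in the state under test) are
#' dropped, with the count recorded in the result.
#'
#' @param maps subjects x voxels matrix (rows may be all-NA).
#' @param group per-subject labels, "MSP" or "SSP".
#' @param covariate_table data.frame with the covariate columns (sex is
#'   coded male = 1, female = 0); NULL for an unadjusted test.
#' @param params a [stat_params()].
#' @return list of class `stat_map`: `t` (per-voxel), `df`, `n_used`,
#'   `n_dropped`, `sign_convention`.
#' @export
voxelwise_group_ttest <- function(maps, group, covariate_table = NULL,
                                  params = stat_params()) {
  keep <- rowSums(!is.na(maps)) > 0
  n_dropped <- sum(!keep)
  maps <- maps[keep, , drop = FALSE]
  group <- group[keep]
  if (min(table(group)) < 2)
    stop("need at least two subjects per group")
  X <- cbind(intercept = 1, group = as.numeric(group == "MSP"))
  if (!is.null(covariate_table) && length(params$covariates) > 0) {
    covariate_table <- covariate_table[keep, , drop = FALSE]
    for (cv in params$covariates) {
      col <- covariate_table[[cv]]
      if (is.null(col)) stop("missing covariate: ", cv)
      if (cv == "sex" || is.character(col) || is.factor(col))
        col <- as.numeric(as.character(col) == "male")
      X <- cbind(X, as.numeric(col))
      colnames(X)[ncol(X)] <- cv
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear covariates: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  coefs <- qr.coef(qrX, maps)
  resid <- maps - X %*% coefs
  sigma2 <- colSums(resid^2) / df
  xtx_inv_gg <- solve(crossprod(X))[2, 2]
  tval <- coefs[2, ] / sqrt(pmax(sigma2 * xtx_inv_gg, 1e-300))
  tval[sigma2 <= 1e-300 & abs(coefs[2, ]) < 1e-12] <- 0
  structure(list(t = as.numeric(tval), df = df, n_used = n,
                 n_dropped = n_dropped,
                 sign_convention = "positive = MSP > SSP"),
            class = "stat_map")
}

#' Label connected components of a 3D mask
#'
#' Breadth-first labelling under 6-, 18- or 26-neighbour connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array, 0 outside the mask, component ids inside.
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  stopifnot(length(d) == 3, connectivity %in% c(6L, 18L, 26L))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  max_ord <- c(`6` = 1L, `18` = 2L, `26` = 3L)[as.character(connectivity)]
  offs <- offs[ord > 0 & ord <= max_ord, , drop = FALSE]
  off_lin <- offs$dx + d[1] * offs$dy + d[1] * d[2] * offs$dz
  labels <- integer(length(mask))
  comp <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] > 0) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ijk <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        j <- c(ijk) + c(offs$dx[o], offs$dy[o], offs$dz[o])
        if (any(j < 1) || any(j > d)) next
        w <- v + off_lin[o]
        if (mask[w] && labels[w] == 0) {
          labels[w] <- comp
          queue <- c(queue, w)
        }
      }
    }
  }
  array(labels, dim = d)
}

#' Cluster-extent filtering of a voxelwise t-map
#'
#' Thresholds |t| separately for each sign, labels connected components,
#' drops those below the minimum extent and reports one row per surviving
#' cluster: direction, peak mm coordinate (via the affine), extent and
#' peak t. Uncorrected for multiple comparisons.
#'
#' @param statmap a `stat_map` (or numeric t vector).
#' @param spec an [acquisition_spec()] supplying grid and affine.
#' @param params a [stat_params()].
#' @return data.frame with columns index, direction, peak_x/y/z (mm),
#'   cluster_voxels, peak_t; attribute `correction = "uncorrected"`.
#' @export
cluster_extent_filter <- function(statmap, spec, params = stat_params()) {
  tval <- if (inherits(statmap, "stat_map")) statmap$t else as.numeric(statmap)
  d <- spec$grid_dims
  stopifnot(length(tval) == prod(d))
  tvol <- array(tval, dim = d)
  rows <- list()
  for (direction in c("MSP > SSP", "MSP < SSP")) {
    mask <- if (direction == "MSP > SSP") tvol > params$t_threshold
            else tvol < -params$t_threshold
    labs <- label_components(mask, params$connectivity)
    if (max(labs) == 0) next
    for (cid in seq_len(max(labs))) {
      vox <- which(labs == cid)
      if (length(vox) < params$min_cluster_voxels) next
      peak <- vox[which.max(abs(tvol[vox]))]
      mmc <- voxel_to_mm(spec, arrayInd(peak, d))
      rows[[length(rows) + 1]] <- data.frame(
        direction = direction,
        peak_x = mmc[1], peak_y = mmc[2], peak_z = mmc[3],
        cluster_voxels = length(vox), peak_t = tvol[peak])
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(direction = character(0), peak_x = numeric(0),
               peak_y = numeric(0), peak_z = numeric(0),
               cluster_voxels = integer(0), peak_t = numeric(0))
  if (nrow(out) > 0) {
    out <- out[order(-out$cluster_voxels), , drop = FALSE]
    out <- cbind(index = seq_len(nrow(out)), out)
    rownames(out) <- NULL
  } else {
    out <- cbind(index = integer(0), out)
  }
  attr(out, "correction") <- "uncorrected"
  out
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance t with df = n_a + n_b - 2, computable from published
#' group means and SDs alone.
#'
#' @param mean_a,sd_a,n_a first group summary.
#' @param mean_b,sd_b,n_b second group summary.
#' @return list: `t`, `df`, `p` (two-sided).
#' @export
summary_ttest <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  if (se == 0) {
    tstat <- if (mean_a == mean_b) 0 else sign(mean_a - mean_b) * Inf
  } else {
    tstat <- (mean_a - mean_b) / se
  }
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Pearson correlation with a two-sided p-value
#'
#' p from the t transform `r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return list: `r`, `n`, `t`, `p`.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the inputs")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, n = n, t = sign(r) * Inf, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, t = tstat, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Pearson chi-square test of a 2 x 2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param counts 2 x 2 non-negative integer matrix.
#' @return list: `chisq`, `df`, `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("a zero marginal makes the chi-square test undefined")
  ht <- stats::chisq.test(counts, correct = FALSE)
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Demographic comparison table for a cohort
#'
#' One row per characteristic with group summaries and the matching test
#' (summary t for continuous rows, chi-square for sex), printed from the
#' metadata exactly as given.
#'
#' @param metadata cohort metadata (one row per subject).
#' @return data.frame.
#' @export
demographics_table <- function(metadata) {
  g <- split(metadata, metadata$group)
  cont_row <- function(label, col) {
    a <- g$SSP[[col]]; b <- g$MSP[[col]]
    tt <- summary_ttest(mean(a), stats::sd(a), length(a),
                        mean(b), stats::sd(b), length(b))
    data.frame(characteristic = label,
               ssp = sprintf("%.2f +/- %.2f", mean(a), stats::sd(a)),
               msp = sprintf("%.2f +/- %.2f", mean(b), stats::sd(b)),
               p_value = tt$p)
  }
  sex_tab <- table(factor(metadata$group, c("SSP", "MSP")),
                   factor(metadata$sex, c("male", "female")))
  sex <- chi_square_2x2(sex_tab)
  side_tab <- table(factor(metadata$group, c("SSP", "MSP")),
                    factor(metadata$lesion_side, c("left", "right")))
  rows <- rbind(
    cont_row("age_years", "age_years"),
    data.frame(characteristic = "sex_male_female",
               ssp = paste(sex_tab["SSP", ], collapse = "/"),
               msp = paste(sex_tab["MSP", ], collapse = "/"),
               p_value = sex$p),
    cont_row("lesion_volume_ml", "lesion_volume_ml"),
    cont_row("duration_months", "duration_months"),
    data.frame(characteristic = "lesion_side_left_right",
               ssp = paste(side_tab["SSP", ], collapse = "/"),
               msp = paste(side_tab["MSP", ], collapse = "/"),
               p_value = tryCatch(chi_square_2x2(side_tab)$p,
                                  error = function(e) NA_real_)),
    cont_row("ulfma", "ulfma"))
  rownames(rows) <- NULL
  rows
}
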