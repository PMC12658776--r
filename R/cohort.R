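#' Design of a synthetic stroke cohort
#'
#' The generator emulates the structure of a two-group chronic-stroke
#' resting-state study: each subject carries a hidden sequence of
#' connectivity states, and the correlation between a motor-cortex seed and a
#' small set of designated target regions depends on the current state, the
#' subject's severity group, and a planted between-group effect of known
#' size. Everything downstream (preprocessing, windowed connectivity,
#' state clustering, classification, voxelwise statistics) can therefore be
#' validated against ground truth.
#'
#' The BOLD model is: seed signal `s(t)` is a band-limited (0.01-0.1 Hz)
#' Gaussian process; a target voxel follows `y = beta * s + e` with unit
#' white innovation `e`, where `beta` is chosen so that the model
#' correlation equals the planted value (on the Fisher-z scale: the
#' state/group map plus a subject-level random effect plus the subject
#' signature). Nuisance structure — AR(1) noise, linear drift, motion
#' leakage, tissue-specific WM/CSF signals and an initial equilibration
#' transient — is layered on top and is what the preprocessing stage is
#' expected to remove.
#'
#' @param n_msp,n_ssp subjects per group (mild/moderate and severe).
#' @param effect_z planted group difference (MSP minus SSP) in Fisher-z
#'   connectivity inside the target regions; 0 gives exchangeable groups.
#' @param n_states_true number of hidden connectivity states.
#' @param state_dwell_mean mean dwell time of a state, in volumes (at a
#'   1-TR window step, windows and volumes are on the same footing).
#' @param ar1_coef AR(1) coefficient of the temporally correlated nuisance.
#' @param drift_amp amplitude of the per-voxel linear drift.
#' @param motion_amp scale of the motion traces and of their leakage into
#'   voxel time series.
#' @param noise_sd amplitude of the AR(1)-plus-white nuisance noise.
#' @param subject_sd SD of the subject-level random effect on planted z.
#' @param signature_sd SD of the subject-specific connectivity fingerprint
#'   (z scale, all states); non-zero values make windows of one subject
#'   recognizably alike, which is what window-level cross-validation can
#'   exploit and subject-level cross-validation cannot.
#' @param state_pattern_sd SD of each state's fixed spatial connectivity
#'   pattern over non-target brain voxels (z scale). States must differ in
#'   spatial *pattern*, not merely global level, to be distinguishable
#'   from the window-to-window fluctuation that windowed correlation
#'   estimates share across all voxels.
#' @param rare_state_subject if > 0, one extra state is appended that only
#'   this subject (by index) ever visits — the near-singleton-state pattern
#'   used to exercise participation-rate model selection.
#' @param rng_seed integer seed; identical seeds reproduce identical cohorts.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_msp = 10, n_ssp = 10,
                          effect_z = 1.2,
                          n_states_true = 2,
                          state_dwell_mean = 30,
                          ar1_coef = 0.3,
                          drift_amp = 1,
                          motion_amp = 0.5,
                          noise_sd = 1,
                          subject_sd = 0.3,
                          signature_sd = 0.15,
                          state_pattern_sd = 0.25,
                          rare_state_subject = 0,
                          rng_seed = 1L) {
  stopifnot(n_msp >= 0, n_ssp >= 0, effect_z >= 0, n_states_true >= 1,
            state_dwell_mean > 0, ar1_coef >= 0, ar1_coef < 1,
            noise_sd >= 0, subject_sd >= 0, signature_sd >= 0,
            state_pattern_sd >= 0)
  if (n_msp + n_ssp < 2) stop("a cohort needs at least two subjects")
  structure(as.list(environment()), class = "cohort_design")
}

# Designated target-region centers (mm). The first is the homotopic
# (contralesional) motor cortex, the second a midline parietal region.
target_centers_mm <- function() {
  rbind(c(38, -22, 56), c(-3, -63, 36))
}
target_radius_mm <- 16

#' Tissue and region masks for a synthetic brain
#'
#' Builds nested ellipsoidal brain / white-matter / CSF masks plus the
#' designated connectivity target regions on the grid of `spec`. The brain
#' is an ellipsoid inscribed in the grid; WM is a mid-depth shell and CSF a
#' small central blob, both clear of the seed and target regions.
#'
#' @param spec an [acquisition_spec()].
#' @param seed_mni_mm seed coordinate that must fall inside the brain mask.
#' @return list of logical arrays `brain`, `wm`, `csf`, `target` and an
#'   integer array `target_id` (0 outside targets).
#' @export
make_masks <- function(spec, seed_mni_mm = c(-38, -22, 56)) {
  d <- spec$grid_dims
  mm <- grid_mm_coords(spec)
  ctr <- voxel_to_mm(spec, matrix((d + 1) / 2, ncol = 3))
  semi <- 0.48 * d * spec$voxel_mm
  e2 <- ((mm[, 1] - ctr[1]) / semi[1])^2 +
        ((mm[, 2] - ctr[2]) / semi[2])^2 +
        ((mm[, 3] - ctr[3]) / semi[3])^2
  brain <- e2 <= 1
  csf <- e2 <= 0.04
  wm <- e2 > 0.06 & e2 <= 0.16

  tc <- target_centers_mm()
  target_id <- integer(nrow(mm))
  for (j in seq_len(nrow(tc))) {
    d2 <- (mm[, 1] - tc[j, 1])^2 + (mm[, 2] - tc[j, 2])^2 +
          (mm[, 3] - tc[j, 3])^2
    hit <- brain & !wm & !csf & d2 <= target_radius_mm^2 & target_id == 0
    target_id[hit] <- j
  }
  if (!any(target_id > 0))
    stop("grid too small to contain the designated target regions")
  seed_vox <- round(mm_to_voxel(spec, seed_mni_mm))
  if (any(seed_vox < 1) || any(seed_vox > d))
    stop("grid too small to contain the seed region")
  seed_lin <- seed_vox[1] + d[1] * (seed_vox[2] - 1) +
    d[1] * d[2] * (seed_vox[3] - 1)
  if (!brain[seed_lin])
    stop("seed coordinate falls outside the brain mask")
  shape <- function(v) array(v, dim = d)
  list(brain = shape(brain), wm = shape(wm), csf = shape(csf),
       target = shape(target_id > 0), target_id = shape(target_id))
}

#' Plant a contiguous lesion of a requested volume
#'
#' Grows an approximately spherical blob around a fixed deep subcortical
#' center in the requested hemisphere, entirely inside the brain mask, with
#' voxel count chosen so that count x voxel volume matches `volume_ml` to
#' within one voxel's volume. Deterministic (no RNG).
#'
#' @param spec an [acquisition_spec()].
#' @param masks output of [make_masks()].
#' @param lesion_side "left" or "right" (mm x < 0 is left).
#' @param volume_ml lesion volume in millilitres (1 ml = 1000 mm^3).
#' @return logical 3D array.
#' @export
plant_lesion <- function(spec, masks, lesion_side = c("left", "right"),
                         volume_ml) {
  lesion_side <- match.arg(lesion_side)
  if (volume_ml <= 0) stop("lesion volume must be positive")
  n_vox <- max(1L, round(volume_ml * 1000 / voxel_volume_mm3(spec)))
  mm <- grid_mm_coords(spec)
  hemi_sign <- if (lesion_side == "left") -1 else 1
  hemi <- as.vector(masks$brain) & (hemi_sign * mm[, 1] > 0)
  if (sum(hemi) < n_vox)
    stop(sprintf("requested %.3g ml does not fit in the %s hemisphere",
                 volume_ml, lesion_side))
  ctr <- c(hemi_sign * 27, -13, 9)  # deep subcortical, mirrored by side
  d2 <- (mm[, 1] - ctr[1])^2 + (mm[, 2] - ctr[2])^2 + (mm[, 3] - ctr[3])^2
  d2[!hemi] <- Inf
  sel <- order(d2)[seq_len(n_vox)]
  out <- logical(nrow(mm))
  out[sel] <- TRUE
  array(out, dim = spec$grid_dims)
}

# Band-limited unit-variance Gaussian process of length n sampled at dt.
# Frequencies outside [f_lo, f_hi] are zeroed in the Fourier domain.
bandlimited_gp <- function(n, dt, f_lo = 0.01, f_hi = 0.1) {
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freq <- seq(0, n - 1) / (n * dt)
  freq <- pmin(freq, 1 / dt - freq)  # two-sided
  keep <- freq >= f_lo & freq <= f_hi
  f[!keep] <- 0
  s <- Re(stats::fft(f, inverse = TRUE)) / n
  s / max(stats::sd(s), 1e-12)
}

# AR(1) process with unit marginal variance, vectorized over n_series.
ar1_noise <- function(n, n_series, coef) {
  innov_sd <- sqrt(max(1 - coef^2, 1e-12))
  x <- matrix(stats::rnorm(n * n_series), n, n_series)
  if (coef > 0) {
    for (t in 2:n) x[t, ] <- coef * x[t - 1, ] + innov_sd * x[t, ]
  }
  x
}

# Hidden-state Markov chain: stay with prob 1 - 1/dwell, otherwise jump
# uniformly to another allowed state.
sample_state_seq <- function(n, states, dwell_mean) {
  if (length(states) == 1) return(rep(states, n))
  p_stay <- 1 - 1 / dwell_mean
  seq_out <- integer(n)
  seq_out[1] <- sample(states, 1)
  for (t in 2:n) {
    if (stats::runif(1) < p_stay) {
      seq_out[t] <- seq_out[t - 1]
    } else {
      seq_out[t] <- sample(setdiff(states, seq_out[t - 1]), 1)
    }
  }
  seq_out
}

# Smoothed random-walk motion trace (t x 6): translations mm, rotations deg.
simulate_motion <- function(n, amp) {
  m <- apply(matrix(stats::rnorm(n * 6, sd = 0.02), n, 6), 2, cumsum)
  k <- stats::dnorm(-4:4, sd = 2); k <- k / sum(k)
  m <- apply(m, 2, function(col)
    stats::filter(c(rep(col[1], 4), col, rep(col[n], 4)), k)[5:(n + 4)])
  sweep(m, 2, c(amp, amp, amp, amp / 2, amp / 2, amp / 2), "*")
}

# z-scale connectivity amplitude of state m in target region j:
# each regular state "prefers" one target; the rare state anticorrelates.
state_target_z <- function(m, j, n_regular, rare) {
  if (rare) return(-0.4)
  if (((m - 1) %% 2 + 1) == ((j - 1) %% 2 + 1)) 0.7 else 0.1
}

# brain-wide background connectivity of each state: connectivity states
# are whole-map configurations, not purely local target effects, which is
# what makes windowed maps clusterable
state_background_z <- function(m, rare) {
  if (rare) return(-0.1)
  0.05 + 0.15 * ((m - 1) %% 2)
}

#' Generate a synthetic stroke rs-fMRI cohort
#'
#' See [cohort_design()] for the signal model. Group labels follow the
#' upper-limb Fugl-Meyer convention: scores <= 20 are severe (SSP), > 20
#' mild/moderate (MSP). Lesions are planted in one hemisphere and their
#' voxels carry no seed-locked signal.
#'
#' @param spec an [acquisition_spec()].
#' @param design a [cohort_design()].
#' @return a list of class `cohort` with elements `subjects` (each holding
#'   `bold` (4D array), `motion`, `record`, `lesion`), `masks`, `metadata`
#'   (one row per subject), `truth` (hidden state sequences, per-state
#'   z-maps by group, effect map, subject z offsets) and `spec`, `design`.
#' @export
generate_cohort <- function(spec, design) {
  stopifnot(inherits(spec, "acquisition_spec"), inherits(design, "cohort_design"))
  set.seed(design$rng_seed)
  masks <- make_masks(spec)
  d <- spec$grid_dims
  V <- prod(d)
  T <- spec$n_volumes
  n_sub <- design$n_msp + design$n_ssp
  groups <- rep(c("MSP", "SSP"), c(design$n_msp, design$n_ssp))

  brain_v <- as.vector(masks$brain)
  wm_v <- as.vector(masks$wm)
  csf_v <- as.vector(masks$csf)

  # seed support: voxels within one voxel diagonal of the seed coordinate
  mm <- grid_mm_coords(spec)
  seed_mm <- c(-38, -22, 56)
  seed_d2 <- (mm[, 1] - seed_mm[1])^2 + (mm[, 2] - seed_mm[2])^2 +
             (mm[, 3] - seed_mm[3])^2
  seed_sup <- brain_v & seed_d2 <= max(6, max(spec$voxel_mm))^2
  if (!any(seed_sup)) seed_sup[which.min(seed_d2)] <- TRUE
  seed_sup_arr <- array(seed_sup, dim = d)

  n_states <- design$n_states_true + (design$rare_state_subject > 0)
  rare_id <- if (design$rare_state_subject > 0) n_states else 0L

  # per-state per-group z maps over target voxels (truth, before subject terms)
  n_targets <- max(masks$target_id)
  z_state_group <- array(0, c(n_states, n_targets, 2),
                         dimnames = list(NULL, NULL, c("MSP", "SSP")))
  for (m in seq_len(n_states)) for (j in seq_len(n_targets)) {
    base <- state_target_z(m, j, design$n_states_true, m == rare_id)
    z_state_group[m, j, "MSP"] <- base + design$effect_z / 2
    z_state_group[m, j, "SSP"] <- base - design$effect_z / 2
  }
  effect_map <- numeric(V)
  effect_map[as.vector(masks$target_id) > 0] <- design$effect_z

  # fixed spatial pattern of each state over non-target brain voxels
  state_patterns <- matrix(stats::rnorm(V * n_states,
                                        sd = design$state_pattern_sd),
                           V, n_states)
  state_patterns[!brain_v | as.vector(masks$target_id) > 0, ] <- 0

  # magnetization-equilibration transient: present only when the
  # acquisition keeps dummy volumes, and decayed well within them
  dummy_transient <- if (spec$n_dummy > 0)
    5 * exp(-(seq_len(T) - 1) / (spec$n_dummy / 5)) else numeric(T)

  subjects <- vector("list", n_sub)
  state_seqs <- vector("list", n_sub)
  subj_offset <- stats::rnorm(n_sub, 0, design$subject_sd)
  meta <- vector("list", n_sub)

  for (i in seq_len(n_sub)) {
    g <- groups[i]
    ulfma <- if (g == "SSP") sample(0:20, 1) else sample(21:66, 1)
    lesion_side <- sample(c("left", "right"), 1)
    lesion_ml <- min(stats::rlnorm(1, log(5), 0.6), 40)
    age <- round(stats::rnorm(1, 52.5, 11), 1)
    sex <- sample(c("male", "female"), 1, prob = c(0.2, 0.8))
    duration <- round(3 + stats::rexp(1, 1 / 5.5), 1)
    lesion <- plant_lesion(spec, masks, lesion_side, lesion_ml)
    lesion_v <- as.vector(lesion)

    # native-space geometry: the seed is the ipsilesional M1 and the
    # designated targets sit relative to it, so right-lesion subjects
    # carry the mirrored layout; the preprocessing flip maps everyone
    # back onto the standard (left-ipsilesional) side
    if (lesion_side == "right") {
      target_id_v <- as.vector(flip_midsagittal(masks$target_id, "right"))
      seed_sup_i <- as.vector(flip_midsagittal(seed_sup_arr, "right"))
      patt_i <- apply(state_patterns, 2, function(p)
        as.vector(flip_midsagittal(array(p, dim = d), "right")))
    } else {
      target_id_v <- as.vector(masks$target_id)
      seed_sup_i <- seed_sup
      patt_i <- state_patterns
    }

    allowed <- seq_len(design$n_states_true)
    if (i == design$rare_state_subject) allowed <- c(allowed, rare_id)
    st <- sample_state_seq(T, allowed, design$state_dwell_mean)
    if (i == design$rare_state_subject) {
      # guarantee a visible rare-state episode late in the run
      len <- min(30L, T - spec$n_dummy)
      st[(T - len + 1):T] <- rare_id
    }
    state_seqs[[i]] <- st

    s <- bandlimited_gp(T, spec$tr_seconds)
    sig <- stats::rnorm(V, 0, design$signature_sd) * brain_v

    # planted z per voxel and state -> beta (y = beta s + unit white noise)
    z_vox <- matrix(0, V, n_states)
    for (m in seq_len(n_states)) {
      z_vox[, m] <- state_background_z(m, m == rare_id) + patt_i[, m]
      for (j in seq_len(n_targets)) {
        z_vox[target_id_v == j, m] <- z_state_group[m, j, g] + subj_offset[i]
      }
      z_vox[, m] <- (z_vox[, m] + sig) * brain_v
    }
    r_vox <- tanh(pmin(pmax(z_vox, -2.6), 2.6))  # |r| <= ~0.99
    beta <- r_vox / sqrt(1 - r_vox^2)
    beta[lesion_v, ] <- 0

    # seed-locked component: beta depends on the state at each time point
    bold <- matrix(stats::rnorm(V * T), T, V)
    for (m in unique(st)) {
      idx <- which(st == m)
      bold[idx, ] <- bold[idx, ] + outer(s[idx], beta[, m])
    }
    # seed region carries the seed signal itself
    bold[, seed_sup_i] <- s + 0.1 * matrix(stats::rnorm(T * sum(seed_sup_i)),
                                           T, sum(seed_sup_i))

    # nuisance: AR(1) + white mixture, drift, motion leakage, tissue signals
    if (design$noise_sd > 0) {
      nb <- sum(brain_v)
      bold[, brain_v] <- bold[, brain_v] +
        design$noise_sd * (0.7 * ar1_noise(T, nb, design$ar1_coef) +
                           0.3 * matrix(stats::rnorm(T * nb), T, nb))
    }
    if (design$drift_amp > 0) {
      tt <- seq(-1, 1, length.out = T)
      bold[, brain_v] <- bold[, brain_v] +
        outer(tt, design$drift_amp * stats::rnorm(sum(brain_v)))
    }
    motion <- simulate_motion(T, design$motion_amp)
    if (design$motion_amp > 0) {
      load <- matrix(stats::rnorm(6 * sum(brain_v), sd = 0.3), 6)
      bold[, brain_v] <- bold[, brain_v] + motion %*% load
    }
    wm_sig <- 0.8 * bandlimited_gp(T, spec$tr_seconds, 0.005, 0.15)
    csf_sig <- 0.8 * bandlimited_gp(T, spec$tr_seconds, 0.005, 0.2)
    bold[, wm_v] <- bold[, wm_v] + wm_sig
    bold[, csf_v] <- bold[, csf_v] + csf_sig
    bold[, brain_v] <- bold[, brain_v] + dummy_transient

    subjects[[i]] <- list(
      bold = bold_run(array(t(bold), dim = c(d, T)), spec,
                      subject_id = sprintf("sub-%02d", i)),
      motion = motion,
      lesion = lesion,
      record = NULL)
    meta[[i]] <- data.frame(
      subject_id = sprintf("sub-%02d", i), group = g, ulfma = ulfma,
      age_years = age, sex = sex, duration_months = duration,
      lesion_side = lesion_side,
      lesion_volume_ml = sum(lesion_v) * voxel_volume_mm3(spec) / 1000,
      stringsAsFactors = FALSE)
    subjects[[i]]$record <- meta[[i]]
  }

  metadata <- do.call(rbind, meta)
  stopifnot(all((metadata$group == "SSP") == (metadata$ulfma <= 20)))

  truth <- list(
    state_seq = state_seqs,
    z_state_group = z_state_group,
    state_patterns = state_patterns,
    effect_map = array(effect_map, dim = d),
    subject_offset = subj_offset,
    rare_state = rare_id,
    n_states = n_states)

  structure(list(subjects = subjects, masks = masks, metadata = metadata,
                 truth = truth, spec = spec, design = design),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d MSP / %d SSP), grid %s, %d volumes\n",
              nrow(x$metadata), sum(x$metadata$group == "MSP"),
              sum(x$metadata$group == "SSP"),
              paste(x$spec$grid_dims, collapse = "x"), x$spec$n_volumes))
  invisible(x)
}
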