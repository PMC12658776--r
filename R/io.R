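#' Write / read volumes as NIfTI-1
#'
#' Values and the affine round-trip exactly for double data; 4D runs keep
#' their time dimension.
#'
#' @param x 3D or 4D numeric array (logical masks are written as integer).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spec an [acquisition_spec()] supplying voxel size and affine.
#' @export
write_volume <- function(x, path, spec) {
  if (is.logical(x)) x <- array(as.integer(x), dim = dim(x))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- spec$voxel_mm
  img <- RNifti::`sform<-`(img, structure(spec$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @return `read_volume()` returns a list with `data` (array) and
#'   `affine` (4 x 4 matrix).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img),
       affine = unclass(structure(RNifti::xform(img),
                                  imagedim = NULL, code = NULL))[, ,
                                    drop = TRUE][1:4, 1:4])
}

#' Save a synthetic cohort to disk
#'
#' Per subject: the 4D BOLD run (`.nii.gz`), the lesion mask, and the
#' motion table (6-column TSV); cohort-wide: the tissue masks, the subject
#' metadata CSV and a ground-truth JSON sidecar.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  for (m in c("brain", "wm", "csf", "target"))
    write_volume(cohort$masks[[m]], file.path(dir, paste0("mask_", m, ".nii.gz")),
                 spec)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    id <- s$bold$subject_id
    write_volume(s$bold$data, file.path(dir, paste0(id, "_bold.nii.gz")), spec)
    write_volume(s$lesion, file.path(dir, paste0(id, "_lesion.nii.gz")), spec)
    utils::write.table(s$motion, file.path(dir, paste0(id, "_motion.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(cohort$metadata, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(state_seq = truth$state_seq,
         rare_state = truth$rare_state, n_states = truth$n_states,
         subject_offset = truth$subject_offset),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# deterministic per-stage seed fan-out from one global seed
stage_seed <- function(global_seed, stage_index) {
  as.integer((as.numeric(global_seed) + 101 * stage_index) %% 2147483647)
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters plus a global seed that fans out to
#' per-stage seeds through a fixed counter scheme, so one (config, seed)
#' pair determines every artifact. Unknown keys in a module block are
#' rejected with the offending path.
#'
#' @param preset "desk" (20 x 24 x 20 grid at 9 mm, width-1/8 network,
#'   10 epochs) or "canonical" (61 x 73 x 61 at 3 mm, full-width network,
#'   240-volume runs; heavy — supported by configuration, not exercised by
#'   the test suite).
#' @param rng_seed global integer seed.
#' @param out_dir optional output directory for artifacts.
#' @param design,dfc,states,cnn,stats named lists of overrides merged
#'   over the preset defaults of [cohort_design()], [dfc_params()],
#'   [state_params()], [cnn_config()] and [stat_params()].
#' @param preprocess overrides for [preprocess_params()].
#' @param n_folds,granularity,n_perm cross-validation protocol settings.
#' @export
run_config <- function(preset = c("desk", "canonical"), rng_seed = 1L,
                       out_dir = NULL, design = list(),
                       preprocess = list(), dfc = list(), states = list(),
                       cnn = list(), stats = list(), n_folds = 10L,
                       granularity = "window", n_perm = 1000L) {
  preset <- match.arg(preset)
  check_keys <- function(block, fn, path) {
    legal <- names(formals(fn))
    bad <- setdiff(names(block), legal)
    if (length(bad) > 0)
      stop(sprintf("unknown config key%s under '%s': %s",
                   if (length(bad) > 1) "s" else "", path,
                   paste(bad, collapse = ", ")))
    block
  }
  structure(list(
    preset = preset, rng_seed = as.integer(rng_seed), out_dir = out_dir,
    design = check_keys(design, cohort_design, "design"),
    preprocess = check_keys(preprocess, preprocess_params, "preprocess"),
    dfc = check_keys(dfc, dfc_params, "dfc"),
    states = check_keys(states, state_params, "states"),
    cnn = check_keys(cnn, cnn_config, "cnn"),
    stats = check_keys(stats, stat_params, "stats"),
    n_folds = as.integer(n_folds), granularity = granularity,
    n_perm = as.integer(n_perm)), class = "run_config")
}

merge_args <- function(fn, defaults, overrides) {
  do.call(fn, utils::modifyList(defaults, overrides))
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain any of [run_config()]'s arguments; module blocks
#' are named lists. Unknown keys are rejected with their path.
#'
#' @param path YAML file.
#' @export
run_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configurations requires the yaml package")
  conf <- yaml::read_yaml(path)
  legal <- names(formals(run_config))
  bad <- setdiff(names(conf), legal)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, conf)
}

#' Run the complete pipeline
#'
#' simulate -> preprocess -> windowed seed connectivity -> connectivity
#' states -> cross-validated 3D-CNN classification -> group statistics,
#' with a provenance log and (when `out_dir` is set) CSV/NIfTI artifacts.
#' Rerunning with the same configuration reproduces every numeric output.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result`: `cohort`, `dfc`, `states`,
#'   `cv_report`, `demographics`, `cluster_tables`, `provenance`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  desk <- config$preset == "desk"
  provenance <- list()
  t_all <- proc.time()[3]
  note <- function(stage, params) {
    provenance[[length(provenance) + 1]] <<-
      list(stage = stage, params = params,
           elapsed_s = round(proc.time()[3] - t_all, 2))
  }

  spec <- if (desk) acq_desk() else acq_canonical()
  design_defaults <- list(rng_seed = stage_seed(config$rng_seed, 1))
  if (!desk) design_defaults <- c(design_defaults,
                                  list(n_msp = 29, n_ssp = 40))
  design <- merge_args(cohort_design, design_defaults, config$design)
  cohort <- generate_cohort(spec, design)
  note("simulate", list(preset = config$preset, n_subjects = nrow(cohort$metadata)))

  pp <- merge_args(preprocess_params, list(), config$preprocess)
  dfc_p <- merge_args(dfc_params, list(), config$dfc)
  if (desk && !("window_len_tr" %in% names(config$dfc))) {
    chk <- window_length_check(dfc_p, spec$tr_seconds)
    stopifnot(chk$within_bound)
  }
  dfc_list <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    masks_i <- cohort$masks
    masks_i$lesion <- s$lesion
    pre <- preprocess_pipeline(s$bold, s$motion, masks_i,
                               s$record$lesion_side, pp)
    dfc_list[[i]] <- compute_dfc_series(pre$run, pre$masks, dfc_p)
  }
  note("preprocess+dfc", list(params = pp[lengths(pp) > 0],
                              windows = nrow(dfc_list[[1]]$windows)))

  st_defaults <- list(rng_seed = stage_seed(config$rng_seed, 2))
  if (desk) st_defaults$k_range <- 2:4
  st_p <- merge_args(state_params, st_defaults, config$states)
  pooled <- pool_dfc_features(dfc_list)
  sel <- select_k_and_retain(pooled$X, pooled$subject_of_window, st_p,
                             pooled$exemplar_idx)
  note("states", list(k = sel$k, retained = sel$retained,
                      participation = round(sel$participation, 3)))

  cnn_defaults <- list(rng_seed = stage_seed(config$rng_seed, 3))
  cnn_cfg <- if (desk)
    merge_args(cnn_config_desk, c(cnn_defaults, list(input_dims = spec$grid_dims)),
               config$cnn)
  else
    merge_args(cnn_config, c(cnn_defaults, list(input_dims = spec$grid_dims)),
               config$cnn)
  Xcnn <- do.call(cbind, lapply(dfc_list, `[[`, "maps"))
  labels <- rep(cohort$metadata$group,
                vapply(dfc_list, function(d) nrow(d$windows), integer(1)))
  subj <- rep(cohort$metadata$subject_id,
              vapply(dfc_list, function(d) nrow(d$windows), integer(1)))
  cv <- cross_validate(Xcnn, labels, cnn_cfg, config$granularity, subj,
                       config$n_folds, config$n_perm)
  note("cnn", list(granularity = config$granularity,
                   mean_bac = round(100 * cv$summary$mean[
                     cv$summary$metric == "balanced_accuracy"], 2)))

  stat_defaults <- list(rng_seed = stage_seed(config$rng_seed, 4))
  if (desk) stat_defaults$min_cluster_voxels <- 5L
  st <- merge_args(stat_params, stat_defaults, config$stats)
  demo <- demographics_table(cohort$metadata)
  msm <- subject_state_mean_maps(pooled$X, sel$model$labels,
                                 pooled$subject_of_window, sel$retained)
  group_of <- cohort$metadata$group[match(msm$subjects,
                                          cohort$metadata$subject_id)]
  cov_tab <- cohort$metadata[match(msm$subjects, cohort$metadata$subject_id),
                             , drop = FALSE]
  cluster_tables <- list()
  t_maps <- list()
  for (s in names(msm$maps)) {
    present <- rowSums(!is.na(msm$maps[[s]])) > 0
    if (min(table(factor(group_of[present], c("MSP", "SSP")))) < 2) {
      note("stats_skip", list(state = s,
                              reason = "fewer than two subjects per group"))
      next
    }
    # small cohorts cannot support the covariate model; fall back to the
    # unadjusted two-sample test rather than fail on a deficient design
    tmap_valid <- tryCatch(
      voxelwise_group_ttest(msm$maps[[s]], group_of, cov_tab, st),
      error = function(e) {
        note("stats_unadjusted", list(state = s, reason = conditionMessage(e)))
        st0 <- st; st0$covariates <- character(0)
        voxelwise_group_ttest(msm$maps[[s]], group_of, NULL, st0)
      })
    tfull <- numeric(prod(spec$grid_dims))
    tfull[pooled$common_valid] <- tmap_valid$t
    t_maps[[s]] <- tfull
    tab <- cluster_extent_filter(tfull, spec, st)
    if (nrow(tab) > 0) tab <- cbind(state = as.integer(s), tab)
    cluster_tables[[s]] <- tab
  }
  note("stats", list(states_tested = names(msm$maps),
                     correction = "uncorrected"))

  out <- structure(list(cohort = cohort, dfc = dfc_list,
                        states = sel, cv_report = cv,
                        demographics = demo,
                        cluster_tables = cluster_tables,
                        t_maps = t_maps,
                        provenance = provenance, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
  out
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- result$cohort$spec
  utils::write.csv(result$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(cv_report_table(result$cv_report),
                   file.path(dir, "cv_report.csv"), row.names = FALSE)
  utils::write.csv(result$states$pr_table,
                   file.path(dir, "participation_rates.csv"),
                   row.names = FALSE)
  for (s in names(result$cluster_tables)) {
    tab <- result$cluster_tables[[s]]
    utils::write.csv(tab, file.path(dir, sprintf("clusters_state%s.csv", s)),
                     row.names = FALSE)
    write_volume(array(result$t_maps[[s]], dim = spec$grid_dims),
                 file.path(dir, sprintf("tmap_state%s.nii.gz", s)), spec)
  }
  jsonlite::write_json(result$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$cohort)
  cat(sprintf("  states: k = %d, retained %s\n", x$states$k,
              paste(x$states$retained, collapse = ", ")))
  print(x$cv_report)
  invisible(x)
}
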