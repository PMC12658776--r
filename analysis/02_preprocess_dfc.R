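#!/usr/bin/env Rscript
# Preprocess every subject (dummy discard, midsagittal flip for
# right-sided lesions, nuisance regression, smoothing, detrend, band-pass)
# and compute the sliding-window seed connectivity series. Writes one 4D
# dFC NIfTI per subject plus a summary table under results/.

suppressPackageStartupMessages(library(strokedfc))

seed <- 1L
spec <- acq_desk(n_volumes = 10L + 10L + 21L)
design <- cohort_design(n_msp = 10, n_ssp = 10, effect_z = 1.2,
                        rng_seed = strokedfc:::stage_seed(seed, 1))
cohort <- generate_cohort(spec, design)

dir.create("results/dfc", recursive = TRUE, showWarnings = FALSE)
rows <- list()
dfc_list <- list()
for (i in seq_along(cohort$subjects)) {
  s <- cohort$subjects[[i]]
  masks <- cohort$masks
  masks$lesion <- s$lesion
  pre <- preprocess_pipeline(s$bold, s$motion, masks, s$record$lesion_side)
  dfc <- compute_dfc_series(pre$run, pre$masks)
  dfc_list[[i]] <- dfc
  write_volume(array(dfc$maps, c(spec$grid_dims, nrow(dfc$windows))),
               file.path("results/dfc", paste0(s$bold$subject_id,
                                               "_dfc.nii.gz")), spec)
  # post-flip, the planted targets sit at the standard coordinates
  tgt <- as.vector(cohort$masks$target) & dfc$valid
  rows[[i]] <- data.frame(subject_id = s$bold$subject_id,
                          group = s$record$group,
                          n_windows = nrow(dfc$windows),
                          n_valid_voxels = sum(dfc$valid),
                          mean_target_z = mean(dfc$maps[tgt, ]))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/dfc_summary.csv", row.names = FALSE)
print(tab)

message(sprintf(
  "Mean seed-target z: MSP %.3f vs SSP %.3f (planted difference %.2f, ",
  mean(tab$mean_target_z[tab$group == "MSP"]),
  mean(tab$mean_target_z[tab$group == "SSP"]), design$effect_z),
  "attenuated by nuisance noise and windowed estimation).")
saveRDS(dfc_list, "results/dfc/dfc_series.rds")  # scratch for later steps
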