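# 04 - Exposure-connectivity cluster inference.
#
# Fits the voxelwise GLM (metric ~ log2 exposure + age + sex + education),
# forms sign-split clusters at the p < 0.001 voxel threshold, assigns
# cluster-extent p-values by permutation (residualized-exposure shuffling)
# with BH-FDR across candidates, and expresses each cluster's effect as a
# percent change per doubling of exposure with its 95% CI.

source("analysis/00_config.R")

dc <- denoise_cohort()
cohort <- dc$cohort
expo <- cohort$exposures_prepared[dc$kept, ]
cova <- cohort$covariates[dc$kept, ]
mask <- cohort$masks$brain
vox <- cohort$config$voxel_size

analyses <- list(
  list(metric = "GCOR", exposure = "log2_sum5"),
  list(metric = "LCOR", exposure = "log2_bde153"))

rows <- list()
for (an in analyses) {
  maps <- lapply(dc$kept, function(i) {
    d <- dc$denoised[[i]]
    if (an$metric == "GCOR") gcor_map(d$img, censored = d$censored)
    else lcor_map(d$img, neighborhood_fwhm = 25, censored = d$censored)
  })
  y <- stack_maps(maps)
  ci <- cluster_extent_inference(y, expo[[an$exposure]], cova, mask, vox,
                                 n_perm = N_PERM, seed = COHORT_SEED + 131L)
  cat(sprintf("\n%s ~ %s: %d candidate cluster(s)\n", an$metric,
              an$exposure, length(ci$clusters)))
  for (cl in ci$clusters) {
    eff <- summarize_cluster_effect(y, cl, mask, expo[[an$exposure]], cova)
    cat(sprintf(
      "  center (%s), %.2f cm^3, sign %+d, p = %.3g, p-FDR = %.3g, %+.1f%% per doubling (%.1f%% to %.1f%%)\n",
      paste(cl$peak, collapse = ","), cl$volume_cm3, cl$sign, cl$p,
      cl$p_fdr, eff$percent_per_doubling, eff$percent_ci[1],
      eff$percent_ci[2]))
    rows[[length(rows) + 1L]] <- data.frame(
      metric = an$metric, exposure = an$exposure,
      center = paste(cl$peak, collapse = ","), volume_cm3 = cl$volume_cm3,
      size = cl$size, sign = cl$sign, p = cl$p, p_fdr = cl$p_fdr,
      percent_per_doubling = eff$percent_per_doubling,
      percent_lo = eff$percent_ci[1], percent_hi = eff$percent_ci[2])
  }
}
clusters <- do.call(rbind, rows)
write.csv(clusters, results_dir("clusters.csv"), row.names = FALSE)
cat("\nCluster table written to results/clusters.csv\n")
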