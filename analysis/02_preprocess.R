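# 02 - Denoise the functional time series and apply motion QC.
#
# Runs the scrubbing / nuisance-regression / detrend / band-pass chain per
# participant and applies the exclusion rules (mean FD > 0.4 mm or > 40%
# of frames censored).  Writes the per-participant QC table.

source("analysis/00_config.R")

dc <- denoise_cohort()
write.csv(dc$qc, results_dir("qc.csv"), row.names = FALSE)

cat(sprintf("Denoised %d participants: mean FD %.3f mm (range %.3f-%.3f), mean censored fraction %.1f%%\n",
            nrow(dc$qc), mean(dc$qc$mean_fd), min(dc$qc$mean_fd),
            max(dc$qc$mean_fd), 100 * mean(dc$qc$censored_fraction)))
dropped <- dc$qc[!dc$qc$keep, ]
if (nrow(dropped)) {
  cat(sprintf("Excluded %d participant(s):\n", nrow(dropped)))
  cat(sprintf("  #%d: %s\n", dropped$participant_id, dropped$reason), sep = "")
} else cat("No participants excluded for motion.\n")
cat(sprintf("%d participants enter the connectivity analyses.\n",
            length(dc$kept)))
cat("QC table written to results/qc.csv\n")
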