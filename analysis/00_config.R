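# Shared settings for the numbered analysis drivers.  Every driver is
# self-contained: it regenerates what it needs from the seeded synthetic
# cohort (generation is deterministic and cheap), so the scripts can be run
# independently or in order from the repository root:
#
#   Rscript analysis/01_simulate.R
#   ...
#   Rscript analysis/06_report.R
#
# Tables land under results/; bulky binary artifacts (NIfTI volumes) go
# under scratch/ and are not part of the deliverable.

library(pbdefc)

COHORT_SEED <- 11L
N_PARTICIPANTS <- 60L
N_PERM <- 199L        # cluster-extent and PDM permutations
N_BOOT <- 499L        # mediation bootstrap resamples
N_PDMS <- 5L

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(dirname(d), recursive = TRUE, showWarnings = FALSE)
  d
}

cohort_config <- function() default_config(n_participants = N_PARTICIPANTS,
                                           seed = COHORT_SEED)

# denoised images + QC for every participant (used by drivers 02-05)
denoise_cohort <- function(cfg = cohort_config()) {
  cohort <- generate_cohort(cfg)
  ts <- generate_timeseries(cohort, cfg)
  den <- lapply(seq_len(cfg$n_participants), function(i)
    denoise_participant(ts$images[[i]], ts$motion[[i]],
                        ts$wm_ts[[i]], ts$csf_ts[[i]]))
  qc <- data.frame(
    participant_id = seq_len(cfg$n_participants),
    mean_fd = vapply(den, function(d) d$qc$mean_fd, numeric(1)),
    censored_fraction = vapply(den, function(d) d$qc$censored_fraction,
                               numeric(1)))
  excl <- exclude_participants(qc$mean_fd, qc$censored_fraction)
  qc$keep <- excl$keep
  qc$reason <- excl$reason
  list(cohort = cohort, denoised = den, qc = qc, kept = which(excl$keep))
}
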