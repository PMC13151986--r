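#' Default synthetic-cohort generator configuration
#'
#' Builds the configuration of the seeded synthetic-cohort generator.  The
#' defaults emulate the measured quantities of a pregnancy birth cohort with
#' an adolescent resting-state fMRI follow-up: five correlated log-normal
#' PBDE congener serum concentrations (ng/g lipid) with limit-of-detection
#' censoring, age / sex / maternal-education covariates, neurobehavioral
#' T-score outcomes with known direct and mediated exposure effects, and 4D
#' voxel time series with a planted cluster whose global connectivity
#' declines with exposure (Sigma5BDE) and a region whose local connectivity
#' rises with BDE-153.
#'
#' Exposure marginals are calibrated to published cohort summaries:
#' geometric means 1.1, 22, 4.9, 4.0, 4.9 ng/g lipid for BDE-28, -47, -99,
#' -100, -153; detection rates 88.8/99.4/99.4/97.6/97.1 percent; log-scale
#' SDs derived from the ratio of arithmetic to geometric means under the
#' log-normal law; pairwise log-scale correlations default to the reported
#' range midpoint (0.46 to 0.93) with the two named extreme pairs pinned.
#' The planted global-correlation effect is calibrated so that a doubling of
#' Sigma5BDE lowers cluster GCOR by roughly 22 percent, and the planted
#' local-correlation effect so that a doubling of BDE-153 raises cluster
#' LCOR by roughly 5 percent.
#'
#' @param n_participants number of participants.
#' @param grid_shape integer vector of 3 voxel counts per axis
#'   (product must be >= 64).
#' @param voxel_size voxel edge length, mm.
#' @param n_frames frames per run.
#' @param n_runs number of runs (`n_frames * n_runs >= 60`).
#' @param tr repetition time, seconds.
#' @param congener_geomeans geometric means of the 5 congeners, ng/g lipid.
#' @param congener_log_sd SDs of the natural-log concentrations.
#' @param congener_log_corr 5x5 correlation matrix of log concentrations
#'   (symmetric positive-definite, unit diagonal).
#' @param detection_rates fraction of samples above the LOD, per congener,
#'   each in (0, 1].
#' @param covariate_params list: `age_mean`, `age_sd` (years), `sex_prob`
#'   (probability female), `education_probs` (4 ordered category
#'   probabilities).
#' @param effect_params list of planted path sizes: `a_gcor` (change in
#'   cluster-to-global coupling per doubling of Sigma5BDE), `b_outcome`
#'   (T-score points per unit of the latent mediator), `c_prime` (direct
#'   T-score effect per doubling), `lcor_effect` (local-coupling change per
#'   doubling of BDE-153), `a_second` / `b_second` (second planted
#'   mediation direction), and covariate effects `age_beta`, `sex_beta`,
#'   `edu_beta` on the outcome.
#' @param noise_params list: `ts_noise_sd` (voxel noise SD), `outcome_noise_sd`
#'   (T-score points), `mediator_noise_sd`, `motion_spike_rate`
#'   (per-frame spike probability).
#' @param seed integer RNG seed.
#'
#' @return A list of class `generator_config`.
#' @export
default_config <- function(n_participants = 60,
                           grid_shape = c(10L, 10L, 8L),
                           voxel_size = 4,
                           n_frames = 100,
                           n_runs = 2,
                           tr = 2,
                           congener_geomeans = c(bde28 = 1.1, bde47 = 22,
                                                 bde99 = 4.9, bde100 = 4.0,
                                                 bde153 = 4.9),
                           congener_log_sd = c(0.87, 1.00, 1.03, 1.03, 1.08),
                           congener_log_corr = default_congener_corr(),
                           detection_rates = c(0.888, 0.994, 0.994,
                                               0.976, 0.971),
                           covariate_params = list(
                             age_mean = 12.3, age_sd = 0.7,
                             sex_prob = 0.587,
                             education_probs = c(0.252, 0.280, 0.315, 0.153)),
                           effect_params = list(
                             a_gcor = -0.29, b_outcome = -4.5, c_prime = 1.0,
                             lcor_effect = 0.22,
                             a_second = 0.12, b_second = -6.75,
                             age_beta = -1.0, sex_beta = 2.0, edu_beta = -1.0),
                           noise_params = list(
                             ts_noise_sd = 1.0, outcome_noise_sd = 9.0,
                             mediator_noise_sd = 0.1,
                             motion_spike_rate = 0.05),
                           seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              grid_shape = as.integer(grid_shape),
              voxel_size = voxel_size,
              n_frames = as.integer(n_frames),
              n_runs = as.integer(n_runs),
              tr = tr,
              congener_geomeans = congener_geomeans,
              congener_log_sd = congener_log_sd,
              congener_log_corr = congener_log_corr,
              detection_rates = detection_rates,
              covariate_params = covariate_params,
              effect_params = effect_params,
              noise_params = noise_params,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

#' Default log-scale congener correlation matrix
#'
#' Off-diagonal correlations are set to the midpoint (0.695) of the reported
#' cohort range, with the two extreme pairs pinned: 0.93 between BDE-47 and
#' BDE-99 and 0.46 between BDE-99 and BDE-153.
#'
#' @return 5x5 correlation matrix.
#' @export
default_congener_corr <- function() {
  r <- matrix(0.695, 5, 5)
  diag(r) <- 1
  r[2, 3] <- r[3, 2] <- 0.93  # BDE-47 ~ BDE-99
  r[3, 5] <- r[5, 3] <- 0.46  # BDE-99 ~ BDE-153
  dimnames(r) <- list(names_congeners(), names_congeners())
  r
}

names_congeners <- function() c("bde28", "bde47", "bde99", "bde100", "bde153")

#' Validate a generator configuration
#'
#' @param config a `generator_config`.
#' @return `config`, invisibly, after checking all invariants.
#' @export
validate_config <- function(config) {
  stopifnot(length(config$grid_shape) == 3L)
  if (prod(config$grid_shape) < 64)
    stop("grid_shape product must be >= 64")
  if (config$n_frames * config$n_runs < 60)
    stop("n_frames * n_runs must be >= 60")
  r <- config$congener_log_corr
  if (!isTRUE(all.equal(r, t(r))) || any(abs(diag(r) - 1) > 1e-12))
    stop("congener_log_corr must be symmetric with unit diagonal")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("congener_log_corr is not positive-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  dr <- config$detection_rates
  if (any(dr <= 0 | dr > 1)) stop("detection_rates must lie in (0, 1]")
  if (any(config$congener_geomeans <= 0))
    stop("congener_geomeans must be positive")
  ep <- config$covariate_params$education_probs
  if (length(ep) != 4 || any(ep < 0))
    stop("education_probs must be 4 non-negative probabilities")
  invisible(config)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# baseline couplings of the latent-factor time-series model
.base_coupling <- list(global = 0.8, local = 0.6, nuisance = 0.3)

#' Geometry masks for the synthetic grid
#'
#' Lays out a central ellipsoidal brain mask, two small corner noise
#' compartments (white-matter- and CSF-like), and three disjoint planted
#' regions inside the brain: the global-correlation (GCOR) effect cluster,
#' the local-correlation (LCOR) effect cluster, and a second spatial pattern
#' carrying the second planted mediation direction.
#'
#' @param config a `generator_config`.
#' @return list of logical 3D arrays: `brain`, `wm`, `csf`, `gcor_cluster`,
#'   `lcor_cluster`, `pattern2`.
#' @export
make_masks <- function(config) {
  d <- config$grid_shape
  ctr <- (d + 1) / 2
  ax <- 0.45 * d
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  rel <- sweep(sweep(as.matrix(g), 2, ctr), 2, ax, "/")
  brain <- array(rowSums(rel^2) <= 1, dim = d)

  block <- function(frac_ctr, half) {
    ctr_vox <- round(frac_ctr * d)
    lo <- pmax(ctr_vox - half, 1L)
    hi <- pmin(ctr_vox + half, d)
    m <- array(FALSE, dim = d)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  }
  gcor_cluster <- block(c(0.50, 0.42, 0.55), c(1L, 1L, 1L)) & brain
  lcor_cluster <- block(c(0.72, 0.66, 0.50), c(1L, 1L, 1L)) & brain
  pattern2     <- block(c(0.34, 0.66, 0.45), c(0L, 1L, 0L)) & brain
  lcor_cluster <- lcor_cluster & !gcor_cluster
  pattern2     <- pattern2 & !gcor_cluster & !lcor_cluster

  corner <- function(side) {
    m <- array(FALSE, dim = d)
    if (side == 1) m[1:2, 1:2, 1:2] <- TRUE
    else m[(d[1] - 1):d[1], 1:2, 1:2] <- TRUE
    m & !brain
  }
  wm <- corner(1)
  csf <- corner(2)
  if (sum(wm) < 6 || sum(csf) < 6)
    stop("grid too small to place noise compartments outside the brain mask")
  if (sum(gcor_cluster) < 4 || sum(lcor_cluster) < 2 || sum(pattern2) < 2)
    stop("grid too small to place planted clusters inside the brain mask")
  list(brain = brain, wm = wm, csf = csf,
       gcor_cluster = gcor_cluster, lcor_cluster = lcor_cluster,
       pattern2 = pattern2)
}

#' Generate a synthetic cohort
#'
#' Draws correlated log-normal congener concentrations with LOD censoring,
#' covariates, latent mediators, and neurobehavioral T-score outcomes with
#' known planted direct and mediated exposure effects.  The LOD of each
#' congener is the empirical quantile of its generated distribution at
#' (1 - detection rate); values below it are stored censored at the LOD with
#' a below-LOD flag (substitution is the exposure-preparation stage's job).
#'
#' Outcomes follow a linear structural model: for the planted outcome,
#' T-score = 50 + c_prime * (log2 Sigma5BDE - mean) + b_outcome * (m1 - mean)
#' + b_second * (m2 - mean) + covariate effects + noise, where m1 and m2 are
#' the two latent mediators (cluster-to-global and second-pattern coupling).
#'
#' @param config a `generator_config`.
#' @return list with elements `exposures` (raw censored concentrations, LOD
#'   flags and LODs), `exposures_prepared` (after LOD substitution, Sigma5BDE
#'   and log2 transforms), `covariates`, `outcomes` (three T-scores:
#'   `tscore_social` with planted mediation, `tscore_anxiety` with a direct
#'   effect only, `tscore_memory` null), and `truth` (planted masks, true
#'   paths, latent mediators, noiseless linear predictors).
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  eff <- config$effect_params
  np <- config$noise_params
  cp <- config$covariate_params

  sdl <- config$congener_log_sd
  sigma <- diag(sdl) %*% config$congener_log_corr %*% diag(sdl)
  zlog <- MASS::mvrnorm(n, mu = log(config$congener_geomeans), Sigma = sigma)
  conc <- exp(zlog)
  colnames(conc) <- names_congeners()

  lod <- vapply(seq_len(5), function(j)
    as.numeric(stats::quantile(conc[, j], 1 - config$detection_rates[j])),
    numeric(1))
  names(lod) <- names_congeners()
  below <- sweep(conc, 2, lod, "<")
  conc_cens <- conc
  conc_cens[below] <- rep(lod, each = n)[below]

  exposures <- data.frame(participant_id = seq_len(n), conc_cens)
  for (j in names_congeners()) {
    exposures[[paste0(j, "_below_lod")]] <- below[, j]
    exposures[[paste0(j, "_lod")]] <- lod[[j]]
  }

  covariates <- data.frame(
    participant_id = seq_len(n),
    age = stats::rnorm(n, cp$age_mean, cp$age_sd),
    sex = stats::rbinom(n, 1, cp$sex_prob),
    education = sample.int(4, n, replace = TRUE,
                           prob = cp$education_probs / sum(cp$education_probs)))

  prepared <- prepare_exposures(exposures)
  x <- prepared$log2_sum5

  # latent mediators: couplings of the planted regions to the global signal
  m1 <- .base_coupling$global + eff$a_gcor * (x - mean(x)) +
    stats::rnorm(n, 0, np$mediator_noise_sd)
  m2 <- .base_coupling$global + eff$a_second * (x - mean(x)) +
    stats::rnorm(n, 0, np$mediator_noise_sd)
  # negative couplings are allowed (anticorrelation with the global
  # signal); the clamp only guards against extreme tails so the planted
  # exposure->mediator path stays linear over the realistic range
  m1 <- clamp(m1, -1, 3)
  m2 <- clamp(m2, -1, 3)

  cov_term <- eff$age_beta * (covariates$age - cp$age_mean) +
    eff$sex_beta * (covariates$sex - cp$sex_prob) +
    eff$edu_beta * (covariates$education - 2.5)

  lp_social <- 50 + eff$c_prime * (x - mean(x)) +
    eff$b_outcome * (m1 - mean(m1)) + eff$b_second * (m2 - mean(m2)) +
    cov_term
  lp_anxiety <- 50 + 1.5 * (x - mean(x)) + cov_term
  lp_memory <- rep(50, n)

  outcomes <- data.frame(
    participant_id = seq_len(n),
    tscore_social = lp_social + stats::rnorm(n, 0, np$outcome_noise_sd),
    tscore_anxiety = lp_anxiety + stats::rnorm(n, 0, np$outcome_noise_sd),
    tscore_memory = lp_memory + stats::rnorm(n, 0, np$outcome_noise_sd))

  masks <- make_masks(config)
  truth <- list(
    gcor_cluster_mask = masks$gcor_cluster,
    lcor_cluster_mask = masks$lcor_cluster,
    pattern2_mask = masks$pattern2,
    true_a = eff$a_gcor,
    true_b = eff$b_outcome,
    true_c_prime = eff$c_prime,
    true_indirect = eff$a_gcor * eff$b_outcome,
    true_a2 = eff$a_second,
    true_b2 = eff$b_second,
    mediators = data.frame(participant_id = seq_len(n), m1 = m1, m2 = m2),
    linear_predictors = data.frame(participant_id = seq_len(n),
                                   tscore_social = lp_social,
                                   tscore_anxiety = lp_anxiety,
                                   tscore_memory = lp_memory))

  list(exposures = exposures, exposures_prepared = prepared,
       covariates = covariates, outcomes = outcomes, truth = truth,
       masks = masks, config = config)
}

#' Generate synthetic 4D voxel time series and motion traces
#'
#' Each voxel's series is a low-rank latent-factor mixture: a shared global
#' latent, region latents, a nuisance latent shared with the noise
#' compartments, a per-voxel linear drift, and white noise.  The coupling of
#' the GCOR-cluster voxels (and of the second-pattern voxels) to the global
#' latent equals the participant's latent mediator, so global connectivity of
#' the planted cluster declines with log2 Sigma5BDE by `a_gcor` per doubling;
#' within-neighborhood coupling in the LCOR cluster rises with log2 BDE-153.
#' Motion traces are slow random walks with spikes at the configured rate;
#' spike frames also receive a global signal artifact.
#'
#' @param cohort output of [generate_cohort()].
#' @param config the same `generator_config` (seed lineage must match).
#' @return list with `images` (list of [ts_image()]), `motion` (list of
#'   frames x 6 matrices: 3 translations mm, 3 rotations rad), `wm_ts` /
#'   `csf_ts` (noise-compartment series per participant), and `masks`.
#' @export
generate_timeseries <- function(cohort, config) {
  if (!identical(cohort$config$seed, config$seed))
    stop("cohort was generated under a different seed than `config`")
  masks <- cohort$masks
  n <- config$n_participants
  t_run <- config$n_frames
  nr <- config$n_runs
  np <- config$noise_params
  eff <- config$effect_params

  brain_idx <- which(masks$brain)
  v_brain <- length(brain_idx)
  in_gcor <- masks$gcor_cluster[masks$brain]
  in_lcor <- masks$lcor_cluster[masks$brain]
  in_pat2 <- masks$pattern2[masks$brain]

  x153 <- cohort$exposures_prepared$log2_bde153
  mu_loc <- clamp(.base_coupling$local +
                    eff$lcor_effect * (x153 - mean(x153)), 0.05, 3)
  m1 <- cohort$truth$mediators$m1
  m2 <- cohort$truth$mediators$m2

  images <- vector("list", n)
  motion <- vector("list", n)
  wm_ts <- vector("list", n)
  csf_ts <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed((config$seed + 7919L * i) %% .Machine$integer.max)
    run_dat <- vector("list", nr)
    run_wm <- vector("list", nr)
    run_csf <- vector("list", nr)
    mot <- matrix(0, t_run * nr, 6)
    for (r in seq_len(nr)) {
      g <- stats::rnorm(t_run)
      nuis <- stats::rnorm(t_run)
      loc <- stats::rnorm(t_run)
      wml <- stats::rnorm(t_run)
      csfl <- stats::rnorm(t_run)
      trend01 <- seq(-0.5, 0.5, length.out = t_run)

      coupling <- rep(.base_coupling$global, v_brain)
      coupling[in_gcor] <- m1[i]
      coupling[in_pat2] <- m2[i]
      # local coupling is variance-preserving: within the LCOR cluster the
      # shared local latent replaces voxel noise (mu^2 + sigma_i^2 held at
      # mu0^2 + sigma^2), so stronger local coupling raises neighborhood
      # correlation without suppressing correlations with the rest of the
      # brain
      noise_sd <- rep(np$ts_noise_sd, v_brain)
      noise_sd[in_lcor] <- sqrt(pmax(
        np$ts_noise_sd^2 + .base_coupling$local^2 - mu_loc[i]^2, 0.01))
      dat <- outer(g, coupling) +
        .base_coupling$nuisance * outer(nuis, rep(1, v_brain)) +
        outer(trend01, stats::rnorm(v_brain, 0, 0.3)) +
        sweep(matrix(stats::rnorm(t_run * v_brain), t_run, v_brain),
              2, noise_sd, "*")
      dat[, in_lcor] <- dat[, in_lcor] + mu_loc[i] * loc

      mk_comp <- function(lat, nv)
        outer(lat, rep(1, nv)) + outer(nuis, rep(1, nv)) +
          outer(trend01, stats::rnorm(nv, 0, 0.3)) +
          matrix(stats::rnorm(t_run * nv, 0, 0.7), t_run, nv)
      wmat <- mk_comp(wml, sum(masks$wm))
      cmat <- mk_comp(csfl, sum(masks$csf))

      # slow motion random walk
      mrun <- cbind(
        apply(matrix(stats::rnorm(t_run * 3, 0, 0.02), t_run, 3), 2, cumsum),
        apply(matrix(stats::rnorm(t_run * 3, 0, 4e-4), t_run, 3), 2, cumsum))
      spikes <- which(stats::runif(t_run) < np$motion_spike_rate)
      spikes <- spikes[spikes > 1]
      if (length(spikes)) {
        mrun[spikes, 1] <- mrun[spikes, 1] +
          stats::runif(length(spikes), 1.2, 3) *
          sample(c(-1, 1), length(spikes), replace = TRUE)
        amp <- 8 * np$ts_noise_sd
        dat[spikes, ] <- dat[spikes, ] + amp
        wmat[spikes, ] <- wmat[spikes, ] + amp
        cmat[spikes, ] <- cmat[spikes, ] + amp
      }
      run_dat[[r]] <- dat
      run_wm[[r]] <- wmat
      run_csf[[r]] <- cmat
      mot[(r - 1) * t_run + seq_len(t_run), ] <- mrun
    }
    images[[i]] <- ts_image(do.call(rbind, run_dat), masks$brain,
                            voxel_size = config$voxel_size, tr = config$tr,
                            run = rep(seq_len(nr), each = t_run),
                            participant_id = i)
    motion[[i]] <- mot
    wm_ts[[i]] <- do.call(rbind, run_wm)
    csf_ts[[i]] <- do.call(rbind, run_csf)
  }
  list(images = images, motion = motion, wm_ts = wm_ts, csf_ts = csf_ts,
       masks = masks)
}

#' Generate a map-level mediation cohort (low-rank planted signal)
#'
#' Directly generates participant x voxel mediator maps (the shape of
#' stacked seed-to-voxel connectivity maps) whose planted indirect effect is
#' concentrated in exactly two orthogonal spatial directions plus isotropic
#' voxel noise, together with exposure, covariates and outcome.  This is the
#' reference condition for studying how the multivariate indirect effect
#' concentrates in the leading principal directions of mediation: the
#' time-series route necessarily smears a planted coupling effect over
#' additional directions because correlation is a nonlinear function of
#' coupling, whereas this generator realizes the exact low-rank condition.
#' Path sizes default to published multivariate-mediation magnitudes
#' (a about 3.6 and 2.3, b about 0.78 and -0.76 for the two directions).
#'
#' @param n participants.
#' @param n_voxels map length.
#' @param a1,b1 exposure->mediator and mediator->outcome paths of the first
#'   planted direction.
#' @param a2,b2 paths of the second planted direction (orthogonal pattern).
#' @param c_prime direct exposure->outcome effect (T-score per doubling).
#' @param exposure_mean,exposure_sd log2 exposure distribution (doublings).
#' @param mediator_noise_sd SD of the latent mediator residuals.
#' @param map_noise_sd SD of the isotropic voxel noise.
#' @param outcome_noise_sd SD of the outcome residual (T-score points).
#' @param with_covariates include age/sex/education with modest outcome
#'   effects.
#' @param seed RNG seed.
#' @return list: `M` (n x n_voxels mediator maps), `x`, `y`, `covariates`
#'   (or `NULL`), `patterns` (n_voxels x 2 orthonormal), `m` (n x 2 latent
#'   mediators), `true_indirect` (a1*b1 + a2*b2), `truth` (per-direction
#'   paths).
#' @export
generate_mediation_maps <- function(n = 300, n_voxels = 296,
                                    a1 = 3.6, b1 = 0.78,
                                    a2 = 2.3, b2 = -0.76,
                                    c_prime = 1.0,
                                    exposure_mean = log2(38),
                                    exposure_sd = 1.3,
                                    mediator_noise_sd = 1,
                                    map_noise_sd = 1,
                                    outcome_noise_sd = 9,
                                    with_covariates = TRUE,
                                    seed = 1L) {
  stopifnot(n >= 10, n_voxels >= 20)
  set.seed(as.integer(seed))
  x <- stats::rnorm(n, exposure_mean, exposure_sd)
  xc <- x - mean(x)
  m1 <- a1 * xc + stats::rnorm(n, 0, mediator_noise_sd)
  m2 <- a2 * xc + stats::rnorm(n, 0, mediator_noise_sd)
  # orthonormal patterns with disjoint support (two "regions")
  half <- floor(n_voxels / 4)
  p1 <- numeric(n_voxels); p1[seq_len(half)] <- 1 / sqrt(half)
  p2 <- numeric(n_voxels); p2[half + seq_len(half)] <- 1 / sqrt(half)
  M <- outer(m1, p1) + outer(m2, p2) +
    matrix(stats::rnorm(n * n_voxels, 0, map_noise_sd), n, n_voxels)
  covariates <- NULL
  cov_term <- 0
  if (with_covariates) {
    covariates <- data.frame(age = stats::rnorm(n, 12.3, 0.7),
                             sex = stats::rbinom(n, 1, 0.587),
                             education = sample.int(4, n, replace = TRUE))
    cov_term <- -1.0 * (covariates$age - 12.3) + 2.0 *
      (covariates$sex - 0.587) - 1.0 * (covariates$education - 2.5)
  }
  y <- 50 + c_prime * xc + b1 * m1 + b2 * m2 + cov_term +
    stats::rnorm(n, 0, outcome_noise_sd)
  list(M = M, x = x, y = y, covariates = covariates,
       patterns = cbind(p1, p2), m = cbind(m1 = m1, m2 = m2),
       true_indirect = a1 * b1 + a2 * b2,
       truth = list(a = c(a1, a2), b = c(b1, b2), c_prime = c_prime))
}
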