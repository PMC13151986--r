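#' Denoising configuration
#'
#' Thresholds and parameters of the scrubbing / nuisance-regression /
#' filtering chain.
#'
#' @param fd_outlier_mm framewise-displacement outlier threshold (mm).
#' @param global_z_outlier global-signal-change outlier threshold (SDs).
#' @param exclude_mean_fd_mm participant exclusion threshold on mean FD (mm).
#' @param exclude_censored_fraction participant exclusion threshold on the
#'   fraction of censored frames.
#' @param n_compcor_per_compartment principal components retained per noise
#'   compartment (white matter, CSF).
#' @param band band-pass limits in Hz, `c(low, high)`.
#' @param smooth_fwhm spatial smoothing kernel FWHM (mm); 0 disables.
#' @param lcor_neighborhood_fwhm Gaussian neighborhood FWHM (mm) used by the
#'   local-correlation metric downstream.
#' @param rotation_radius head radius (mm) converting rotations to
#'   displacement in the FD computation.
#' @return list of class `denoise_config`.
#' @export
denoise_config <- function(fd_outlier_mm = 0.9,
                           global_z_outlier = 5,
                           exclude_mean_fd_mm = 0.4,
                           exclude_censored_fraction = 0.4,
                           n_compcor_per_compartment = 5,
                           band = c(0.008, 0.09),
                           smooth_fwhm = 6,
                           lcor_neighborhood_fwhm = 25,
                           rotation_radius = 50) {
  stopifnot(band[1] > 0, band[2] > band[1],
            fd_outlier_mm > 0, global_z_outlier > 0,
            exclude_mean_fd_mm > 0, exclude_censored_fraction > 0)
  structure(list(fd_outlier_mm = fd_outlier_mm,
                 global_z_outlier = global_z_outlier,
                 exclude_mean_fd_mm = exclude_mean_fd_mm,
                 exclude_censored_fraction = exclude_censored_fraction,
                 n_compcor_per_compartment = n_compcor_per_compartment,
                 band = band, smooth_fwhm = smooth_fwhm,
                 lcor_neighborhood_fwhm = lcor_neighborhood_fwhm,
                 rotation_radius = rotation_radius),
            class = "denoise_config")
}

#' Framewise displacement from rigid-body motion parameters
#'
#' FD_t = sum of absolute frame-to-frame changes of the three translations
#' (mm) plus `rotation_radius` times the sum of absolute changes of the
#' three rotations (radians).  The first frame of each run has FD = 0.
#'
#' @param motion frames x 6 matrix: translations x/y/z in mm then rotations
#'   pitch/roll/yaw in radians.
#' @param rotation_radius head radius in mm.
#' @param run optional run label per frame; FD resets at run boundaries.
#' @return numeric FD series (mm), one value per frame.
#' @export
compute_fd <- function(motion, rotation_radius = 50, run = NULL) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6, nrow(motion) >= 2)
  if (any(!is.finite(motion))) stop("non-finite motion parameters")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius * rowSums(d[, 4:6, drop = FALSE]))
  if (!is.null(run)) fd[c(TRUE, diff(as.integer(run)) != 0)] <- 0
  fd
}

#' Flag outlier frames by motion and global-signal change
#'
#' A frame is an outlier when its framewise displacement exceeds
#' `fd_threshold` or the z-score of its frame-to-frame global-signal change
#' exceeds `z_threshold` in absolute value.  Global-signal changes are
#' z-scored within run; the first frame of a run has no change and is never
#' flagged on that criterion.
#'
#' @param fd framewise displacement series (mm).
#' @param global_signal per-frame mean in-mask signal.
#' @param fd_threshold FD threshold, mm.
#' @param z_threshold global-signal-change threshold, SDs.
#' @param run optional run label per frame.
#' @return logical vector, `TRUE` for outlier frames.
#' @export
flag_outlier_frames <- function(fd, global_signal, fd_threshold = 0.9,
                                z_threshold = 5, run = NULL) {
  stopifnot(length(fd) == length(global_signal))
  if (is.null(run)) run <- rep(1L, length(fd))
  z <- numeric(length(fd))
  for (r in unique(run)) {
    ix <- which(run == r)
    dg <- c(0, diff(global_signal[ix]))
    s <- stats::sd(dg[-1])
    z[ix] <- if (is.na(s) || s == 0) 0 else (dg - mean(dg[-1])) / s
    z[ix[1]] <- 0
  }
  fd > fd_threshold | abs(z) > z_threshold
}

#' Participant-level motion exclusion decisions
#'
#' A participant is dropped when mean FD exceeds `fd_limit` or when more
#' than `censor_limit` of frames are censored.
#'
#' @param mean_fd numeric vector of participant mean FD (mm).
#' @param censored_fraction numeric vector of censored-frame fractions.
#' @param fd_limit mean-FD exclusion threshold (mm).
#' @param censor_limit censored-fraction exclusion threshold.
#' @return data.frame with `keep` (logical) and `reason` (string, `""` when
#'   kept).
#' @export
exclude_participants <- function(mean_fd, censored_fraction,
                                 fd_limit = 0.4, censor_limit = 0.4) {
  stopifnot(length(mean_fd) == length(censored_fraction))
  reason <- character(length(mean_fd))
  bad_fd <- mean_fd > fd_limit
  bad_cen <- censored_fraction > censor_limit
  reason[bad_fd] <- sprintf("mean FD %.3f mm > %.2f mm",
                            mean_fd[bad_fd], fd_limit)
  reason[bad_cen & !bad_fd] <- sprintf("censored fraction %.2f > %.2f",
                                       censored_fraction[bad_cen & !bad_fd],
                                       censor_limit)
  reason[bad_cen & bad_fd] <- paste0(reason[bad_cen & bad_fd],
                                     "; censored fraction above limit")
  data.frame(keep = !(bad_fd | bad_cen), reason = reason,
             mean_fd = mean_fd, censored_fraction = censored_fraction)
}

#' CompCor-style nuisance components from a noise compartment
#'
#' Principal component time courses of the linearly detrended,
#' variance-normalized compartment voxel signals.  Returned components are
#' mutually orthogonal with unit norm.
#'
#' @param compartment_ts frames x voxels matrix of compartment signals.
#' @param n number of components requested.
#' @return frames x k matrix of component series (k <= n; fewer than `n`
#'   with a warning when the compartment is rank-deficient).
#' @export
compcor_components <- function(compartment_ts, n = 5) {
  x <- as.matrix(compartment_ts)
  t_n <- nrow(x)
  if (ncol(x) < n || t_n < n + 1)
    stop("compartment needs >= n voxels and >= n+1 frames")
  x <- detrend_linear(x)
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/")
  sv <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  k <- min(n, rank)
  if (k < n)
    warning("compartment rank ", rank, " below requested ", n,
            " components; returning ", k)
  sv$u[, seq_len(k), drop = FALSE]
}

#' Regress nuisance confounds out of voxel time series
#'
#' Ordinary least squares projection: residuals are orthogonal to every
#' retained confound column.  Collinear confound columns are dropped (with a
#' message) before fitting; frames covered by spike regressors are absorbed
#' exactly.
#'
#' @param y frames x voxels matrix.
#' @param confounds frames x p confound matrix (include a constant column if
#'   an intercept is wanted).
#' @return residual matrix of the same shape as `y`.
#' @export
nuisance_regress <- function(y, confounds) {
  y <- as.matrix(y)
  x <- as.matrix(confounds)
  stopifnot(nrow(y) == nrow(x))
  if (ncol(x) >= nrow(x)) stop("more confounds than frames")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop <- setdiff(seq_len(ncol(x)), qx$pivot[seq_len(qx$rank)])
    message("dropping ", length(drop), " collinear confound column(s)")
    x <- x[, -drop, drop = FALSE]
    qx <- qr(x)
  }
  y - qr.fitted(qx, y)
}

# per-column linear detrend (intercept + slope removed)
detrend_linear <- function(y) {
  t_n <- nrow(y)
  x <- cbind(1, seq_len(t_n))
  y - x %*% qr.solve(x, y)
}

#' Linear detrend and band-pass filter voxel time series
#'
#' Removes the per-voxel linear trend, then applies a frequency-domain mask
#' retaining Fourier components with `band[1] <= f <= band[2]`.  The hard
#' spectral mask is bit-reproducible; its attenuation contract (stop-band
#' < 5 percent, pass-band > 90 percent of input amplitude at the synthetic
#' frame counts used here) is what the tests check.
#'
#' @param y frames x voxels matrix (single run).
#' @param tr repetition time, seconds.
#' @param band band limits in Hz.
#' @return filtered matrix of the same shape.
#' @export
bandpass_detrend <- function(y, tr, band = c(0.008, 0.09)) {
  y <- as.matrix(y)
  t_n <- nrow(y)
  if (t_n < 16) stop("too few frames (", t_n, ") to band-pass filter")
  if (band[2] >= 1 / (2 * tr))
    stop("band high edge must be below the Nyquist frequency")
  y <- detrend_linear(y)
  freq <- seq(0, t_n - 1) / (t_n * tr)
  freq <- pmin(freq, 1 / tr - freq)   # fold to two-sided frequencies
  keep <- as.numeric(freq >= band[1] & freq <= band[2])
  Re(stats::mvfft(stats::mvfft(y) * keep, inverse = TRUE)) / t_n
}

#' Spatial Gaussian smoothing within a mask
#'
#' 3D Gaussian convolution with sigma = fwhm / 2.3548 mm, kernel truncated
#' at 3 sigma and renormalized to unit mass within the mask (so a constant
#' image is unchanged and no signal bleeds in from outside the mask).
#'
#' @param x a 3D array, or a [ts_image()] (each frame smoothed).
#' @param fwhm kernel full width at half maximum, mm; 0 returns the input.
#' @param voxel_size voxel edge length, mm (taken from `x` for `ts_image`).
#' @param mask logical 3D array (taken from `x` for `ts_image`).
#' @return object of the same type as `x`.
#' @export
smooth_spatial <- function(x, fwhm, voxel_size = NULL, mask = NULL) {
  if (inherits(x, "ts_image")) {
    sm <- smooth_frames(x$data, x$mask, fwhm, x$voxel_size)
    x$data <- sm
    return(x)
  }
  stopifnot(length(dim(x)) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(x))
  if (fwhm == 0) return(x)
  if (fwhm < voxel_size / 2) {
    warning("fwhm ", fwhm, " mm below half the voxel size; no smoothing")
    return(x)
  }
  k <- gaussian_kernel_offsets(fwhm, voxel_size)
  num <- array(0, dim = dim(x))
  den <- array(0, dim = dim(x))
  xm <- x
  xm[!mask] <- 0
  mnum <- array(0, dim = dim(x))
  for (o in seq_len(nrow(k$offsets))) {
    sh <- shift_array(xm, k$offsets[o, ])
    shm <- shift_array(mask * 1, k$offsets[o, ])
    num <- num + k$weights[o] * sh
    mnum <- mnum + k$weights[o] * shm
  }
  den <- mnum
  out <- x
  out[mask] <- num[mask] / den[mask]
  out
}

# smooth every frame of a frames x voxels matrix defined over `mask`
smooth_frames <- function(dat, mask, fwhm, voxel_size) {
  if (fwhm == 0) return(dat)
  if (fwhm < voxel_size / 2) {
    warning("fwhm ", fwhm, " mm below half the voxel size; no smoothing")
    return(dat)
  }
  k <- gaussian_kernel_offsets(fwhm, voxel_size)
  d <- dim(mask)
  vol <- array(0, dim = d)
  out <- dat
  # precompute, per kernel offset, the mapping between in-mask voxels
  idx <- which(mask)
  ijk <- arrayInd(idx, d)
  pos <- array(0L, dim = d)
  pos[idx] <- seq_along(idx)
  wsum <- numeric(length(idx))
  pairs <- vector("list", nrow(k$offsets))
  for (o in seq_len(nrow(k$offsets))) {
    tgt <- sweep(ijk, 2, k$offsets[o, ], "+")
    ok <- tgt[, 1] >= 1 & tgt[, 1] <= d[1] &
      tgt[, 2] >= 1 & tgt[, 2] <= d[2] &
      tgt[, 3] >= 1 & tgt[, 3] <= d[3]
    lin <- pos[tgt[ok, , drop = FALSE]]
    src <- which(ok)[lin > 0]
    lin <- lin[lin > 0]
    pairs[[o]] <- cbind(src = src, nb = lin)
    wsum[src] <- wsum[src] + k$weights[o]
  }
  acc <- matrix(0, nrow(dat), ncol(dat))
  for (o in seq_len(nrow(k$offsets))) {
    p <- pairs[[o]]
    if (!nrow(p)) next
    acc[, p[, "src"]] <- acc[, p[, "src"]] +
      k$weights[o] * dat[, p[, "nb"], drop = FALSE]
  }
  sweep(acc, 2, wsum, "/")
}

gaussian_kernel_offsets <- function(fwhm, voxel_size) {
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / voxel_size
  r <- max(1L, ceiling(3 * sigma_vox))
  g <- expand.grid(di = -r:r, dj = -r:r, dk = -r:r)
  dist_mm <- sqrt(rowSums(g^2)) * voxel_size
  keep <- dist_mm <= 3 * sigma_mm + 1e-9
  g <- g[keep, , drop = FALSE]
  w <- exp(-dist_mm[keep]^2 / (2 * sigma_mm^2))
  list(offsets = as.matrix(g), weights = w / sum(w))
}

shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0, dim = d)
  src <- lapply(1:3, function(ax) {
    ix <- seq_len(d[ax]) - off[ax]
    ix[ix >= 1 & ix <= d[ax]]
  })
  dst <- lapply(1:3, function(ax) {
    ix <- seq_len(d[ax])
    ix[ix - off[ax] >= 1 & ix - off[ax] <= d[ax]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Denoise one participant's functional data
#'
#' Applies the chain in fixed order: optional spatial smoothing; per-run
#' nuisance regression (6 motion parameters and their first derivatives,
#' CompCor components from the white-matter and CSF compartments, spike
#' regressors for outlier frames, run constant and linear term); per-run
#' linear detrend and band-pass filter; run concatenation.  Censored frames
#' are recorded in the QC block so correlation stages can drop them.
#'
#' Smoothing is off by default: voxel-level correlation metrics (LCOR,
#' GCOR) are conventionally computed on unsmoothed residuals — the LCOR
#' neighborhood kernel performs the spatial integration — and pre-smoothing
#' would blur a focal effect into its neighbors.  Set `smooth = TRUE` for
#' seed-based workflows that want the configured kernel applied before
#' regression.
#'
#' @param img a [ts_image()].
#' @param motion frames x 6 motion-parameter matrix.
#' @param wm_ts,csf_ts frames x voxels noise-compartment matrices.
#' @param config a [denoise_config()].
#' @param smooth apply `config$smooth_fwhm` spatial smoothing first.
#' @return list: `img` (denoised `ts_image`), `censored` (logical per
#'   frame), `qc` (list with `mean_fd`, `censored_fraction`, `n_outliers`).
#' @export
denoise_participant <- function(img, motion, wm_ts, csf_ts,
                                config = denoise_config(),
                                smooth = FALSE) {
  run <- img$run
  fd <- compute_fd(motion, config$rotation_radius, run = run)
  gs <- rowMeans(img$data)
  censored <- flag_outlier_frames(fd, gs, config$fd_outlier_mm,
                                  config$global_z_outlier, run = run)
  dat <- if (smooth && config$smooth_fwhm > 0)
    smooth_frames(img$data, img$mask, config$smooth_fwhm, img$voxel_size)
  else img$data

  out <- matrix(0, nrow(dat), ncol(dat))
  for (r in unique(run)) {
    ix <- which(run == r)
    mot <- motion[ix, 1:6, drop = FALSE]
    dmot <- rbind(0, diff(mot))
    cc <- cbind(
      compcor_components(wm_ts[ix, , drop = FALSE],
                         config$n_compcor_per_compartment),
      compcor_components(csf_ts[ix, , drop = FALSE],
                         config$n_compcor_per_compartment))
    spikes <- which(censored[ix])
    spike_reg <- matrix(0, length(ix), length(spikes))
    if (length(spikes)) spike_reg[cbind(spikes, seq_along(spikes))] <- 1
    trend01 <- seq(-0.5, 0.5, length.out = length(ix))
    confounds <- cbind(1, trend01, mot, dmot, cc, spike_reg)
    resid <- nuisance_regress(dat[ix, , drop = FALSE], confounds)
    out[ix, ] <- bandpass_detrend(resid, img$tr, config$band)
  }
  img$data <- out
  list(img = img, censored = censored,
       qc = list(mean_fd = mean(fd),
                 censored_fraction = mean(censored),
                 n_outliers = sum(censored)))
}
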