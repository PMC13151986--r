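#' Voxelwise local correlation (LCOR) map
#'
#' For each in-mask voxel v, LCOR(v) is the Gaussian-weighted average of the
#' Pearson correlations between v's time series and the series of its
#' spatial neighbors: weights follow a Gaussian of the stated FWHM on
#' inter-voxel distance in mm, truncated at 3 sigma and renormalized.  The
#' self-correlation is excluded by default (set `include_self = TRUE` for
#' the alternative convention).  Censored frames are removed before
#' correlating.
#'
#' @param img a [ts_image()] (denoised).
#' @param neighborhood_fwhm Gaussian neighborhood FWHM, mm.
#' @param censored optional logical per frame; flagged frames are dropped.
#' @param include_self include the voxel's own (unit) correlation.
#' @param uniform_weights use equal weights over all other voxels instead of
#'   Gaussian weights (the large-neighborhood limit, equal to GCOR).
#' @return a [scalar_map()] with metric `"LCOR"`.  Zero-variance voxels get
#'   `NA` and are counted in the `n_undefined` attribute.
#' @export
lcor_map <- function(img, neighborhood_fwhm = 25, censored = NULL,
                     include_self = FALSE, uniform_weights = FALSE) {
  z <- normalized_series(img, censored)
  v <- ncol(z$x)
  cmat <- crossprod(z$x)                       # voxel x voxel correlations
  if (uniform_weights) {
    w <- matrix(1, v, v)
  } else {
    coords <- voxel_coords(img$mask, img$voxel_size)
    sigma <- neighborhood_fwhm / (2 * sqrt(2 * log(2)))
    d2 <- as.matrix(stats::dist(coords))^2
    w <- exp(-d2 / (2 * sigma^2))
    w[sqrt(d2) > 3 * sigma] <- 0
  }
  if (!include_self) diag(w) <- 0
  num <- rowSums(w * cmat)
  den <- rowSums(w)
  vals <- ifelse(den > 0, num / den, NA_real_)
  vals[z$zero_var] <- NA_real_
  out <- scalar_map(vals, img$mask, img$voxel_size, metric = "LCOR",
                    participant_id = img$participant_id)
  attr(out, "n_undefined") <- sum(z$zero_var)
  out
}

#' Voxelwise global correlation (GCOR) map
#'
#' GCOR(v) is the average Pearson correlation between voxel v's series and
#' every other in-mask voxel (self excluded by default), computed through
#' the normalized-series inner-product identity.
#'
#' @inheritParams lcor_map
#' @return a [scalar_map()] with metric `"GCOR"`.
#' @export
gcor_map <- function(img, censored = NULL, include_self = FALSE) {
  z <- normalized_series(img, censored)
  v <- ncol(z$x)
  g <- rowSums(z$x)                            # sum of normalized series
  tot <- as.numeric(crossprod(z$x, g))         # row sums of the corr matrix
  vals <- if (include_self) tot / v else (tot - 1) / (v - 1)
  vals[z$zero_var] <- NA_real_
  out <- scalar_map(vals, img$mask, img$voxel_size, metric = "GCOR",
                    participant_id = img$participant_id)
  attr(out, "n_undefined") <- sum(z$zero_var)
  out
}

#' Mean time series over a seed cluster
#'
#' @param img a [ts_image()].
#' @param cluster_mask logical 3D array selecting the seed voxels (must be
#'   non-empty and contained in the brain mask).
#' @return numeric series, the unweighted per-frame mean over cluster
#'   voxels.
#' @export
seed_series <- function(img, cluster_mask) {
  if (!any(cluster_mask)) stop("empty seed cluster mask")
  cols <- mask_index(img$mask, cluster_mask)
  rowMeans(img$data[, cols, drop = FALSE])
}

#' Seed-to-voxel connectivity map (Fisher z)
#'
#' Correlates the seed series with every in-mask voxel and applies the
#' Fisher z (atanh) transform.  Correlations of exactly +/-1 are clipped to
#' +/-(1 - 1e-7) before the transform and counted in the `n_clipped`
#' attribute.
#'
#' @param img a [ts_image()].
#' @param seed numeric series (same frame count as `img`).
#' @param censored optional logical per frame; flagged frames are dropped.
#' @param fisher_z return atanh(r) (default) or raw r.
#' @return a [scalar_map()] with metric `"seed-z"` (or `"seed-r"`).
#' @export
seed_to_voxel_map <- function(img, seed, censored = NULL, fisher_z = TRUE) {
  stopifnot(length(seed) == nrow(img$data))
  keep <- if (is.null(censored)) seq_along(seed) else which(!censored)
  r <- as.numeric(stats::cor(seed[keep], img$data[keep, , drop = FALSE]))
  n_clip <- sum(abs(r) >= 1, na.rm = TRUE)
  if (fisher_z) {
    r <- clamp(r, -(1 - 1e-7), 1 - 1e-7)
    r <- atanh(r)
  }
  out <- scalar_map(r, img$mask, img$voxel_size,
                    metric = if (fisher_z) "seed-z" else "seed-r",
                    participant_id = img$participant_id)
  attr(out, "n_clipped") <- n_clip
  out
}

# center and unit-normalize each voxel series after dropping censored frames
normalized_series <- function(img, censored = NULL) {
  dat <- img$data
  if (!is.null(censored)) {
    stopifnot(length(censored) == nrow(dat))
    dat <- dat[!censored, , drop = FALSE]
  }
  if (nrow(dat) < 30)
    stop("fewer than 30 frames remain after censoring")
  x <- sweep(dat, 2, colMeans(dat))
  nrm <- sqrt(colSums(x^2))
  zero_var <- nrm == 0
  nrm[zero_var] <- 1
  list(x = sweep(x, 2, nrm, "/"), zero_var = zero_var)
}
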