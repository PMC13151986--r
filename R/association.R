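#' Stack scalar maps into a participants x voxels matrix
#'
#' @param maps list of [scalar_map()] objects sharing one geometry.
#' @return numeric matrix, one row per participant.
#' @export
stack_maps <- function(maps) {
  dims <- lapply(maps, function(m) m$dims)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("maps do not share a common grid geometry")
  do.call(rbind, lapply(maps, function(m) m$values))
}

# design matrix: intercept + covariates (education as ordered integer by
# default, or indicator-coded)
build_design <- function(covariates, education_coding = c("ordinal",
                                                          "indicator")) {
  education_coding <- match.arg(education_coding)
  stopifnot(all(c("age", "sex", "education") %in% names(covariates)))
  edu <- covariates$education
  edu_cols <- if (education_coding == "ordinal") {
    matrix(as.numeric(edu), ncol = 1, dimnames = list(NULL, "education"))
  } else {
    stats::model.matrix(~ factor(edu, levels = 1:4))[, -1, drop = FALSE]
  }
  cbind(intercept = 1, age = covariates$age, sex = covariates$sex, edu_cols)
}

#' Voxelwise general linear model of connectivity on exposure
#'
#' Fits, for every voxel, an ordinary-least-squares model of the
#' connectivity metric on the log2 exposure with age, sex and maternal
#' education as additional explanatory variables, and returns the exposure
#' coefficient, its standard error, t statistic and two-sided p per voxel.
#'
#' @param y participants x voxels matrix of connectivity values (use
#'   [stack_maps()]), complete cases only.
#' @param exposure numeric log2 exposure vector.
#' @param covariates data.frame with `age`, `sex`, `education` columns.
#' @param education_coding `"ordinal"` (default) or `"indicator"`.
#' @return list of class `glm_result`: `beta`, `se`, `t`, `p` (per voxel),
#'   `df`, `design`, `exposure`.
#' @export
fit_voxelwise_glm <- function(y, exposure, covariates,
                              education_coding = "ordinal") {
  y <- as.matrix(y)
  n <- nrow(y)
  stopifnot(length(exposure) == n, nrow(covariates) == n)
  if (anyNA(y) || anyNA(exposure)) stop("complete cases only")
  z <- build_design(covariates, education_coding)
  x_full <- cbind(z, exposure = exposure)
  qx <- qr(x_full)
  if (qx$rank < ncol(x_full)) {
    bad <- colnames(x_full)[setdiff(seq_len(ncol(x_full)),
                                    qx$pivot[seq_len(qx$rank)])]
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  p_design <- ncol(x_full)
  df <- n - p_design
  if (df <= 0) stop("n must exceed the number of design columns")
  # Frisch-Waugh: residualize exposure and y on the nuisance block
  qz <- qr(z)
  xr <- as.numeric(qr.resid(qz, exposure))
  yr <- qr.resid(qz, y)
  sxx <- sum(xr^2)
  beta <- as.numeric(crossprod(xr, yr)) / sxx
  rss <- colSums(yr^2) - beta^2 * sxx
  rss[rss < 0] <- 0
  se <- sqrt(rss / df / sxx)
  tt <- beta / se
  structure(list(beta = beta, se = se, t = tt,
                 p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
                 df = df, design = x_full, exposure = exposure,
                 nuisance = z),
            class = "glm_result")
}

# 3D connected-component labeling over a logical array
label_components <- function(mask3d, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  d <- dim(mask3d)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(offs != 0)
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
                 "26" = offs[nz >= 1, , drop = FALSE])
  idx <- which(mask3d)
  labels <- array(0L, dim = d)
  cur <- 0L
  for (start in idx) {
    if (labels[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      at <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(at), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
        nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- lin[mask3d[lin] & labels[lin] == 0L]
      labels[new] <- cur
      queue <- c(queue, new)
    }
  }
  labels
}

#' Form candidate clusters from voxelwise statistics
#'
#' Thresholds the voxelwise two-sided p map at the cluster-forming level,
#' splits suprathreshold voxels by the sign of t, and groups each sign into
#' connected components under the configured adjacency.
#'
#' @param glm_res a `glm_result` from [fit_voxelwise_glm()].
#' @param mask logical 3D brain mask matching the map ordering.
#' @param voxel_size voxel edge length, mm.
#' @param p_threshold cluster-forming voxel-level threshold.
#' @param connectivity voxel adjacency: 6, 18 or 26 (default).
#' @return list of clusters, each a list with `voxels` (linear indices into
#'   the 3D grid), `size`, `volume_cm3`, `sign` (+1/-1), `peak` (grid
#'   coordinates of max |t|), `peak_t`.  Empty list if nothing survives.
#' @export
form_clusters <- function(glm_res, mask, voxel_size, p_threshold = 0.001,
                          connectivity = 26) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  tmap <- array(0, dim = dim(mask))
  pmap <- array(1, dim = dim(mask))
  tmap[mask] <- glm_res$t
  pmap[mask] <- glm_res$p
  supra <- mask & pmap < p_threshold
  out <- list()
  for (sgn in c(1, -1)) {
    m <- supra & (sgn * tmap > 0)
    if (!any(m)) next
    lab <- label_components(m, connectivity)
    for (l in seq_len(max(lab))) {
      vox <- which(lab == l)
      pk <- vox[which.max(abs(tmap[vox]))]
      out[[length(out) + 1L]] <- list(
        voxels = vox, size = length(vox),
        volume_cm3 = length(vox) * voxel_size^3 / 1000,
        sign = sgn, peak = as.integer(arrayInd(pk, dim(mask))),
        peak_t = tmap[pk])
    }
  }
  out[order(vapply(out, `[[`, integer(1), "size"), decreasing = TRUE)]
}

#' Permutation cluster-extent inference
#'
#' Null distribution of the maximum cluster extent by Freedman-Lane style
#' residual shuffling: the exposure is residualized on the nuisance
#' covariates, permuted, and the voxelwise GLM re-fit; the largest
#' suprathreshold cluster extent (either sign) is recorded per permutation.
#' Each observed cluster gets p = (1 + #(null max >= observed size)) /
#' (1 + n_perm), then Benjamini-Hochberg adjustment across the candidate
#' clusters of this analysis.
#'
#' @param y participants x voxels connectivity matrix.
#' @param exposure numeric log2 exposure vector.
#' @param covariates data.frame with `age`, `sex`, `education`.
#' @param mask logical 3D brain mask.
#' @param voxel_size voxel edge length, mm.
#' @param p_threshold cluster-forming threshold.
#' @param n_perm number of permutations (>= 99).
#' @param connectivity voxel adjacency.
#' @param seed RNG seed for the permutations.
#' @param education_coding passed to [fit_voxelwise_glm()].
#' @return list: `clusters` (as [form_clusters()], plus `p` and `p_fdr` per
#'   cluster), `null_max_extent`, `glm` (the observed fit).
#' @export
cluster_extent_inference <- function(y, exposure, covariates, mask,
                                     voxel_size, p_threshold = 0.001,
                                     n_perm = 1000, connectivity = 26,
                                     seed = 1L,
                                     education_coding = "ordinal") {
  if (n_perm < 99) stop("n_perm must be >= 99")
  glm_obs <- fit_voxelwise_glm(y, exposure, covariates, education_coding)
  clusters <- form_clusters(glm_obs, mask, voxel_size, p_threshold,
                            connectivity)
  if (!length(clusters))
    return(list(clusters = list(), null_max_extent = numeric(0),
                glm = glm_obs))

  n <- nrow(y)
  z <- glm_obs$nuisance
  qz <- qr(z)
  yr <- qr.resid(qz, y)
  xr <- as.numeric(qr.resid(qz, exposure))
  df <- glm_obs$df
  tcrit <- stats::qt(1 - p_threshold / 2, df)
  yss <- colSums(yr^2)

  set.seed(seed)
  null_max <- integer(n_perm)
  tmap <- array(0, dim = dim(mask))
  for (b in seq_len(n_perm)) {
    xp <- xr[sample.int(n)]
    xp <- as.numeric(qr.resid(qz, xp))   # re-orthogonalize to the nuisance
    sxx <- sum(xp^2)
    beta <- as.numeric(crossprod(xp, yr)) / sxx
    rss <- pmax(yss - beta^2 * sxx, 0)
    tt <- beta / sqrt(rss / df / sxx)
    mx <- 0L
    if (any(abs(tt) > tcrit, na.rm = TRUE)) {
      tmap[] <- 0
      tmap[mask] <- tt
      for (sgn in c(1, -1)) {
        m <- sgn * tmap > tcrit
        if (any(m)) {
          lab <- label_components(m, connectivity)
          mx <- max(mx, tabulate(lab[lab > 0L]))
        }
      }
    }
    null_max[b] <- mx
  }
  sizes <- vapply(clusters, `[[`, integer(1), "size")
  p <- vapply(sizes, function(s) (1 + sum(null_max >= s)) / (1 + n_perm),
              numeric(1))
  p_fdr <- stats::p.adjust(p, method = "BH")
  for (i in seq_along(clusters)) {
    clusters[[i]]$p <- p[i]
    clusters[[i]]$p_fdr <- p_fdr[i]
  }
  list(clusters = clusters, null_max_extent = null_max, glm = glm_obs)
}

#' Cluster effect summary: percent change per doubling
#'
#' Averages the connectivity metric over the cluster per participant,
#' regresses that mean on the log2 exposure and covariates, and expresses
#' the exposure coefficient as a percent change per doubling relative to the
#' adjusted cluster mean (the model-implied mean at average exposure and
#' covariates, which under OLS equals the sample mean of the cluster means).
#' When that denominator is degenerate (near zero, as can happen for GCOR),
#' the absolute change per doubling is reported instead and flagged.
#'
#' @param y participants x voxels connectivity matrix.
#' @param cluster one cluster from [form_clusters()].
#' @param mask logical 3D brain mask (defines the column order of `y`).
#' @param exposure numeric log2 exposure vector.
#' @param covariates data.frame with `age`, `sex`, `education`.
#' @param conf_level confidence level.
#' @param education_coding passed to the design builder.
#' @return list: `beta` (metric units per doubling), `ci` (length 2),
#'   `percent_per_doubling`, `percent_ci`, `adjusted_mean`, `absolute_scale`
#'   (`TRUE` when the percent scale was degenerate), `cluster_means`.
#' @export
summarize_cluster_effect <- function(y, cluster, mask, exposure, covariates,
                                     conf_level = 0.95,
                                     education_coding = "ordinal") {
  cols <- match(cluster$voxels, which(mask))
  if (anyNA(cols)) stop("cluster voxels outside the analysis mask")
  cm <- rowMeans(y[, cols, drop = FALSE])
  z <- build_design(covariates, education_coding)
  fit <- stats::lm(cm ~ 0 + z + exposure)
  co <- stats::summary.lm(fit)$coefficients
  beta <- co["exposure", "Estimate"]
  half <- stats::qt(1 - (1 - conf_level) / 2, fit$df.residual) *
    co["exposure", "Std. Error"]
  ci <- beta + c(-1, 1) * half
  adj_mean <- mean(cm)
  degenerate <- abs(adj_mean) < 100 * .Machine$double.eps * max(abs(cm), 1)
  list(beta = beta, ci = ci,
       percent_per_doubling = if (degenerate) NA_real_ else
         100 * beta / adj_mean,
       percent_ci = if (degenerate) c(NA_real_, NA_real_) else
         sort(100 * ci / adj_mean),
       adjusted_mean = adj_mean, absolute_scale = degenerate,
       cluster_means = cm)
}
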