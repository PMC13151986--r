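# Independent oracles used across the suite.  These are deliberately slow,
# literal implementations (double loops, exhaustive search) kept separate
# from the package's computational paths.

# double-loop LCOR: Gaussian-weighted average correlation with neighbors
brute_lcor <- function(dat, mask, voxel_size, fwhm, include_self = FALSE) {
  coords <- pbdefc::voxel_coords(mask, voxel_size)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  v <- ncol(dat)
  cm <- stats::cor(dat)
  out <- numeric(v)
  for (i in seq_len(v)) {
    num <- 0; den <- 0
    for (j in seq_len(v)) {
      if (!include_self && j == i) next
      dist <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (dist > 3 * sigma) next
      w <- exp(-dist^2 / (2 * sigma^2))
      num <- num + w * cm[i, j]
      den <- den + w
    }
    out[i] <- if (den > 0) num / den else NA_real_
  }
  out
}

# double-loop GCOR: mean correlation with every other voxel
brute_gcor <- function(dat, include_self = FALSE) {
  cm <- stats::cor(dat)
  v <- ncol(dat)
  out <- numeric(v)
  for (i in seq_len(v)) {
    s <- 0; k <- 0
    for (j in seq_len(v)) {
      if (!include_self && j == i) next
      s <- s + cm[i, j]; k <- k + 1
    }
    out[i] <- s / k
  }
  out
}

# per-voxel OLS via lm(), returning exposure coefficient stats
brute_voxel_glm <- function(y, exposure, covariates) {
  res <- t(apply(y, 2, function(col) {
    fit <- stats::lm(col ~ exposure + age + sex + education,
                     data = cbind(covariates, exposure = exposure))
    s <- summary(fit)$coefficients["exposure", ]
    c(beta = s[["Estimate"]], se = s[["Std. Error"]],
      t = s[["t value"]], p = s[["Pr(>|t|)"]])
  }))
  as.data.frame(res)
}

# Benjamini-Hochberg step-up, written out literally
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive search for the first PDM on the unit circle (k = 2),
# paths fit exactly as in the univariate mediation models
grid_pdm_k2 <- function(scores, x, y, covariates = NULL,
                        step_deg = 0.5) {
  thetas <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  best <- list(ab = 0, w = c(1, 0))
  for (th in thetas) {
    w <- c(cos(th), sin(th))
    m <- as.numeric(scores %*% w)
    dat <- data.frame(x = x, m = m, y = y)
    if (!is.null(covariates)) dat <- cbind(dat, covariates)
    fa <- if (is.null(covariates)) stats::lm(m ~ x, dat) else
      stats::lm(m ~ x + age + sex + education, dat)
    fb <- if (is.null(covariates)) stats::lm(y ~ x + m, dat) else
      stats::lm(y ~ x + m + age + sex + education, dat)
    ab <- stats::coef(fa)[["x"]] * stats::coef(fb)[["m"]]
    if (abs(ab) > abs(best$ab)) best <- list(ab = ab, w = w)
  }
  best
}

# a tiny deterministic ts_image on a small full-grid mask
tiny_ts_image <- function(dat, dims, voxel_size = 4, tr = 2) {
  mask <- array(TRUE, dim = dims)
  pbdefc::ts_image(dat, mask, voxel_size = voxel_size, tr = tr)
}

angle_deg <- function(u, v) {
  cs <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, cs)) * 180 / pi
}
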