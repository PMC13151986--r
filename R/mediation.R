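#' Univariate mediation with bootstrap inference
#'
#' Linear-model mediation: path a from `m ~ x (+ covariates)`, paths b and
#' c' from `y ~ x + m (+ covariates)`, total effect c from
#' `y ~ x (+ covariates)`.  The indirect effect is ab = a * b, equal to
#' c - c' when all paths are fit by least squares on the same sample with
#' the same covariates.  Its confidence interval and two-sided p come from
#' a nonparametric percentile bootstrap over participants (add-one
#' smoothed, doubled tail probability).
#'
#' @param x exposure (e.g. log2 concentration).
#' @param m scalar mediator.
#' @param y outcome.
#' @param covariates optional data.frame with `age`, `sex`, `education`
#'   (adjusted for in every path; `NULL` for unadjusted paths).
#' @param n_boot bootstrap resamples.
#' @param conf_level confidence level for the percentile interval.
#' @param interval_months optional imaging-to-assessment interval per
#'   participant; rows with interval > `max_interval_months` are excluded
#'   before fitting.
#' @param max_interval_months exclusion threshold, months.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `mediation_result`: `a`, `b`, `c`, `c_prime`,
#'   `ab`, `ab_ci`, `ab_p`, `n`, `n_boot`, `boot_ab`.
#' @export
mediate_univariate <- function(x, m, y, covariates = NULL, n_boot = 5000,
                               conf_level = 0.95, interval_months = NULL,
                               max_interval_months = 3, seed = 1L) {
  keep <- stats::complete.cases(x, m, y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  if (!is.null(interval_months))
    keep <- keep & !is.na(interval_months) &
      interval_months <= max_interval_months
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  z <- if (is.null(covariates)) matrix(1, length(x), 1) else
    build_design(covariates[keep, , drop = FALSE])
  n <- length(x)
  if (n <= ncol(z) + 3) stop("too few complete cases for the path models")
  if (stats::sd(x) == 0 || stats::sd(m) == 0)
    stop("zero variance in exposure or mediator")

  paths <- function(ix) {
    fa <- stats::lm.fit(cbind(z[ix, , drop = FALSE], x = x[ix]), m[ix])
    fb <- stats::lm.fit(cbind(z[ix, , drop = FALSE], x = x[ix], m = m[ix]),
                        y[ix])
    fc <- stats::lm.fit(cbind(z[ix, , drop = FALSE], x = x[ix]), y[ix])
    c(a = unname(fa$coefficients["x"]),
      b = unname(fb$coefficients["m"]),
      c_prime = unname(fb$coefficients["x"]),
      c = unname(fc$coefficients["x"]))
  }
  obs <- paths(seq_len(n))
  set.seed(seed)
  boot_ab <- vapply(seq_len(n_boot), function(i) {
    ix <- sample.int(n, replace = TRUE)
    p <- tryCatch(paths(ix), error = function(e) c(a = NA_real_, b = NA_real_,
                                                   c_prime = NA, c = NA))
    p[["a"]] * p[["b"]]
  }, numeric(1))
  boot_ab <- boot_ab[!is.na(boot_ab)]
  alpha <- 1 - conf_level
  ci <- as.numeric(stats::quantile(boot_ab, c(alpha / 2, 1 - alpha / 2)))
  nb <- length(boot_ab)
  p <- 2 * min((1 + sum(boot_ab <= 0)) / (1 + nb),
               (1 + sum(boot_ab >= 0)) / (1 + nb))
  structure(list(a = obs[["a"]], b = obs[["b"]], c = obs[["c"]],
                 c_prime = obs[["c_prime"]],
                 ab = obs[["a"]] * obs[["b"]],
                 ab_ci = ci, ab_p = min(p, 1), n = n, n_boot = nb,
                 boot_ab = boot_ab),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation> n=%d  a=%.4f  b=%.4f  c=%.4f  c'=%.4f\n  ab=%.4f  95%% CI [%.4f, %.4f]  p=%.4g  (%d bootstraps)\n",
    x$n, x$a, x$b, x$c, x$c_prime, x$ab, x$ab_ci[1], x$ab_ci[2], x$ab_p,
    x$n_boot))
  invisible(x)
}

#' SVD reduction of a high-dimensional mediator matrix
#'
#' Column-centers the participants x voxels mediator matrix and keeps the
#' smallest number of singular directions whose cumulative squared singular
#' values reach the variance threshold.
#'
#' @param m participants x voxels matrix (e.g. stacked seed-to-voxel maps).
#' @param variance_threshold fraction of variance to retain (default 0.90).
#' @return list of class `reduced_mediator`: `basis` (voxels x k,
#'   orthonormal columns), `d` (all singular values), `scores`
#'   (participants x k), `k`, `variance_threshold`, `center` (column
#'   means), `explained` (per-component variance fractions).
#' @export
reduce_svd <- function(m, variance_threshold = 0.90) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need at least 3 participants")
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  if (all(mc == 0)) stop("mediator matrix has no variance")
  sv <- svd(mc)
  share <- sv$d^2 / sum(sv$d^2)
  k <- which(cumsum(share) >= variance_threshold - 1e-12)[1]
  structure(list(basis = sv$v[, seq_len(k), drop = FALSE],
                 d = sv$d,
                 scores = sv$u[, seq_len(k), drop = FALSE] %*%
                   diag(sv$d[seq_len(k)], k, k),
                 k = k, variance_threshold = variance_threshold,
                 center = ctr, explained = share),
            class = "reduced_mediator")
}

# Path ingredients for the PDM objective in the reduced space.
# a(w) = alpha'w ; b(w) = beta'w / (w'Gw) ; ab(w) scale-invariant.
pdm_prepare <- function(scores, x, y, z) {
  w0 <- z                              # nuisance block (incl. intercept)
  q0 <- qr(w0)
  xr <- as.numeric(qr.resid(q0, x))
  alpha <- as.numeric(crossprod(scores, xr)) / sum(xr^2)
  w1 <- cbind(z, x = x)
  q1 <- qr(w1)
  yr <- as.numeric(qr.resid(q1, y))
  sr <- qr.resid(q1, scores)
  list(alpha = alpha, beta = as.numeric(crossprod(sr, yr)),
       G = crossprod(sr), q1 = q1)
}

# Exact maximizer of |ab(w)| over unit w in the column span of B.
# In the whitened metric the objective is the Rayleigh quotient of the
# rank-2 symmetric matrix (ab' + ba')/2, whose extreme eigenpairs are
# closed-form; the larger |eigenvalue| is the optimum.
solve_pdm_direction <- function(alpha, beta, G, B, tol = 1e-12) {
  aB <- as.numeric(crossprod(B, alpha))
  bB <- as.numeric(crossprod(B, beta))
  GB <- crossprod(B, G %*% B)
  eg <- eigen((GB + t(GB)) / 2, symmetric = TRUE)
  # directions with zero residual mediator variance make the b path
  # ill-posed (zero denominator); restrict the search to the span where
  # the denominator is positive
  pos <- eg$values > max(eg$values, 0) * 1e-10
  if (!any(pos))
    return(list(w = B[, 1], a = 0, b = 0, ab = 0, degenerate = TRUE))
  Qp <- eg$vectors[, pos, drop = FALSE]
  s <- 1 / sqrt(eg$values[pos])
  at <- s * as.numeric(crossprod(Qp, aB))
  bt <- s * as.numeric(crossprod(Qp, bB))
  na <- sqrt(sum(at^2)); nb <- sqrt(sum(bt^2))
  if (na < tol || nb < tol) {
    w <- B[, 1] / sqrt(sum(B[, 1]^2))
    return(list(w = w, a = sum(alpha * w),
                b = 0, ab = 0, degenerate = TRUE))
  }
  cc <- sum(at * bt)
  lam_pos <- (cc + na * nb) / 2
  lam_neg <- (cc - na * nb) / 2
  sgn <- if (abs(lam_pos) >= abs(lam_neg)) 1 else -1
  lam <- if (sgn > 0) lam_pos else lam_neg
  v <- at / na + sgn * bt / nb
  u <- Qp %*% (s * v)                 # undo the whitening
  w <- as.numeric(B %*% u)
  w <- w / sqrt(sum(w^2))
  if (sum(alpha * w) < 0) w <- -w     # sign convention: a_k >= 0
  a <- sum(alpha * w)
  list(w = w, a = a, b = if (a == 0) 0 else lam / a, ab = lam,
       degenerate = FALSE)
}

#' Estimate principal directions of mediation (PDMs)
#'
#' Sequentially finds unit vectors in the reduced mediator space that
#' maximize the absolute indirect effect |a(w) * b(w)| of the projected
#' mediator `scores %*% w`, each direction orthogonal to all previous ones,
#' with paths fit as in [mediate_univariate()] (covariate-adjusted least
#' squares).  With least-squares paths the objective is a ratio of
#' quadratic forms whose constrained maximizer has a closed form, so the
#' solution is exact and deterministic.
#'
#' @param reduced a `reduced_mediator` from [reduce_svd()], or a plain
#'   participants x k score matrix.
#' @param x exposure vector.
#' @param y outcome vector.
#' @param covariates optional data.frame with `age`, `sex`, `education`.
#' @param n_pdms number of directions (truncated to the reduced dimension).
#' @return list of class `pdm_set`: `directions` (k x n_pdms, orthonormal
#'   columns), `a`, `b`, `ab` (per direction, |ab| non-increasing),
#'   `degenerate` (logical per direction), `reduced`.
#' @export
estimate_pdms <- function(reduced, x, y, covariates = NULL, n_pdms = 15) {
  scores <- if (inherits(reduced, "reduced_mediator")) reduced$scores else
    as.matrix(reduced)
  n <- nrow(scores)
  stopifnot(length(x) == n, length(y) == n)
  z <- if (is.null(covariates)) matrix(1, n, 1) else build_design(covariates)
  k <- ncol(scores)
  n_pdms <- min(n_pdms, k)
  prep <- pdm_prepare(scores, x, y, z)
  dirs <- matrix(0, k, n_pdms)
  a <- b <- ab <- numeric(n_pdms)
  degen <- logical(n_pdms)
  for (j in seq_len(n_pdms)) {
    B <- if (j == 1) diag(k) else {
      qr.Q(qr(dirs[, seq_len(j - 1), drop = FALSE]),
           complete = TRUE)[, j:k, drop = FALSE]
    }
    sol <- solve_pdm_direction(prep$alpha, prep$beta, prep$G, B)
    dirs[, j] <- sol$w
    a[j] <- sol$a; b[j] <- sol$b; ab[j] <- sol$ab
    degen[j] <- sol$degenerate
  }
  structure(list(directions = dirs, a = a, b = b, ab = ab,
                 degenerate = degen,
                 reduced = if (inherits(reduced, "reduced_mediator"))
                   reduced else NULL),
            class = "pdm_set")
}

#' Permutation p-value of the multivariate mediation model
#'
#' Test statistic: the sum of absolute indirect effects over all PDMs.
#' Under the null, rows of the reduced mediator matrix are shuffled across
#' participants (exposure, outcome and covariates fixed) and the full PDM
#' stack re-estimated per permutation.  Add-one convention:
#' p = (1 + #(T_perm >= T_obs)) / (1 + n_perm).
#'
#' @inheritParams estimate_pdms
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list: `p`, `T_obs`, `T_perm`, `pdms` (the observed `pdm_set`).
#' @export
pdm_model_pvalue <- function(reduced, x, y, covariates = NULL, n_pdms = 15,
                             n_perm = 1000, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  scores <- if (inherits(reduced, "reduced_mediator")) reduced$scores else
    as.matrix(reduced)
  n <- nrow(scores)
  obs <- estimate_pdms(scores, x, y, covariates, n_pdms)
  t_obs <- sum(abs(obs$ab))
  set.seed(seed)
  t_perm <- vapply(seq_len(n_perm), function(i) {
    sp <- scores[sample.int(n), , drop = FALSE]
    sum(abs(estimate_pdms(sp, x, y, covariates, n_pdms)$ab))
  }, numeric(1))
  list(p = (1 + sum(t_perm >= t_obs)) / (1 + n_perm),
       T_obs = t_obs, T_perm = t_perm, pdms = obs)
}

#' Back-project a reduced-space direction to voxel space
#'
#' @param w_reduced length-k weight vector (or k x m matrix of directions).
#' @param basis voxels x k orthonormal basis from [reduce_svd()].
#' @return voxel-space weight vector (or matrix); norms are preserved when
#'   the basis is orthonormal.
#' @export
backproject_weights <- function(w_reduced, basis) {
  w_reduced <- as.matrix(w_reduced)
  if (nrow(w_reduced) != ncol(basis))
    stop("dimension mismatch: direction has ", nrow(w_reduced),
         " entries but the basis has ", ncol(basis), " columns")
  basis %*% w_reduced
}

#' Bootstrap significance of PDM voxel weights
#'
#' Re-estimates the PDM stack on participant bootstrap resamples, matches
#' each resampled direction to an original one by maximal absolute inner
#' product (greedy in original index order; ties broken by that order) with
#' sign alignment, back-projects to voxel space, and flags a voxel weight as
#' significant when its percentile interval excludes zero.  Voxels with a
#' degenerate (zero-variance) bootstrap distribution are never significant
#' and are flagged.
#'
#' @param reduced a `reduced_mediator` from [reduce_svd()].
#' @param pdms the observed `pdm_set` for the same data.
#' @param x,y,covariates as in [estimate_pdms()].
#' @param n_boot bootstrap resamples.
#' @param conf_level confidence level of the percentile interval.
#' @param seed RNG seed.
#' @return list: `significant` (voxels x n_pdms logical), `lower`, `upper`
#'   (percentile bounds), `weights` (observed voxel weights),
#'   `degenerate` (voxels x n_pdms logical).
#' @export
bootstrap_pdm_weights <- function(reduced, pdms, x, y, covariates = NULL,
                                  n_boot = 5000, conf_level = 0.95,
                                  seed = 1L) {
  stopifnot(inherits(reduced, "reduced_mediator"))
  scores <- reduced$scores
  n <- nrow(scores)
  n_pdms <- ncol(pdms$directions)
  w_obs <- backproject_weights(pdms$directions, reduced$basis)
  nv <- nrow(w_obs)
  boot <- array(NA_real_, dim = c(n_boot, nv, n_pdms))
  set.seed(seed)
  for (bi in seq_len(n_boot)) {
    ix <- sample.int(n, replace = TRUE)
    fit <- tryCatch(
      estimate_pdms(scores[ix, , drop = FALSE], x[ix], y[ix],
                    if (is.null(covariates)) NULL else
                      covariates[ix, , drop = FALSE], n_pdms),
      error = function(e) NULL)
    if (is.null(fit)) next
    # match resampled directions to the originals
    taken <- logical(n_pdms)
    for (j in seq_len(n_pdms)) {
      sims <- abs(crossprod(fit$directions, pdms$directions[, j]))
      sims[taken] <- -Inf
      pick <- which.max(sims)
      taken[pick] <- TRUE
      wj <- fit$directions[, pick]
      if (sum(wj * pdms$directions[, j]) < 0) wj <- -wj
      boot[bi, , j] <- backproject_weights(wj, reduced$basis)
    }
  }
  alpha <- 1 - conf_level
  lower <- apply(boot, c(2, 3), stats::quantile, probs = alpha / 2,
                 na.rm = TRUE)
  upper <- apply(boot, c(2, 3), stats::quantile, probs = 1 - alpha / 2,
                 na.rm = TRUE)
  degenerate <- upper - lower == 0
  significant <- (lower > 0 | upper < 0) & !degenerate
  list(significant = significant, lower = lower, upper = upper,
       weights = w_obs, degenerate = degenerate)
}

#' Percent of the multivariate indirect effect per direction
#'
#' share_k = 100 * |ab_k| / sum_j |ab_j|.
#'
#' @param pdms a `pdm_set`.
#' @return numeric vector of shares summing to 100 (all-`NA` with a warning
#'   when every indirect effect is zero).
#' @export
percent_indirect <- function(pdms) {
  ab <- abs(pdms$ab)
  if (sum(ab) == 0) {
    warning("all indirect effects are zero; shares undefined")
    return(rep(NA_real_, length(ab)))
  }
  100 * ab / sum(ab)
}
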