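test_that("a noiseless mediation chain returns the constructed paths", {
  set.seed(3)
  n <- 50
  x <- rnorm(n)
  d <- resid(lm(rnorm(n) ~ x))          # exactly orthogonal to x
  m <- 2 * x + d
  y <- 0.25 * m + 0.1 * x
  res <- mediate_univariate(x, m, y, n_boot = 50, seed = 1)
  expect_equal(res$a, 2, tolerance = 1e-10)
  expect_equal(res$b, 0.25, tolerance = 1e-10)
  expect_equal(res$c_prime, 0.1, tolerance = 1e-10)
  expect_equal(res$ab, 0.5, tolerance = 1e-10)
  expect_equal(res$c - res$c_prime, 0.5, tolerance = 1e-10)
})

test_that("mediation paths match independent lm fits, with covariates", {
  set.seed(9)
  n <- 120
  cov <- data.frame(age = rnorm(n, 12, 1), sex = rbinom(n, 1, 0.5),
                    education = sample(1:4, n, TRUE))
  x <- rnorm(n)
  m <- 0.8 * x + 0.3 * cov$age + rnorm(n)
  y <- 0.5 * m - 0.4 * x + 0.2 * cov$sex + rnorm(n)
  res <- mediate_univariate(x, m, y, cov, n_boot = 50, seed = 2)
  d <- cbind(data.frame(x = x, m = m, y = y), cov)
  fa <- lm(m ~ x + age + sex + education, d)
  fb <- lm(y ~ x + m + age + sex + education, d)
  fc <- lm(y ~ x + age + sex + education, d)
  expect_equal(res$a, unname(coef(fa)["x"]), tolerance = 1e-10)
  expect_equal(res$b, unname(coef(fb)["m"]), tolerance = 1e-10)
  expect_equal(res$c_prime, unname(coef(fb)["x"]), tolerance = 1e-10)
  expect_equal(res$c, unname(coef(fc)["x"]), tolerance = 1e-10)
  expect_equal(res$ab, res$c - res$c_prime, tolerance = 1e-10)
  expect_error(mediate_univariate(x, rep(1, n), y), "zero variance")
})

test_that("imaging-to-assessment intervals over 3 months are excluded", {
  set.seed(11)
  n <- 60
  x <- rnorm(n); m <- x + rnorm(n); y <- m + rnorm(n)
  iv <- rep(1, n); iv[1:10] <- 5
  res <- mediate_univariate(x, m, y, n_boot = 50, interval_months = iv)
  expect_equal(res$n, 50)
  ref <- mediate_univariate(x[-(1:10)], m[-(1:10)], y[-(1:10)], n_boot = 50)
  expect_equal(res$ab, ref$ab, tolerance = 1e-12)
})

test_that("bootstrap CI for a null b path usually contains zero", {
  set.seed(21)
  hits <- vapply(1:20, function(i) {
    n <- 100
    x <- rnorm(n)
    m <- 0.9 * x + rnorm(n)
    y <- 0.5 * x + rnorm(n)            # b = 0 by construction
    ci <- mediate_univariate(x, m, y, n_boot = 199, seed = i)$ab_ci
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(sum(hits), 17)
})

test_that("SVD reduction follows the cumulative-variance rule", {
  set.seed(5)
  shares <- c(0.6, 0.25, 0.1, 0.05)
  # left factors orthogonal to the constant vector, so the matrix is
  # already column-centred and the singular values are exactly as planted
  u <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 4), 40, 4))))[, 2:5]
  v <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))
  m <- u %*% diag(sqrt(shares)) %*% t(v)
  red <- reduce_svd(m, 0.90)
  expect_equal(red$k, 3)
  expect_equal(sum(red$explained[1:2]), 0.85, tolerance = 1e-6)
  # scores reproduce the projection of the centred matrix onto the basis
  expect_lt(max(abs(red$scores - m %*% red$basis)), 1e-8)

  # rank-2 matrix at threshold 0.90: k = 2 and reconstruction exact
  m2 <- outer(rnorm(25), rnorm(12)) + outer(rnorm(25), rnorm(12))
  m2c <- sweep(m2, 2, colMeans(m2))
  red2 <- reduce_svd(m2, 0.90)
  expect_equal(red2$k, 2)
  expect_lt(max(abs(red2$scores %*% t(red2$basis) - m2c)), 1e-8)
  expect_error(reduce_svd(matrix(1, 10, 5)), "variance")
})

test_that("first PDM matches a 0.5-degree exhaustive search on the circle", {
  set.seed(14)
  n <- 100
  x <- rnorm(n)
  m1 <- 1.5 * x + rnorm(n)             # mediating score direction
  m2 <- rnorm(n)                       # inert direction
  y <- 0.8 * m1 + 0.2 * x + rnorm(n)
  scores <- cbind(m1, m2)
  pdms <- estimate_pdms(scores, x, y, n_pdms = 2)
  oracle <- grid_pdm_k2(scores, x, y)
  expect_lt(angle_deg(pdms$directions[, 1], oracle$w), 2)
  expect_lt(abs(abs(pdms$ab[1]) - abs(oracle$ab)), 1e-3)
  expect_gte(pdms$a[1], 0)             # sign convention
})

test_that("PDM stacks are orthonormal with non-increasing |ab|", {
  set.seed(26)
  n <- 90
  k <- 6
  x <- rnorm(n)
  scores <- matrix(rnorm(n * k), n, k)
  scores[, 1] <- scores[, 1] + 1.2 * x
  scores[, 3] <- scores[, 3] + 0.6 * x
  y <- 0.7 * scores[, 1] - 0.5 * scores[, 3] + 0.3 * x + rnorm(n)
  cov <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                    education = sample(1:4, n, TRUE))
  pdms <- estimate_pdms(scores, x, y, cov, n_pdms = k)
  w <- pdms$directions
  expect_lt(max(abs(crossprod(w) - diag(k))), 1e-6)
  expect_true(all(diff(abs(pdms$ab)) <= 1e-6))
  expect_true(all(pdms$a >= 0))
})

test_that("PDM permutation p-value: construction bound and determinism", {
  set.seed(31)
  n <- 60
  x <- rnorm(n)
  scores <- cbind(2 * x + 0.1 * rnorm(n), matrix(rnorm(n * 2), n, 2))
  y <- 3 * scores[, 1] + 0.1 * rnorm(n)
  pv <- pdm_model_pvalue(scores, x, y, n_pdms = 3, n_perm = 199, seed = 5)
  expect_equal(pv$p, 1 / 200)          # T_obs beats every permutation
  pv2 <- pdm_model_pvalue(scores, x, y, n_pdms = 3, n_perm = 199, seed = 5)
  expect_identical(pv$p, pv2$p)
  expect_identical(pv$T_perm, pv2$T_perm)
})

test_that("percent indirect shares behave as ratios of |ab|", {
  fake <- structure(list(ab = c(3, -1, 1)), class = "pdm_set")
  expect_equal(percent_indirect(fake), c(60, 20, 20))
  expect_equal(percent_indirect(structure(list(ab = 2), class = "pdm_set")),
               100)
  set.seed(2)
  fake2 <- structure(list(ab = rnorm(9)), class = "pdm_set")
  expect_equal(sum(percent_indirect(fake2)), 100, tolerance = 1e-9)
  expect_warning(
    out <- percent_indirect(structure(list(ab = c(0, 0)),
                                      class = "pdm_set")), "zero")
  expect_true(all(is.na(out)))
})

test_that("back-projection preserves norms and round-trips", {
  set.seed(44)
  basis <- qr.Q(qr(matrix(rnorm(50 * 6), 50, 6)))
  w <- rnorm(6)
  expect_equal(backproject_weights(w, diag(6)), matrix(w, 6, 1))
  vw <- backproject_weights(w, basis)
  expect_equal(sqrt(sum(vw^2)), sqrt(sum(w^2)), tolerance = 1e-10)
  # an in-span voxel map projects and back-projects to itself
  map <- as.numeric(basis %*% rnorm(6))
  expect_equal(as.numeric(backproject_weights(crossprod(basis, map), basis)),
               map, tolerance = 1e-8)
  expect_error(backproject_weights(rnorm(4), basis), "dimension mismatch")
})

test_that("bootstrap voxel-weight significance recovers a planted pattern", {
  set.seed(55)
  n <- 80; v <- 40
  x <- rnorm(n)
  pattern <- c(rep(1, 10), rep(0, v - 10)) / sqrt(10)
  m_mat <- outer(2 * x + 0.3 * rnorm(n), pattern) +
    matrix(rnorm(n * v, 0, 0.3), n, v)
  y <- 1.5 * (m_mat %*% pattern) + 0.2 * x + rnorm(n, 0, 0.5)
  red <- reduce_svd(m_mat, 0.90)
  pdms <- estimate_pdms(red, x, y, n_pdms = 2)
  bw <- bootstrap_pdm_weights(red, pdms, x, y, n_boot = 150, seed = 9)
  expect_true(all(bw$significant[1:10, 1]))
  # pure-noise voxels flagged well below half the time
  expect_lt(mean(bw$significant[11:v, 1]), 0.5)
  expect_false(any(bw$degenerate[1:10, 1]))
})

test_that("zero-variance bootstrap weight distributions are flagged, not significant", {
  set.seed(66)
  n <- 60
  scores <- cbind(rnorm(n), rnorm(n))
  x <- rnorm(n); y <- rnorm(n)
  basis <- rbind(diag(2), 0)           # third voxel has no loading at all
  red <- structure(list(basis = basis, scores = scores, k = 2,
                        d = c(1, 1), center = rep(0, 3),
                        variance_threshold = 0.9,
                        explained = c(0.5, 0.5)),
                   class = "reduced_mediator")
  pdms <- estimate_pdms(red, x, y, n_pdms = 2)
  bw <- bootstrap_pdm_weights(red, pdms, x, y, n_boot = 50, seed = 3)
  expect_true(all(bw$degenerate[3, ]))
  expect_false(any(bw$significant[3, ]))
})
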