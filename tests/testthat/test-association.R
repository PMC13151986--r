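make_cov <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = rnorm(n, 12.3, 0.7), sex = rbinom(n, 1, 0.5),
             education = sample(1:4, n, replace = TRUE))
}

test_that("voxelwise GLM recovers a noiseless planted slope exactly", {
  n <- 40
  cov <- make_cov(n, 2)
  x <- rnorm(n)
  beta <- -0.7
  y <- outer(beta * x + 0.3 * cov$age - 0.1 * cov$sex, rep(1, 25))
  fit <- fit_voxelwise_glm(y, x, cov)
  expect_lt(max(abs(fit$beta - beta)), 1e-10)
  expect_equal(fit$df, n - 5)
})

test_that("voxelwise GLM matches an independent per-voxel lm oracle", {
  set.seed(7)
  n <- 35
  cov <- make_cov(n, 3)
  x <- rnorm(n)
  y <- matrix(rnorm(n * 30), n, 30) + outer(x, rnorm(30, 0, 0.4))
  fit <- fit_voxelwise_glm(y, x, cov)
  oracle <- brute_voxel_glm(y, x, cov)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-8)
  expect_equal(fit$se, oracle$se, tolerance = 1e-8)
  expect_equal(fit$t, oracle$t, tolerance = 1e-8)
  expect_equal(fit$p, oracle$p, tolerance = 1e-8)
  # t and p are consistent under the t CDF
  expect_equal(fit$p, 2 * pt(abs(fit$t), fit$df, lower.tail = FALSE))
  # rank-deficient design is rejected with the offending column named
  cov2 <- cov; cov2$age <- cov2$sex
  expect_error(fit_voxelwise_glm(y, cov2$sex, cov2), "rank-deficient")
})

test_that("null exposure yields the nominal suprathreshold fraction", {
  set.seed(19)
  n <- 50
  cov <- make_cov(n, 4)
  y <- matrix(rnorm(n * 20000), n)
  fit <- fit_voxelwise_glm(y, rnorm(n), cov)
  frac <- mean(fit$p < 0.001)
  expect_lt(abs(frac - 0.001), 3 * sqrt(0.001 * 0.999 / 20000))
})

test_that("cluster formation splits by sign and honours adjacency", {
  n <- 40
  dims <- c(8, 8, 4)
  mask <- array(TRUE, dims)
  cov <- make_cov(n, 5)
  x <- rnorm(n)
  blob_pos <- array(FALSE, dims); blob_pos[2:3, 2:3, 1:2] <- TRUE
  blob_neg <- array(FALSE, dims); blob_neg[6:8, 6:8, 3:4] <- TRUE
  y <- matrix(rnorm(n * prod(dims), 0, 0.05), n)
  y[, which(blob_pos)] <- y[, which(blob_pos)] + outer(x, rep(1, 8))
  y[, which(blob_neg)] <- y[, which(blob_neg)] - outer(x, rep(1, 18))
  fit <- fit_voxelwise_glm(y, x, cov)
  cl <- form_clusters(fit, mask, voxel_size = 4)
  expect_length(cl, 2)
  expect_identical(sort(vapply(cl, `[[`, integer(1), "size")), c(8L, 18L))
  signs <- vapply(cl, `[[`, numeric(1), "sign")
  expect_identical(sort(signs), c(-1, 1))
  # volume bookkeeping is exact
  expect_equal(vapply(cl, `[[`, numeric(1), "volume_cm3"),
               vapply(cl, `[[`, integer(1), "size") * 4^3 / 1000)
  # touching blobs of opposite sign stay separate clusters
  blob2 <- array(FALSE, dims); blob2[4, 2:3, 1:2] <- TRUE
  y2 <- y; y2[, which(blob2)] <- y2[, which(blob2)] - outer(x, rep(1, 4))
  cl2 <- form_clusters(fit_voxelwise_glm(y2, x, cov), mask, 4)
  expect_length(cl2, 3)
  # a null fit yields an empty candidate list at a strict threshold
  y_null <- matrix(rnorm(n * prod(dims)), n)
  fit_null <- fit_voxelwise_glm(y_null, x, cov)
  expect_length(form_clusters(fit_null, mask, 4, p_threshold = 1e-8), 0)
})

test_that("connected-component labeling distinguishes 6 from 26 adjacency", {
  m <- array(FALSE, c(4, 4, 2))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE     # diagonal contact only
  lab26 <- pbdefc:::label_components(m, 26)
  lab6 <- pbdefc:::label_components(m, 6)
  expect_equal(max(lab26), 1L)
  expect_equal(max(lab6), 2L)
})

test_that("permutation cluster inference: construction bound and BH oracle", {
  set.seed(8)
  n <- 45
  dims <- c(8, 8, 4)
  mask <- array(TRUE, dims)
  cov <- make_cov(n, 6)
  x <- rnorm(n)
  blob <- array(FALSE, dims); blob[3:6, 3:6, 2:3] <- TRUE
  y <- matrix(rnorm(n * prod(dims), 0, 0.3), n)
  y[, which(blob)] <- y[, which(blob)] - outer(x, rep(1, sum(blob)))
  ci <- cluster_extent_inference(y, x, cov, mask, voxel_size = 4,
                                 n_perm = 199, seed = 42)
  expect_gte(length(ci$clusters), 1)
  top <- ci$clusters[[1]]
  expect_equal(top$p, 1 / 200)           # observed exceeds all null maxima
  expect_equal(top$sign, -1)
  ps <- vapply(ci$clusters, `[[`, numeric(1), "p")
  expect_equal(vapply(ci$clusters, `[[`, numeric(1), "p_fdr"),
               brute_bh(ps), tolerance = 1e-12)
  expect_true(all(vapply(ci$clusters, `[[`, numeric(1), "p_fdr") >= ps))
})

test_that("cluster effect summaries match a from-scratch regression", {
  set.seed(13)
  n <- 60
  dims <- c(6, 6, 2)
  mask <- array(TRUE, dims)
  cov <- make_cov(n, 7)
  x <- rnorm(n)
  y <- matrix(rnorm(n * prod(dims), 1, 0.2), n) + outer(0.05 * x, rep(1, 72))
  cluster <- list(voxels = which(array(c(rep(TRUE, 10),
                                         rep(FALSE, 62)), dims)),
                  size = 10L, sign = 1)
  eff <- summarize_cluster_effect(y, cluster, mask, x, cov)
  cm <- rowMeans(y[, 1:10])
  fit <- lm(cm ~ x + age + sex + education, cbind(cov, x = x))
  expect_equal(eff$beta, unname(coef(fit)["x"]), tolerance = 1e-10)
  expect_equal(eff$ci, unname(confint(fit)["x", ]), tolerance = 1e-8)
  expect_equal(eff$percent_per_doubling, 100 * eff$beta / mean(cm))
  # percent CI scales linearly with the coefficient CI and brackets the point
  expect_equal(eff$percent_ci, sort(100 * eff$ci / mean(cm)))
  expect_true(eff$percent_ci[1] <= eff$percent_per_doubling &&
                eff$percent_per_doubling <= eff$percent_ci[2])
  expect_false(eff$absolute_scale)
})
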