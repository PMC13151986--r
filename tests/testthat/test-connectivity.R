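test_that("degenerate inputs give the closed-form LCOR/GCOR values", {
  dims <- c(4, 3, 3)
  t_n <- 50
  shared <- rnorm(t_n)
  img <- tiny_ts_image(matrix(shared, t_n, prod(dims)), dims)
  expect_equal(gcor_map(img)$values, rep(1, prod(dims)), tolerance = 1e-12)
  expect_equal(lcor_map(img)$values, rep(1, prod(dims)), tolerance = 1e-12)

  # two equal anticorrelated blocks: row sums of the correlation matrix are
  # exactly zero, so GCOR = -1/(N-1) everywhere
  n_half <- prod(dims) / 2
  dat <- cbind(matrix(shared, t_n, n_half), matrix(-shared, t_n, n_half))
  img2 <- tiny_ts_image(dat, dims)
  g2 <- gcor_map(img2)$values
  expect_equal(g2, brute_gcor(dat), tolerance = 1e-12)
  expect_equal(g2, rep(-1 / (prod(dims) - 1), prod(dims)),
               tolerance = 1e-12)
})

test_that("independent-noise LCOR is centred on zero", {
  set.seed(12)
  dims <- c(5, 5, 2)
  t_n <- 2000
  img <- tiny_ts_image(matrix(rnorm(t_n * prod(dims)), t_n), dims)
  vals <- lcor_map(img)$values
  # null correlation sd ~ 1/sqrt(T); the mean over voxels stays within 3 sd
  expect_lt(abs(mean(vals)), 3 / sqrt(t_n))
})

test_that("fast paths match the brute-force double loop", {
  set.seed(33)
  dims <- c(6, 6, 4)
  t_n <- 120
  shared <- rnorm(t_n)
  dat <- outer(shared, runif(prod(dims), -1, 1)) +
    matrix(rnorm(t_n * prod(dims)), t_n)
  img <- tiny_ts_image(dat, dims, voxel_size = 4)
  expect_equal(gcor_map(img)$values, brute_gcor(dat), tolerance = 1e-8)
  expect_equal(lcor_map(img, neighborhood_fwhm = 25)$values,
               brute_lcor(dat, img$mask, 4, 25), tolerance = 1e-8)
  # include-self variants agree too
  expect_equal(gcor_map(img, include_self = TRUE)$values,
               brute_gcor(dat, include_self = TRUE), tolerance = 1e-8)
})

test_that("relabeling voxels permutes the maps identically", {
  set.seed(54)
  dims <- c(4, 4, 3)
  t_n <- 80
  dat <- matrix(rnorm(t_n * prod(dims)), t_n) +
    outer(rnorm(t_n), runif(prod(dims)))
  img <- tiny_ts_image(dat, dims)
  g <- gcor_map(img)$values
  perm <- sample(prod(dims))
  gp <- gcor_map(tiny_ts_image(dat[, perm], dims))$values
  expect_equal(gp, g[perm], tolerance = 1e-12)
})

test_that("per-voxel temporal shuffling drives GCOR toward zero", {
  set.seed(77)
  dims <- c(4, 4, 3)
  t_n <- 1000
  dat <- outer(rnorm(t_n), rep(1, prod(dims))) + matrix(rnorm(t_n * 48), t_n)
  shuffled <- apply(dat, 2, sample)
  g <- gcor_map(tiny_ts_image(shuffled, dims))$values
  expect_lt(mean(abs(g)), 3 / sqrt(t_n) * 3)
})

test_that("LCOR with uniform weights over all voxels equals GCOR", {
  set.seed(90)
  dims <- c(4, 3, 3)
  dat <- matrix(rnorm(60 * prod(dims)), 60) + outer(rnorm(60), runif(36))
  img <- tiny_ts_image(dat, dims)
  expect_equal(lcor_map(img, uniform_weights = TRUE)$values,
               gcor_map(img)$values, tolerance = 1e-10)
})

test_that("seed series and seed-to-voxel maps match brute force", {
  set.seed(61)
  dims <- c(4, 4, 2)
  t_n <- 90
  dat <- matrix(rnorm(t_n * prod(dims)), t_n)
  img <- tiny_ts_image(dat, dims)
  m1 <- array(FALSE, dims); m1[1, 1, 1] <- TRUE
  expect_equal(seed_series(img, m1), dat[, 1])
  m2 <- array(FALSE, dims); m2[1, 1, 1] <- m2[2, 1, 1] <- TRUE
  expect_equal(seed_series(img, m2), rowMeans(dat[, 1:2]))
  # antiphase pair averages to ~0
  dat2 <- dat; dat2[, 2] <- -dat2[, 1]
  expect_equal(seed_series(tiny_ts_image(dat2, dims), m2), rep(0, t_n))
  expect_error(seed_series(img, array(FALSE, dims)), "empty")

  seed <- rowMeans(dat[, 1:3])
  zmap <- seed_to_voxel_map(img, seed)
  brute <- atanh(apply(dat, 2, cor, y = seed))
  expect_equal(zmap$values, brute, tolerance = 1e-10)
  # closed form: r = 0.5 -> z = 0.54931; |r| = 1 is clipped and flagged
  expect_equal(atanh(0.5), 0.5493061, tolerance = 1e-6)
  self_map <- seed_to_voxel_map(img, dat[, 4])
  expect_equal(attr(self_map, "n_clipped"), 1)
  expect_true(is.finite(self_map$values[4]))
})

test_that("zero-variance voxels are masked out and counted", {
  dims <- c(4, 4, 2)
  dat <- matrix(rnorm(40 * prod(dims)), 40)
  dat[, 5] <- 2.5
  g <- gcor_map(tiny_ts_image(dat, dims))
  expect_true(is.na(g$values[5]))
  expect_equal(attr(g, "n_undefined"), 1)
})
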