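test_that("framewise displacement follows the displacement formula", {
  mot <- matrix(0, 4, 6)
  mot[2, 1] <- 1                       # 1 mm x-translation at frame 2
  mot[3, 4] <- mot[2, 4] + 0.02        # 0.02 rad pitch change at frame 3
  mot[2, 4] <- 0
  fd <- compute_fd(mot, rotation_radius = 50)
  expect_equal(fd[1], 0)
  expect_equal(fd[2], 1.0)
  expect_equal(fd[3], 1.0 + 0.02 * 50)  # x returning to 0 plus the rotation
  expect_equal(compute_fd(matrix(5, 10, 6)), rep(0, 10))
  expect_error(compute_fd(matrix(c(NaN, rep(0, 11)), 2, 6)), "finite")
  # FD resets at run boundaries
  mot2 <- rbind(matrix(0, 3, 6), matrix(10, 3, 6))
  fd2 <- compute_fd(mot2, run = rep(1:2, each = 3))
  expect_equal(fd2[4], 0)
})

test_that("outlier frames are flagged by FD or global-signal z", {
  fd <- c(0, 1.0, 0.5)
  gs <- c(0, 0, 0)
  expect_identical(flag_outlier_frames(fd, gs), c(FALSE, TRUE, FALSE))
  # one huge global-signal jump among small ones
  set.seed(4)
  gs2 <- cumsum(rnorm(200, 0, 0.1)); gs2[25] <- gs2[24] + 20
  flags <- flag_outlier_frames(rep(0, 200), gs2)
  expect_true(flags[25])
  expect_lt(sum(flags), 5)
  expect_identical(flag_outlier_frames(c(0, 0.1), c(0, 0)), c(FALSE, FALSE))
})

test_that("participant exclusion applies the mean-FD / censoring rules", {
  dec <- exclude_participants(c(0.45, 0.2, 0.39), c(0.10, 0.41, 0.39))
  expect_identical(dec$keep, c(FALSE, FALSE, TRUE))
  expect_match(dec$reason[1], "mean FD")
  expect_match(dec$reason[2], "censored")
  expect_identical(dec$reason[3], "")
})

test_that("CompCor components recover a planted compartment latent", {
  set.seed(8)
  t_n <- 80
  latent <- rnorm(t_n)
  comp <- outer(latent, runif(30, 0.5, 2)) +
    matrix(rnorm(t_n * 30, 0, 0.05), t_n, 30)
  cc <- compcor_components(comp, n = 5)
  expect_gt(abs(cor(cc[, 1], latent)), 0.999)
  # orthonormality
  expect_lt(max(abs(crossprod(cc) - diag(5))), 1e-8)
  # rank-3 data yield 3 components and a warning
  low <- matrix(rnorm(t_n * 3), t_n, 3) %*% matrix(rnorm(60), 3, 20)
  expect_warning(cc3 <- compcor_components(low, n = 5), "rank")
  expect_equal(ncol(cc3), 3)
})

test_that("nuisance regression projects out confounds exactly", {
  set.seed(15)
  t_n <- 60
  conf <- cbind(1, rnorm(t_n), rnorm(t_n), rnorm(t_n))
  y <- matrix(rnorm(t_n * 12), t_n, 12)
  y[, 1] <- conf[, 2]                      # a voxel equal to a confound
  res <- nuisance_regress(y, conf)
  expect_lt(max(abs(res[, 1])), 1e-10)
  expect_lt(max(abs(crossprod(conf, res))) / max(abs(y)), 1e-8)
  # matches an independent per-voxel least-squares solve
  for (j in c(2, 5, 12))
    expect_equal(res[, j], unname(resid(lm(y[, j] ~ 0 + conf))),
                 tolerance = 1e-10)
  expect_error(nuisance_regress(y[1:3, ], conf[1:3, ]), "confounds")
  # collinear columns are dropped, not fatal
  expect_message(res2 <- nuisance_regress(y, cbind(conf, conf[, 2])),
                 "collinear")
  expect_equal(res2, res, tolerance = 1e-10)
})

test_that("band-pass filter honours its attenuation contract", {
  t_n <- 200; tr <- 2
  tt <- seq_len(t_n) * tr
  ramp <- matrix(seq_len(t_n), t_n, 1)
  expect_lt(max(abs(bandpass_detrend(ramp, tr))), 1e-6 * t_n)
  hi <- matrix(sin(2 * pi * 0.15 * tt), t_n, 1)
  expect_lt(max(abs(bandpass_detrend(hi, tr))), 0.05)
  lo <- matrix(sin(2 * pi * 0.03 * tt), t_n, 1)
  expect_gt(max(abs(bandpass_detrend(lo, tr))), 0.90)
  expect_error(bandpass_detrend(matrix(1, 8, 1), tr), "few frames")
  expect_error(bandpass_detrend(matrix(1, 100, 1), tr, band = c(0.01, 0.3)),
               "Nyquist")
})

test_that("spatial smoothing is unit-mass and matches the analytic Gaussian", {
  dims <- c(21, 21, 21)
  const <- array(3.5, dim = dims)
  out <- smooth_spatial(const, fwhm = 8, voxel_size = 2)
  expect_equal(out, const, tolerance = 1e-12)
  expect_identical(smooth_spatial(const, fwhm = 0, voxel_size = 2), const)
  expect_warning(smooth_spatial(const, fwhm = 0.5, voxel_size = 2), "voxel")

  imp <- array(0, dim = dims); imp[11, 11, 11] <- 1
  sm <- smooth_spatial(imp, fwhm = 8, voxel_size = 2)
  sigma <- 8 / (2 * sqrt(2 * log(2)))
  # profile proportional to the analytic Gaussian within 1% at <= 2 sigma
  ref <- sm[11, 11, 11]
  for (off in 1:3) {
    dist <- off * 2
    if (dist > 2 * sigma) next
    expect_equal(sm[11 + off, 11, 11] / ref, exp(-dist^2 / (2 * sigma^2)),
                 tolerance = 0.01)
  }
})

test_that("mean motion is unrelated to GCOR when no coupling is planted", {
  cfg <- default_config(n_participants = 24, seed = 31)
  co <- generate_cohort(cfg)
  ts <- generate_timeseries(co, cfg)
  stats <- vapply(seq_len(24), function(i) {
    d <- denoise_participant(ts$images[[i]], ts$motion[[i]],
                             ts$wm_ts[[i]], ts$csf_ts[[i]])
    c(d$qc$mean_fd, mean(gcor_map(d$img, censored = d$censored)$values))
  }, numeric(2))
  expect_gt(cor.test(stats[1, ], stats[2, ])$p.value, 0.05)
})
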