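test_that("identical seeds give byte-identical cohorts and time series", {
  cfg <- default_config(n_participants = 12, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$exposures, b$exposures)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$covariates, b$covariates)
  ta <- generate_timeseries(a, cfg)
  tb <- generate_timeseries(b, cfg)
  expect_identical(ta$images[[3]]$data, tb$images[[3]]$data)
  expect_identical(ta$motion[[3]], tb$motion[[3]])
})

test_that("below-LOD counts match the configured detection rate", {
  cfg <- default_config(n_participants = 1000, seed = 11)
  co <- generate_cohort(cfg)
  # BDE-28 detection rate 0.888: expect ~112 censored, binomial sd ~10
  n_below <- sum(co$exposures$bde28_below_lod)
  expect_lt(abs(n_below - 112), 3 * sqrt(1000 * 0.888 * 0.112))
  # detection rate 1 would censor nothing
  cfg2 <- default_config(n_participants = 50,
                         detection_rates = rep(1, 5), seed = 2)
  co2 <- generate_cohort(cfg2)
  expect_false(any(co2$exposures$bde47_below_lod))
})

test_that("sample geometric means track the configured geomeans", {
  cfg <- default_config(n_participants = 600, seed = 5)
  co <- generate_cohort(cfg)
  raw_gm <- exp(colMeans(log(
    as.matrix(co$exposures[, c("bde28", "bde47", "bde99", "bde100",
                               "bde153")]))))
  expect_true(all(abs(raw_gm / cfg$congener_geomeans - 1) < 0.15))
})

test_that("zero-noise outcomes equal the linear predictor and recover paths", {
  cfg <- default_config(
    n_participants = 40, seed = 9,
    noise_params = list(ts_noise_sd = 1, outcome_noise_sd = 0,
                        mediator_noise_sd = 0.1, motion_spike_rate = 0))
  co <- generate_cohort(cfg)
  expect_equal(co$outcomes$tscore_social,
               co$truth$linear_predictors$tscore_social, tolerance = 1e-12)
  # regressing the outcome on exposure + mediators + covariates returns the
  # planted coefficients exactly (planted mediation bookkeeping)
  d <- data.frame(y = co$outcomes$tscore_social,
                  x = co$exposures_prepared$log2_sum5,
                  m1 = co$truth$mediators$m1, m2 = co$truth$mediators$m2,
                  co$covariates[c("age", "sex", "education")])
  fit <- lm(y ~ x + m1 + m2 + age + sex + education, d)
  expect_equal(unname(coef(fit)["x"]), co$truth$true_c_prime,
               tolerance = 1e-8)
  expect_equal(unname(coef(fit)["m1"]), co$truth$true_b, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["m2"]), co$truth$true_b2, tolerance = 1e-8)
})

test_that("config invariants are enforced", {
  expect_error(default_config(grid_shape = c(3, 3, 3)), "grid_shape")
  expect_error(default_config(n_frames = 20, n_runs = 2), "n_frames")
  expect_error(default_config(detection_rates = c(0, 1, 1, 1, 1)),
               "detection_rates")
  bad <- matrix(0.99, 5, 5); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(default_config(congener_log_corr = bad),
               "positive-definite")
})

test_that("planted masks are disjoint, in-brain, and the GCOR effect is negative", {
  cfg <- default_config(n_participants = 60, seed = 21,
                        noise_params = list(ts_noise_sd = 0.3,
                                            outcome_noise_sd = 9,
                                            mediator_noise_sd = 0.02,
                                            motion_spike_rate = 0))
  co <- generate_cohort(cfg)
  tr <- co$truth
  expect_false(any(tr$gcor_cluster_mask & tr$lcor_cluster_mask))
  expect_false(any(tr$gcor_cluster_mask & tr$pattern2_mask))
  expect_true(all(which(tr$gcor_cluster_mask) %in% which(co$masks$brain)))
  expect_true(all(which(tr$lcor_cluster_mask) %in% which(co$masks$brain)))
  expect_identical(tr$true_indirect, tr$true_a * tr$true_b)

  # high-SNR cohort: exposure correlates negatively with cluster GCOR
  ts <- generate_timeseries(co, cfg)
  idx <- mask_index(co$masks$brain, tr$gcor_cluster_mask)
  gm <- vapply(seq_len(cfg$n_participants), function(i)
    mean(gcor_map(ts$images[[i]])$values[idx]), numeric(1))
  expect_lt(cor(co$exposures_prepared$log2_sum5, gm), 0)
})
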