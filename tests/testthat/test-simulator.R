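test_that("default settings match the intended study design", {
  cfg <- default_params()
  expect_equal(cfg$n_modes, 16L)
  expect_equal(cfg$timepoint_interval, 0.05)
  expect_equal(cfg$n_subjects * 2L, 8800L)
  expect_equal(range(cfg$ef_targets), c(0.02, 0.68))
  sim <- simulate_cohort(cfg, seed = 3)
  expect_equal(sim$cohort$n, 8800L)
  expect_equal(ncol(sim$cohort$features), 16L)
  expect_true(sim$cohort$paired)
})

test_that("identical seeds give bit-identical cohorts", {
  a <- simulate_cohort(small_config(), seed = 99)
  b <- simulate_cohort(small_config(), seed = 99)
  expect_identical(a$cohort$features, b$cohort$features)
  expect_identical(a$truth$x0, b$truth$x0)
  c <- simulate_cohort(small_config(), seed = 100)
  expect_false(identical(a$cohort$features, c$cohort$features))
})

test_that("zero rate variance and zero noise freeze subjects over time", {
  cfg <- default_params(n_subjects = 200L, n_modes = 6L,
                        ef_targets = rep(1e-9, 6),
                        age_corr_targets = seq(0.5, 0.3, length.out = 6),
                        noise_frac_range = c(1e-12, 2e-12),
                        contraction_fraction = 0)
  sim <- simulate_cohort(cfg, seed = 4)
  x <- sim$cohort$features
  # recover the generative ages and population curve shape
  y <- (sim$cohort$age_years - cfg$age_range_years[1]) /
    diff(cfg$age_range_years)
  shape <- y + cfg$curve_quad_ratio * y^2
  curve_diff <- shape[201:400] - shape[1:200]
  # the only between-timepoint change is the population mean aging curve:
  # subject-level change minus the curve difference vanishes
  for (j in 1:6) {
    dlong <- (x[201:400, j] - x[1:200, j]) -
      curve_diff * sim$truth$curve_scale[j]
    expect_lt(max(abs(dlong)), 1e-3)
  }
})

test_that("a single pure-expansion mode yields Ef near 1 and high rxl", {
  cfg <- default_params(n_modes = 1L, n_subjects = 1500L,
                        ef_targets = 0.999,
                        age_corr_targets = 0.4,
                        noise_frac_range = c(1e-10, 2e-10),
                        contraction_fraction = 0)
  sim <- simulate_cohort(cfg, seed = 5)
  co <- sim$cohort
  d <- compute_mode_delta(co$features[, 1], co$age_norm)
  fit <- fit_expansion(d, co$age_norm, paired = TRUE)
  expect_gt(fit$Ef, 0.97)
  expect_equal(fit$direction, "expand")
  # rxl at its structural ceiling E[Y]/sqrt(E[Y^2]) for noiseless expansion
  s <- cross_long_split(d, co)
  expect_gt(s$rxl, 0.8)
})

test_that("realised moments match the configured generative truth", {
  cfg <- default_params()
  sim <- simulate_cohort(cfg, seed = 6)
  tr <- sim$truth
  n <- cfg$n_subjects
  # per-mode variances of x0 and beta track their targets within sampling
  # error (~ 3 * sqrt(2/n) relative for a chi-square variance estimate)
  band <- 3 * sqrt(2 / n)
  exp_ef <- cfg$ef_targets
  exp_ef[tr$contract] <- exp_ef[tr$contract] / cfg$contraction_attenuation
  expect_true(all(abs(tr$B_true / (1 - exp_ef - tr$noise_frac) - 1) < 2 * band))
  expect_true(all(abs(tr$E_true * tr$ybar2 / exp_ef - 1) < 2 * band))
  expect_true(all(abs(colMeans(tr$x0)) < 4 * sqrt(tr$B_true / n)))
  expect_true(all(abs(colMeans(tr$beta)) < 4 * sqrt(tr$E_true / n)))
  # x0 is shared between timepoints; measurement noise is not
  x <- sim$cohort$features
  for (j in c(1, 9)) {
    d <- compute_mode_delta(x[, j], sim$cohort$age_norm)$delta
    resid1 <- d[1:n] - tr$x0[, j]
    resid2 <- d[(n + 1):(2 * n)] - tr$x0[, j]
    rate_part <- cor(resid1, resid2)  # shared rate term + independent noise
    noiseless <- tr$ybar2[j] * tr$E_true[j] /
      (tr$ybar2[j] * tr$E_true[j] + tr$noise_var[j])
    expect_lt(abs(rate_part - noiseless), 0.12)
  }
})

test_that("achieved cross-mode correlations sit near the calibration targets", {
  sim <- simulate_cohort(default_params(), seed = 7)
  cx <- cor(sim$cohort$features)
  expect_lt(abs(mean(cx[upper.tri(cx)]) - 0.39), 0.1)
  dm <- vapply(compute_mode_deltas(sim$cohort), `[[`,
               numeric(sim$cohort$n), "delta")
  cd <- cor(dm)
  expect_lt(abs(mean(cd[upper.tri(cd)]) - 0.24), 0.08)
  # the true fractional expansions span the intended real-data-like range
  expect_gt(max(abs(sim$truth$ef_true)), 0.55)
  expect_lt(min(abs(sim$truth$ef_true)), 0.06)
})

test_that("an unattainable correlation target is rejected as non-PSD", {
  cfg <- small_config(delta_corr_target = 0.99)
  expect_error(simulate_cohort(cfg, seed = 8), "not positive semi-definite")
})

test_that("truth_corr = 1 yields perfectly correlated baselines and rates", {
  sim <- simulate_cohort(small_config(), truth_corr = 1, seed = 9)
  for (j in 1:6)
    expect_equal(cor(sim$truth$x0[, j], sim$truth$beta[, j]), 1,
                 tolerance = 1e-10)
  sim0 <- simulate_cohort(small_config(), truth_corr = 0, seed = 9)
  cc <- abs(diag(cor(sim0$truth$x0, sim0$truth$beta)))
  expect_lt(max(cc), 0.2)
  expect_error(simulate_cohort(small_config(), truth_corr = 2), "truth_corr")
})
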