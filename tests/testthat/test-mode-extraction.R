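test_that("median/MAD outlier removal matches the hand-computed rule", {
  x <- c(1, 2, 3, 4, 100)  # median 3, MAD 1, threshold 5
  out <- remove_outliers(x)
  expect_equal(out, c(1, 2, 3, 4, NA))
  expect_equal(remove_outliers(rep(2, 5)), rep(2, 5))
  # zero MAD with deviations present: nothing removed, feature flagged
  expect_message(out2 <- remove_outliers(c(rep(1, 10), 50)), "zero MAD")
  expect_false(anyNA(out2))
  expect_error(remove_outliers(c(1, NA, NA, NA)), "non-missing")
  # clean Gaussian data lose well under 1% of values
  set.seed(14)
  g <- rnorm(1000)
  expect_lt(mean(is.na(remove_outliers(g))), 0.01)
})

test_that("confound regression residualises exactly in hand cases", {
  set.seed(15)
  conf <- matrix(rnorm(30), 30, 1)
  # feature identical to the confound: residual ~ 0
  x <- cbind(f1 = conf[, 1], f2 = rnorm(30))
  res <- regress_confounds(x, conf)
  expect_lt(max(abs(res[, "f1"])), 1e-10)
  # orthogonal confound leaves the feature unchanged up to mean removal
  f <- rnorm(30)
  f_orth <- f - mean(f)
  conf_orth <- matrix(residuals(lm(rnorm(30) ~ f)), ncol = 1)
  res2 <- regress_confounds(cbind(f = f), conf_orth)
  expect_equal(unname(res2[, 1]), f_orth, tolerance = 1e-6)
  # 3-sample closed form: residual of y on [1, c]
  y3 <- c(1, 4, 5); c3 <- c(0, 1, 3)
  b <- cov(y3, c3) / var(c3)
  expect_equal(unname(regress_confounds(cbind(y3), cbind(c3))[, 1]),
               y3 - mean(y3) - b * (c3 - mean(c3)), tolerance = 1e-12)
  # collinear confounds are dropped with a warning
  expect_warning(regress_confounds(x, cbind(conf, 2 * conf)), "collinear")
})

test_that("age weighting applies squared Pearson correlations per column", {
  set.seed(16)
  y <- runif(200)
  x <- cbind(age_copy = y, noise = rnorm(200), flat = rep(1, 200),
             mixed = y + rnorm(200))
  xw <- age_weighting(x, y)
  w <- attr(xw, "weights")
  expect_equal(w[["age_copy"]], 1, tolerance = 1e-12)
  expect_lt(w[["noise"]], 0.05)
  expect_equal(w[["flat"]], 0)
  expect_equal(w[["mixed"]], cor(x[, "mixed"], y)^2, tolerance = 1e-12)
  expect_equal(xw[, "age_copy"], x[, "age_copy"], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("SVD soft-impute is exact with no missing data and recovers rank-1", {
  set.seed(17)
  x <- matrix(rnorm(50 * 8), 50, 8)
  out <- svd_soft_impute(x, rank = 3)
  expect_identical(out$completed, x)
  sv <- svd(x)
  # basis spans the same leading row space (compare projectors)
  p1 <- crossprod(out$basis)
  p2 <- tcrossprod(sv$v[, 1:3])
  expect_equal(p1, p2, tolerance = 1e-10)

  # rank-1 matrix with 5% of cells deleted: near-exact completion
  u <- rnorm(80); v <- rnorm(40)
  r1 <- tcrossprod(u, v)
  miss <- matrix(FALSE, 80, 40)
  miss[sample(length(r1), 0.05 * length(r1))] <- TRUE
  r1na <- r1; r1na[miss] <- NA
  comp <- svd_soft_impute(r1na, rank = 1, max_missing = 0.5)
  rel_err <- abs(comp$completed[miss] - r1[miss]) / (abs(r1[miss]) + 1e-12)
  expect_lt(stats::median(rel_err), 0.01)
  expect_lt(mean(rel_err > 0.05), 0.05)

  # lambda = 0 reduces to hard-rank iterative imputation
  comp0 <- svd_soft_impute(r1na, rank = 1, lambda = 0, max_missing = 0.5)
  expect_lt(max(abs(comp0$completed[miss] - r1[miss])) / max(abs(r1)), 0.01)
  # per-column missingness bound enforced
  bad <- x; bad[1:20, 1] <- NA
  expect_error(svd_soft_impute(bad, rank = 2), "missing-data bound")
})

test_that("FastICA recovers planted independent feature-direction sources", {
  set.seed(18)
  p <- 600
  s_true <- rbind(runif(p, -1, 1),
                  sign(rnorm(p)) * rexp(p),
                  rbinom(p, 1, 0.15) * rnorm(p, 0, 3))
  s_true <- s_true - rowMeans(s_true)
  mix <- matrix(rnorm(120 * 3), 120, 3)
  x <- mix %*% s_true
  basis <- svd(x)$v[, 1:3]
  ica <- fast_ica(t(basis), n_comp = 3, seed = 2)
  # sources match truth up to permutation and sign
  cc <- abs(cor(t(ica$sources), t(s_true)))
  expect_true(all(apply(cc, 2, max) > 0.95))
})

test_that("extracted modes obey the sign and ordering conventions", {
  set.seed(19)
  sim <- simulate_cohort(small_config(n_subjects = 250L), seed = 77)
  scores <- sim$cohort$features
  loadings <- matrix(rnorm(6 * 120), 6, 120)
  idps <- scores %*% loadings + matrix(rnorm(500 * 120, 0, 0.5), 500, 120)
  co <- cohort(idps, age_years = sim$cohort$age_years)
  dec <- extract_modes(co, n_modes = 6, seed = 3)
  expect_true(all(dec$age_corr >= 0))
  expect_true(all(diff(dec$age_corr) <= 1e-12))
  expect_equal(dim(dec$subject_weights), c(500L, 6L))
  expect_equal(qr(dec$subject_weights)$rank, 6L)
  # determinism: identical seed gives identical decomposition
  dec2 <- extract_modes(co, n_modes = 6, seed = 3)
  expect_identical(dec$idp_weights, dec2$idp_weights)
  expect_identical(dec$subject_weights, dec2$subject_weights)
})

test_that("age-unrelated planted sources get near-zero age correlation", {
  # the r^2 weighting must not manufacture age associations
  set.seed(20)
  n <- 400
  y <- runif(n)
  aging <- y + 0.3 * rnorm(n)
  unrelated <- rnorm(n)
  loadings <- matrix(rnorm(2 * 80), 2, 80)
  idps <- cbind(aging, unrelated) %*% loadings +
    matrix(rnorm(n * 80, 0, 0.3), n, 80)
  dec <- extract_modes(cohort(idps, 50 + 30 * y), n_modes = 2, seed = 4)
  expect_gt(dec$age_corr[1], 0.6)
  expect_lt(dec$age_corr[2], 0.25)
})

test_that("all-in-one Ef is stable across decomposition dimensionalities", {
  set.seed(22)
  sim <- simulate_cohort(default_params(n_subjects = 600L), seed = 88)
  loadings <- matrix(rnorm(16 * 150), 16, 150)
  idps <- sim$cohort$features %*% loadings +
    matrix(rnorm(1200 * 150, 0, 0.4), 1200, 150)
  co <- cohort(idps, age_years = sim$cohort$age_years,
               subject_id = sim$cohort$subject_id,
               timepoint = sim$cohort$timepoint, paired = TRUE)
  efs <- vapply(c(12L, 16L, 20L), function(k) {
    dec <- extract_modes(co, n_modes = k, seed = 5)
    mc <- cohort(dec$subject_weights, age_years = co$age_years, paired = TRUE)
    aio <- fit_all_in_one(mc)
    fit_expansion(aio$delta, mc$age_norm, paired = TRUE, se = FALSE)$signed_Ef
  }, numeric(1))
  expect_lt(stats::sd(efs) / abs(mean(efs)), 0.35)
})
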