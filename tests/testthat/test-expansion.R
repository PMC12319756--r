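test_that("method-of-moments initialisation solves exact and noisy cases", {
  y <- seq(0.05, 1, length.out = 60)
  d <- sqrt(1 + 2 * y^2) * rep(c(1, -1), 30)  # delta^2 = 1 + 2*Y^2 exactly
  expect_equal(unname(mom_init(d, y)), c(1, 2), tolerance = 1e-10)

  # delta independent of age: E0 within OLS standard error of zero
  set.seed(5)
  y2 <- runif(500)
  d2 <- rnorm(500)
  x <- cbind(1, y2^2)
  cf <- solve(crossprod(x), crossprod(x, d2^2))
  resid <- d2^2 - x %*% cf
  se_E <- sqrt(solve(crossprod(x))[2, 2] * sum(resid^2) / 498)
  expect_lt(abs(mom_init(d2, y2)[["E"]]), 2.5 * se_E + 1e-9)

  # fixed-seed simulated deltas: agrees with the normal-equations oracle
  set.seed(6)
  y3 <- runif(500)
  d3 <- rnorm(500, 0, sqrt(1 + 4 * y3^2))
  x3 <- cbind(1, y3^2)
  oracle <- solve(crossprod(x3), crossprod(x3, d3^2))
  expect_equal(unname(mom_init(d3, y3)), pmax(as.numeric(oracle), 1e-12 * var(d3)),
               tolerance = 1e-10)
  expect_error(mom_init(rnorm(10), rep(0.5, 10)), "not identifiable")
})

test_that("log-likelihood matches closed forms and direct summation", {
  # E = 0 reduces to the iid Gaussian log-likelihood with variance B
  set.seed(7)
  d <- rnorm(30)
  y <- runif(30)
  expect_equal(expansion_loglik(d, y, B = 2, E = 0),
               sum(dnorm(d, 0, sqrt(2), log = TRUE)), tolerance = 1e-12)
  # single sample closed form
  expect_equal(expansion_loglik(0, 1, B = 1, E = 0), -0.5 * log(2 * pi),
               tolerance = 1e-14)
  # term-by-term hand summation
  d20 <- rnorm(20); y20 <- runif(20)
  s2 <- 0.7 + y20^2 * 1.3
  expect_equal(expansion_loglik(d20, y20, 0.7, 1.3),
               sum(-0.5 * (log(2 * pi * s2) + d20^2 / s2)), tolerance = 1e-12)
  expect_identical(expansion_loglik(d20, y20, -1, 1), -Inf)
})

test_that("ML fit matches a dense likelihood grid search on a small instance", {
  set.seed(42)
  n <- 200
  y <- runif(n)
  d <- rnorm(n, 0, sqrt(1 + 4 * y^2))
  d <- orthogonalize_age(d, y)
  fit <- fit_expansion(d, y)
  grid <- exp(seq(log(0.01), log(10), length.out = 250))
  u <- if (fit$direction == "contract") (1 - y)^2 else y^2
  ll <- outer(grid, grid, Vectorize(function(B, E) {
    s2 <- B + u * E
    -0.5 * sum(log(2 * pi * s2) + d^2 / s2)
  }))
  best <- arrayInd(which.max(ll), dim(ll))
  step <- grid[2] / grid[1]  # multiplicative grid resolution
  expect_lt(abs(log(fit$B / grid[best[1]])), 1.01 * log(step))
  expect_lt(abs(log(fit$E / grid[best[2]])), 1.01 * log(step))
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("null and pure-expansion cases land on the fraction boundaries", {
  set.seed(8)
  n <- 5000
  y <- runif(n)
  # baseline only: Ef within 2 SE of 0, Bf within 2 SE of 1
  d_b <- orthogonalize_age(rnorm(n), y)
  fb <- fit_expansion(d_b, y)
  expect_lt(fb$Ef, 2 * fb$se_Ef)
  expect_lt(abs(fb$Bf - 1), 2 * fb$se_Bf)
  # pure expansion: Bf within 2 SE of 0
  d_e <- orthogonalize_age(y * rnorm(n, 0, 2), y)
  fe <- fit_expansion(d_e, y)
  expect_lt(fe$Bf, 2.5 * fe$se_Bf)
  expect_equal(fe$direction, "expand")
})

test_that("fraction identity, variance conservation, and MoM dominance hold", {
  set.seed(9)
  for (rep in 1:6) {
    n <- 400
    y <- runif(n)
    d <- orthogonalize_age(rnorm(n, 0, sqrt(0.5 + 2 * y^2)), y)
    fit <- fit_expansion(d, y)
    expect_equal(fit$Bf + fit$Ef, 1, tolerance = 1e-10)
    expect_gte(fit$Ef, 0); expect_lte(fit$Ef, 1)
    # B + mean(u)*E reproduces the total delta variance when well specified
    expect_equal(fit$B + fit$ybar2 * fit$E, fit$var_delta, tolerance = 0.08)
    # the ML optimum cannot fall below its method-of-moments start
    init <- mom_init(d, y, contraction = fit$direction == "contract")
    expect_gte(fit$loglik,
               expansion_loglik(d, y, init[["B"]], init[["E"]],
                                contraction = fit$direction == "contract"))
  }
})

test_that("contraction data are recovered and mirror to expansion", {
  set.seed(10)
  n <- 3000
  y <- runif(n)
  d <- orthogonalize_age(rnorm(n, 0, sqrt(0.3 + (1 - y)^2 * 2)), y)
  fit <- fit_expansion(d, y)
  expect_equal(fit$direction, "contract")
  expect_lt(fit$signed_Ef, 0)
  expect_equal(fit$Ef, abs(fit$signed_Ef))
  # time-mirrored data fitted as expansion recover the same (B, E)
  mirrored <- fit_expansion(d, 1 - y)
  expect_equal(mirrored$direction, "expand")
  expect_equal(mirrored$B, fit$B, tolerance = 1e-6)
  expect_equal(mirrored$E, fit$E, tolerance = 1e-6)
})

test_that("paired standard errors are exactly sqrt(2) times unpaired", {
  set.seed(12)
  y <- runif(600)
  d <- orthogonalize_age(rnorm(600, 0, sqrt(1 + y^2)), y)
  f1 <- fit_expansion(d, y, paired = FALSE)
  f2 <- fit_expansion(d, y, paired = TRUE)
  expect_equal(f2$se_B, sqrt(2) * f1$se_B, tolerance = 1e-12)
  expect_equal(f2$se_E, sqrt(2) * f1$se_E, tolerance = 1e-12)
  expect_equal(f2$se_Bf, sqrt(2) * f1$se_Bf, tolerance = 1e-12)
  expect_equal(f2$se_Ef, sqrt(2) * f1$se_Ef, tolerance = 1e-12)
})

test_that("theoretical SEs shrink like 1/sqrt(n) and match Monte-Carlo RMSE", {
  set.seed(13)
  gen <- function(n) {
    y <- runif(n)
    list(y = y, d = orthogonalize_age(rnorm(n, 0, sqrt(1 + 2 * y^2)), y))
  }
  g1 <- gen(1000); g4 <- gen(4000)
  s1 <- fit_expansion(g1$d, g1$y)$se_E
  s4 <- fit_expansion(g4$d, g4$y)$se_E
  expect_equal(s1 / s4, 2, tolerance = 0.25)

  # Monte-Carlo: mean theoretical se_Ef within ~30% of the empirical RMSE
  reps <- 80
  ef_err <- se_theory <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- gen(1000)
    f <- fit_expansion(g$d, g$y)
    ef_true <- mean(g$y^2) * 2 / (1 + mean(g$y^2) * 2)
    ef_err[r] <- f$signed_Ef - ef_true
    se_theory[r] <- f$se_Ef
  }
  rmse <- sqrt(mean(ef_err^2))
  expect_lt(abs(mean(se_theory) - rmse) / rmse, 0.35)
})
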