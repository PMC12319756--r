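#' Method-of-moments initialisation for the expansion model
#'
#' Ordinary least squares of squared deltas on `[1, u]` with `u = Y^2`
#' (or `(1-Y)^2` for the contraction variant), giving starting values for
#' the baseline variance B and expansion variance E. Negative estimates
#' are clipped to a small positive floor.
#'
#' @param delta a `delta_set` or numeric vector of deltas.
#' @param age_norm normalised ages.
#' @param contraction use the `1 - Y` parameterisation.
#' @return named numeric `c(B, E)`.
#' @export
mom_init <- function(delta, age_norm, contraction = FALSE) {
  d <- if (inherits(delta, "delta_set")) delta$delta else as.numeric(delta)
  if (length(d) != length(age_norm)) stop("length mismatch")
  if (length(d) < 3) stop("need at least 3 samples")
  if (length(unique(age_norm)) < 2)
    stop("expansion not identifiable: all ages identical")
  u <- if (contraction) (1 - age_norm)^2 else age_norm^2
  cf <- stats::lm.fit(cbind(1, u), d^2)$coefficients
  floor <- 1e-12 * stats::var(d)
  c(B = max(cf[[1]], floor), E = max(cf[[2]], floor))
}

#' Gaussian log-likelihood of the heteroscedastic expansion model
#'
#' Zero-mean Gaussian for each delta with age-dependent variance
#' `sigma_i^2 = B + u_i * E`, `u_i = Y_i^2` (expansion) or `(1-Y_i)^2`
#' (contraction). Returns `-Inf` whenever any variance is non-positive.
#'
#' @param delta a `delta_set` or numeric vector.
#' @param age_norm normalised ages.
#' @param B,E baseline and expansion variance parameters.
#' @param contraction use the `1 - Y` parameterisation.
#' @return scalar log-likelihood.
#' @export
expansion_loglik <- function(delta, age_norm, B, E, contraction = FALSE) {
  d <- if (inherits(delta, "delta_set")) delta$delta else as.numeric(delta)
  u <- if (contraction) (1 - age_norm)^2 else age_norm^2
  s2 <- B + u * E
  if (any(s2 <= 0) || !is.finite(B) || !is.finite(E)) return(-Inf)
  -0.5 * sum(log(2 * pi * s2) + d^2 / s2)
}

# ML fit for one direction; optimises over (log B, log(E + floor)) so
# positivity needs no constrained solver. Returns B, E, loglik, convergence.
fit_one_direction <- function(d, u, max_iter = 500L) {
  n <- length(d)
  vard <- mean(d^2)
  floor <- 1e-12 * vard
  init <- stats::lm.fit(cbind(1, u), d^2)$coefficients
  B0 <- max(init[[1]], floor); E0 <- max(init[[2]], floor)
  ll0 <- -0.5 * sum(log(2 * pi * (B0 + u * E0)) + d^2 / (B0 + u * E0))
  d2 <- d^2
  negll <- function(theta) {
    B <- exp(theta[1]); E <- exp(theta[2]) - floor
    s2 <- B + u * E
    if (any(s2 <= 0)) return(1e300)
    0.5 * sum(log(s2) + d2 / s2) + 0.5 * n * log(2 * pi)
  }
  grad <- function(theta) {
    B <- exp(theta[1]); E <- exp(theta[2]) - floor
    s2 <- B + u * E
    if (any(s2 <= 0)) return(c(0, 0))
    g_common <- (1 / s2 - d2 / s2^2) * 0.5
    c(sum(g_common) * B, sum(g_common * u) * exp(theta[2]))
  }
  opt <- stats::optim(c(log(B0), log(E0 + floor)), negll, grad,
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e2))
  gnorm <- sqrt(sum(grad(opt$par)^2))
  if (opt$convergence != 0 && gnorm > 1e-4)
    stop("expansion optimiser failed to converge after ", max_iter,
         " iterations; last iterate B = ", signif(exp(opt$par[1]), 4),
         ", E = ", signif(exp(opt$par[2]) - floor, 4),
         ", gradient norm = ", signif(gnorm, 4))
  B <- exp(opt$par[1]); E <- max(exp(opt$par[2]) - floor, 0)
  ll <- -negll(opt$par)
  if (ll < ll0) { # safeguard: never return a fit worse than the MoM start
    B <- B0; E <- E0; ll <- ll0
  }
  list(B = B, E = E, loglik = ll, init = c(B = B0, E = E0))
}

#' Fit the baseline/expansion variance decomposition to one delta set
#'
#' Maximum-likelihood fit of the heteroscedastic model
#' `E[delta_i^2] = B + Y_i^2 * E`, run twice -- once as written and once
#' with `Y` replaced by `1 - Y` (delta-contraction) -- keeping the
#' higher-likelihood direction. The model-implied total delta variance
#' `B + mean(u) * E` (equal to the population `sum(delta^2)/N` when the
#' model is well specified) is split into the fractional baseline
#' `Bf = B / V` and fractional expansion `Ef = mean(u) * E / V`, which
#' sum to 1 exactly;
#' `signed_Ef` carries a negative sign when the best-fitting direction is
#' contraction. Standard errors come from the expected Fisher information
#' at the optimum (see [expansion_se()]), inflated by sqrt(2) when the
#' samples are two pooled timepoints per subject.
#'
#' @param delta a `delta_set` or numeric vector of (mean-zero) deltas.
#' @param age_norm normalised ages.
#' @param paired TRUE when rows are two pooled timepoints per subject.
#' @param se compute standard errors (default TRUE).
#' @param max_iter optimiser iteration cap.
#' @return object of class `expansion_fit` with fields `B`, `E`, `Bf`,
#'   `Ef`, `signed_Ef`, `direction` ("expand"/"contract"), `loglik`,
#'   `loglik_both`, `se_B`, `se_E`, `se_Bf`, `se_Ef`, `ybar2` (mean of u in
#'   the chosen direction), `var_delta`, `n`, `paired`, `feature_id`.
#' @export
fit_expansion <- function(delta, age_norm, paired = FALSE, se = TRUE,
                          max_iter = 500L) {
  feature_id <- if (inherits(delta, "delta_set")) delta$feature_id else "delta"
  d <- if (inherits(delta, "delta_set")) delta$delta else as.numeric(delta)
  if (length(d) != length(age_norm)) stop("length mismatch")
  if (length(d) < 3) stop("need at least 3 samples")
  if (length(unique(age_norm)) < 2)
    stop("expansion not identifiable: all ages identical")
  u_exp <- age_norm^2
  u_con <- (1 - age_norm)^2
  fe <- fit_one_direction(d, u_exp, max_iter)
  fc <- fit_one_direction(d, u_con, max_iter)
  # tie-break within 1e-9 goes to expansion, the empirically dominant case
  contract <- fc$loglik > fe$loglik + 1e-9
  best <- if (contract) fc else fe
  u <- if (contract) u_con else u_exp
  ubar <- mean(u)
  vard <- mean(d^2)
  # fractions are taken of the model-implied total variance B + mean(u)*E,
  # which matches the empirical sum(delta^2)/N when the model is well
  # specified and keeps Bf + Ef = 1 an exact identity
  vmod <- best$B + ubar * best$E
  Bf <- best$B / vmod
  Ef <- ubar * best$E / vmod
  fit <- structure(
    list(B = best$B, E = best$E, Bf = Bf, Ef = Ef,
         signed_Ef = if (contract) -Ef else Ef,
         direction = if (contract) "contract" else "expand",
         loglik = best$loglik,
         loglik_both = c(expand = fe$loglik, contract = fc$loglik),
         se_B = NA_real_, se_E = NA_real_, se_Bf = NA_real_, se_Ef = NA_real_,
         ybar2 = ubar, var_delta = vard, var_model = vmod, n = length(d),
         paired = isTRUE(paired), feature_id = feature_id),
    class = "expansion_fit")
  if (se) fit <- expansion_se(fit, d, age_norm, paired = paired)
  fit
}

#' Fisher-information standard errors for an expansion fit
#'
#' Standard errors for (B, E) from the inverse expected Fisher information
#' of the Gaussian heteroscedastic likelihood evaluated at the estimates,
#' and for (Bf, Ef) by the delta method through the ratio transforms
#' (treating the total delta variance as fixed). When the fit was made on
#' two pooled timepoints per subject (`paired`), all reported SEs are
#' multiplied by sqrt(2) as a conservative adjustment for the within-
#' subject dependence.
#'
#' @param fit an `expansion_fit`.
#' @param delta the deltas the fit was made on.
#' @param age_norm normalised ages.
#' @param paired apply the sqrt(2) pooled-timepoint inflation.
#' @return the fit with `se_B`, `se_E`, `se_Bf`, `se_Ef` filled in.
#' @export
expansion_se <- function(fit, delta, age_norm, paired = fit$paired) {
  stopifnot(inherits(fit, "expansion_fit"))
  d <- if (inherits(delta, "delta_set")) delta$delta else as.numeric(delta)
  u <- if (fit$direction == "contract") (1 - age_norm)^2 else age_norm^2
  s2 <- fit$B + u * fit$E
  info <- 0.5 * rbind(c(sum(1 / s2^2), sum(u / s2^2)),
                      c(sum(u / s2^2), sum(u^2 / s2^2)))
  covm <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(covm) || any(diag(covm) <= 0)) {
    warning("singular Fisher information; standard errors unavailable")
    return(fit)
  }
  infl <- if (isTRUE(paired)) sqrt(2) else 1
  fit$se_B <- sqrt(covm[1, 1]) * infl
  fit$se_E <- sqrt(covm[2, 2]) * infl
  # delta method through Bf = B/V, Ef = ubar*E/V with V treated as fixed
  fit$se_Bf <- fit$se_B / fit$var_model
  fit$se_Ef <- fit$ybar2 * fit$se_E / fit$var_model
  fit$paired <- isTRUE(paired)
  fit
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf("expansion_fit '%s' (%s): B = %.4g (SE %.3g), E = %.4g (SE %.3g)\n",
              x$feature_id, x$direction, x$B, x$se_B, x$E, x$se_E))
  cat(sprintf("  Bf = %.3f (SE %.3g), Ef = %.3f (SE %.3g), signed Ef = %.3f\n",
              x$Bf, x$se_Bf, x$Ef, x$se_Ef, x$signed_Ef))
  cat(sprintf("  loglik = %.4f, n = %d%s\n", x$loglik, x$n,
              if (x$paired) " (paired, SEs sqrt(2)-inflated)" else ""))
  invisible(x)
}

#' Fit the expansion model to every mode of a cohort
#'
#' Convenience wrapper: per-mode deltas via [compute_mode_delta()] followed
#' by [fit_expansion()] for each feature column.
#'
#' @param x a [cohort] or numeric matrix of mode scores.
#' @param age_norm normalised ages (from the cohort when given one).
#' @param paired pooled two-timepoint data (from the cohort when given one).
#' @param ... passed to [compute_mode_delta()].
#' @return list with `fits` (list of `expansion_fit`), `deltas` (list of
#'   `delta_set`), and `table` (one row per mode: B, E, Bf, Ef, signed_Ef,
#'   direction, SEs, loglik).
#' @export
fit_expansion_modes <- function(x, age_norm = NULL, paired = NULL, ...) {
  if (inherits(x, "cohort")) {
    if (is.null(age_norm)) age_norm <- x$age_norm
    if (is.null(paired)) paired <- x$paired
    x <- x$features
  }
  if (is.null(paired)) paired <- FALSE
  deltas <- compute_mode_deltas(x, age_norm, ...)
  fits <- lapply(deltas, fit_expansion, age_norm = age_norm, paired = paired)
  list(fits = fits, deltas = deltas, table = expansion_table(fits))
}

#' Tabulate a list of expansion fits
#'
#' @param fits list of `expansion_fit` objects.
#' @return data.frame, one row per fit.
#' @export
expansion_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(feature_id = f$feature_id, B = f$B, E = f$E, Bf = f$Bf,
               Ef = f$Ef, signed_Ef = f$signed_Ef, direction = f$direction,
               se_B = f$se_B, se_E = f$se_E, se_Bf = f$se_Bf, se_Ef = f$se_Ef,
               loglik = f$loglik, n = f$n, row.names = NULL)))
}
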