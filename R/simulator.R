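#' Default simulation settings matched to the real-data characteristics
#'
#' Returns the configuration used throughout the validation battery:
#' 4,400 subjects with two timepoints 0.05 normalised-age units apart
#' (8,800 rows when simulated), 16 aging modes whose fractional-expansion
#' targets span the range estimated from real data (0.02-0.68), per-mode
#' age correlations from 0.55 down to 0.25, on average 10% of modes set
#' for delta-contraction with a 5-fold strength reduction, measurement
#' noise of 2-8% of each mode's delta variance (the level implied by the
#' real-data cross/longitudinal consistency of the strongest expanding
#' mode at the 0.05 scan interval), and cross-mode baseline/
#' rate correlations calibrated so the mean between-mode-delta correlation
#' is near 0.24 (which together with the age curves yields between-mode
#' score correlations near 0.39).
#'
#' @param n_subjects subjects (each contributes two timepoints).
#' @param n_modes number of aging modes.
#' @param timepoint_interval between-scan interval in normalised age units.
#' @param contraction_fraction expected fraction of contraction modes.
#' @param contraction_attenuation divisor applied to a contraction mode's
#'   fractional expansion target.
#' @param ef_targets per-mode fractional-expansion targets (length
#'   `n_modes`); the default spans the real-data range.
#' @param age_corr_targets per-mode target correlation with age.
#' @param noise_frac_range range of the per-mode measurement-noise
#'   fraction of total delta variance (drawn uniformly per mode).
#' @param delta_corr_target target mean between-mode delta correlation.
#' @param mode_corr_target target mean between-mode score correlation
#'   (emergent from the age curves plus `delta_corr_target`; recorded for
#'   reference).
#' @param curve_quad_ratio ratio of quadratic to linear coefficient in the
#'   population mean aging curves.
#' @param age_range_years age range mapped onto normalised age 0-1.
#' @param n_replicates default replicate count for recovery studies.
#' @return object of class `sim_config` (a list of the above).
#' @export
default_params <- function(n_subjects = 4400L, n_modes = 16L,
                           timepoint_interval = 0.05,
                           contraction_fraction = 0.10,
                           contraction_attenuation = 5,
                           ef_targets = c(0.03, 0.25, 0.19, 0.16, 0.34, 0.16,
                                          0.02, 0.05, 0.68, 0.34, 0.04, 0.16,
                                          0.23, 0.22, 0.22, 0.05),
                           age_corr_targets = seq(0.55, 0.25,
                                                  length.out = n_modes),
                           noise_frac_range = c(0.02, 0.08),
                           delta_corr_target = 0.24,
                           mode_corr_target = 0.39,
                           curve_quad_ratio = 0.5,
                           age_range_years = c(46.1, 80.8),
                           n_replicates = 100L) {
  if (length(ef_targets) != n_modes)
    ef_targets <- rep_len(ef_targets, n_modes)
  if (length(age_corr_targets) != n_modes)
    age_corr_targets <- rep_len(age_corr_targets, n_modes)
  stopifnot(n_subjects > 0, n_modes > 0, timepoint_interval > 0,
            contraction_fraction >= 0, contraction_fraction <= 1,
            all(ef_targets > 0), all(ef_targets < 1),
            all(age_corr_targets > 0), all(age_corr_targets < 1))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_modes = as.integer(n_modes),
                 timepoint_interval = timepoint_interval,
                 contraction_fraction = contraction_fraction,
                 contraction_attenuation = contraction_attenuation,
                 ef_targets = ef_targets,
                 age_corr_targets = age_corr_targets,
                 noise_frac_range = noise_frac_range,
                 delta_corr_target = delta_corr_target,
                 mode_corr_target = mode_corr_target,
                 curve_quad_ratio = curve_quad_ratio,
                 age_range_years = age_range_years,
                 n_replicates = as.integer(n_replicates)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_subjects, "subjects x 2 timepoints,",
      x$n_modes, "modes\n")
  cat("  interval", x$timepoint_interval, "| contraction",
      x$contraction_fraction, "/", x$contraction_attenuation,
      "| Ef targets", sprintf("%.2f-%.2f", min(x$ef_targets),
                              max(x$ef_targets)), "\n")
  invisible(x)
}

# shared-factor loading reproducing the target mean between-mode delta
# correlation, solved from the expected baseline/expansion composition
shared_factor_loading <- function(config) {
  if (config$n_modes < 2 || config$delta_corr_target <= 0) return(0)
  ef <- config$ef_targets
  bbar <- 1 - ef - mean(config$noise_frac_range)
  term <- outer(sqrt(bbar), sqrt(bbar)) + outer(sqrt(ef), sqrt(ef))
  mean_off <- mean(term[upper.tri(term)])
  phi <- config$delta_corr_target / mean_off
  if (phi > 1 || phi < 0)
    stop("requested correlation structure is not positive semi-definite; ",
         "reduce 'delta_corr_target' below ", signif(mean_off, 3),
         " (nearest-PSD repair: cap the shared-factor loading at 1)")
  phi
}

#' Simulate a two-timepoint multi-mode aging cohort
#'
#' Generates mode scores from the generative model
#' `x = x0 + curve(Y) + Y * beta + noise` (with `1 - Y` in place of `Y`
#' for contraction modes): per-subject baselines `x0` and aging rates
#' `beta` are drawn from a one-factor multivariate normal giving
#' positively correlated modes, measurement noise is drawn independently
#' for each timepoint while `x0` and `beta` are shared between timepoints,
#' and each mode's total delta variance is standardised to 1 so the
#' configured fractional-expansion targets are hit exactly in expectation.
#' Setting `truth_corr` > 0 correlates each subject's baseline with their
#' aging rate within every mode (1 = the worst-case scenario for the
#' uncorrelatedness assumption of the expansion model).
#'
#' @param config a [default_params()] configuration.
#' @param truth_corr within-mode correlation between true baseline and
#'   true aging rate, in \[0, 1\].
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return list with `cohort` (a [cohort] of `2 * n_subjects` rows, paired)
#'   and `truth` (class `sim_truth`): matrices `x0`, `beta` (subjects x
#'   modes), per-mode `B_true`, `E_true`, `noise_var`, `ef_true`,
#'   `bf_true`, `signed_ef_true`, `direction_true`, `ybar2`, plus
#'   `contract`, `noise_frac`, `phi`, `curve_scale`, `truth_corr`, `seed`.
#' @export
simulate_cohort <- function(config = default_params(), truth_corr = 0,
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (truth_corr < 0 || truth_corr > 1)
    stop("'truth_corr' must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$n_subjects
  m <- config$n_modes
  iv <- config$timepoint_interval
  y1 <- stats::runif(n, 0, 1 - iv)
  y2 <- y1 + iv
  y <- c(y1, y2)
  # per-mode generative parameters
  noise_frac <- stats::runif(m, config$noise_frac_range[1],
                             config$noise_frac_range[2])
  contract <- stats::runif(m) < config$contraction_fraction
  ef <- config$ef_targets
  ef[contract] <- ef[contract] / config$contraction_attenuation
  umat <- matrix(y^2, 2 * n, m)
  if (any(contract)) umat[, contract] <- (1 - y)^2
  ubar <- colMeans(umat)
  E_par <- ef / ubar
  B_par <- 1 - ef - noise_frac
  # correlated baselines and rates across modes (one shared factor each)
  phi <- shared_factor_loading(config)
  g <- stats::rnorm(n); h <- stats::rnorm(n)
  zx <- sqrt(phi) * g + sqrt(1 - phi) * matrix(stats::rnorm(n * m), n, m)
  zb_raw <- sqrt(phi) * h + sqrt(1 - phi) * matrix(stats::rnorm(n * m), n, m)
  zb <- truth_corr * zx + sqrt(1 - truth_corr^2) * zb_raw
  x0 <- sweep(zx, 2, sqrt(B_par), `*`)
  beta <- sweep(zb, 2, sqrt(E_par), `*`)
  # population mean aging curves scaled to hit the target age correlations
  shape <- y + config$curve_quad_ratio * y^2
  shape <- shape - mean(shape)
  rc2 <- stats::cor(shape, y)^2
  a2 <- config$age_corr_targets^2
  if (any(a2 >= rc2))
    stop("age correlation target exceeds what the mean curve allows")
  curve_scale <- sqrt(a2 / (rc2 - a2) / stats::var(shape))
  curves <- outer(shape, curve_scale)
  # umat holds u = Y^2 (or (1-Y)^2), so sqrt(u) is the rate multiplier
  rate_term <- sqrt(umat) * rbind(beta, beta)
  eps <- matrix(stats::rnorm(2 * n * m), 2 * n, m)
  eps <- sweep(eps, 2, sqrt(noise_frac), `*`)
  x <- rbind(x0, x0) + curves + rate_term + eps
  colnames(x) <- sprintf("mode_%02d", seq_len(m))
  yrs <- config$age_range_years
  coh <- cohort(features = x,
                age_years = yrs[1] + y * diff(yrs),
                subject_id = rep(sprintf("S%05d", seq_len(n)), 2),
                timepoint = rep(1:2, each = n),
                interval_years = rep(iv * diff(yrs), 2 * n),
                paired = TRUE)
  popvar <- function(v) mean((v - mean(v))^2)
  B_true <- apply(x0, 2, popvar)
  E_true <- apply(beta, 2, popvar)
  noise_var <- apply(eps, 2, popvar)
  v_nominal <- B_true + ubar * E_true + noise_var
  ef_true <- ubar * E_true / v_nominal
  # noise is indistinguishable from baseline cross-sectionally, so the true
  # baseline FRACTION counts it (keeping bf + ef = 1); B_true does not
  bf_true <- 1 - ef_true
  truth <- structure(
    list(x0 = x0, beta = beta,
         B_true = B_true, E_true = E_true, noise_var = noise_var,
         ef_true = ef_true, bf_true = bf_true,
         signed_ef_true = ifelse(contract, -ef_true, ef_true),
         direction_true = ifelse(contract, "contract", "expand"),
         ybar2 = ubar, contract = contract, noise_frac = noise_frac,
         phi = phi, curve_scale = curve_scale, truth_corr = truth_corr,
         seed = seed),
    class = "sim_truth")
  list(cohort = coh, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", ncol(x$x0), "modes x", nrow(x$x0), "subjects\n")
  cat("  true Ef:", paste(sprintf("%.2f", x$signed_ef_true), collapse = " "),
      "\n  contraction modes:", sum(x$contract), "\n")
  invisible(x)
}
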