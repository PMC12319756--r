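#' Coefficient of determination between estimates and truth
#'
#' `1 - sum((est - true)^2) / sum((true - mean(true))^2)`. Sensitive to
#' errors in scale and mean (unlike correlation); can be negative.
#'
#' @param est,true numeric vectors of equal length (>= 2).
#' @return scalar CoD.
#' @export
coefficient_of_determination <- function(est, true) {
  if (length(est) != length(true)) stop("length mismatch")
  if (length(true) < 2) stop("need at least 2 values")
  sst <- sum((true - mean(true))^2)
  if (sst == 0) stop("constant truth: CoD undefined")
  1 - sum((est - true)^2) / sst
}

#' Correlations of estimated deltas with ground-truth baseline and rate
#'
#' For each simulated mode, correlates the mode's estimated deltas (across
#' all samples) with that mode's true per-subject baseline `x0` and aging
#' rate `beta`, and correlates the all-in-one delta with every mode's true
#' rate. These quantify how strongly deltas reflect ongoing aging versus
#' fixed baseline differences.
#'
#' @param truth a `sim_truth` from [simulate_cohort()].
#' @param mode_deltas list of per-mode `delta_set` objects on the
#'   simulated (pooled) cohort.
#' @param aio_delta the all-in-one `delta_set`, or NULL to skip.
#' @return data.frame per mode: `delta_vs_x0`, `delta_vs_beta`,
#'   `aio_vs_beta`, `ef_true`.
#' @export
delta_truth_correlations <- function(truth, mode_deltas, aio_delta = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  m <- ncol(truth$beta)
  x0s <- rbind(truth$x0, truth$x0)
  bs <- rbind(truth$beta, truth$beta)
  dvx <- dvb <- avb <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    d <- mode_deltas[[j]]$delta
    dvx[j] <- stats::cor(d, x0s[, j])
    dvb[j] <- stats::cor(d, bs[, j])
    if (!is.null(aio_delta))
      avb[j] <- stats::cor(aio_delta$delta, bs[, j])
  }
  data.frame(mode = seq_len(m), delta_vs_x0 = dvx, delta_vs_beta = dvb,
             aio_vs_beta = avb, ef_true = truth$ef_true)
}

# one simulate -> fit -> compare cycle; the unit every evaluation loops over
run_replicate <- function(config, truth_corr = 0, seed = NULL) {
  sim <- simulate_cohort(config, truth_corr = truth_corr, seed = seed)
  coh <- sim$cohort
  truth <- sim$truth
  em <- fit_expansion_modes(coh)
  aio <- fit_all_in_one(coh)
  tc <- delta_truth_correlations(truth, em$deltas, aio$delta)
  est <- em$table
  modes <- data.frame(
    mode = seq_len(config$n_modes),
    B_est = est$B, E_est = est$E,
    Bf_est = est$Bf, ef_est = est$signed_Ef,
    direction_est = est$direction,
    se_B = est$se_B, se_E = est$se_E, se_Bf = est$se_Bf, se_Ef = est$se_Ef,
    B_true = truth$B_true, E_true = truth$E_true,
    Bf_true = truth$bf_true, ef_true = truth$signed_ef_true,
    direction_true = truth$direction_true,
    delta_vs_x0 = tc$delta_vs_x0, delta_vs_beta = tc$delta_vs_beta,
    aio_vs_beta = tc$aio_vs_beta)
  # achieved between-mode correlations (data characteristics check)
  cx <- stats::cor(coh$features)
  dmat <- vapply(em$deltas, `[[`, numeric(coh$n), "delta")
  cd <- stats::cor(dmat)
  modes$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  list(modes = modes,
       mode_corr_mean = mean(cx[upper.tri(cx)]),
       delta_corr_mean = mean(cd[upper.tri(cd)]),
       aio_age_r = stats::cor(aio$ybrain, coh$age_norm))
}

#' Parameter-recovery battery across simulation replicates
#'
#' Runs the full simulate/fit/compare cycle `n_replicates` times (replicate
#' seeds are `seed + replicate index`), computing per replicate the CoD and
#' Pearson correlation between estimated and true E, B, Ef, and Bf across
#' the modes, the mean theoretical standard errors, and the per-mode
#' delta-versus-truth correlations. Ef comparisons use the signed values
#' (negative under contraction); E and B are compared as the fitted
#' direction reports them.
#'
#' @param config a [default_params()] configuration.
#' @param n_replicates replicate count (default from config).
#' @param seed base seed.
#' @param truth_corr within-mode baseline/rate correlation passed to the
#'   simulator.
#' @return object of class `recovery_report`: `summary` (per-parameter
#'   cod_mean/cod_sd/r_mean/r_sd/se_theory_mean/se_actual_mean),
#'   `delta_truth` (mean and max delta-vs-rate correlations for modes and
#'   the all-in-one model), `per_replicate`, `cells` (every mode x
#'   replicate row), `data_checks` (achieved between-mode and between-delta
#'   correlations), `config`, `seed`.
#' @export
recovery_table <- function(config = default_params(),
                           n_replicates = config$n_replicates,
                           seed = 1L, truth_corr = 0) {
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates))
    reps[[r]] <- run_replicate(config, truth_corr = truth_corr,
                               seed = as.integer(seed) + r)
  cells <- do.call(rbind, lapply(seq_along(reps), function(r)
    cbind(replicate = r, reps[[r]]$modes)))
  per_rep <- do.call(rbind, lapply(seq_along(reps), function(r) {
    md <- reps[[r]]$modes
    data.frame(
      replicate = r,
      cod_E = coefficient_of_determination(md$E_est, md$E_true),
      cod_B = coefficient_of_determination(md$B_est, md$B_true),
      cod_Ef = coefficient_of_determination(md$ef_est, md$ef_true),
      cod_Bf = coefficient_of_determination(md$Bf_est, md$Bf_true),
      r_E = stats::cor(md$E_est, md$E_true),
      r_B = stats::cor(md$B_est, md$B_true),
      r_Ef = stats::cor(md$ef_est, md$ef_true),
      r_Bf = stats::cor(md$Bf_est, md$Bf_true),
      mean_delta_vs_beta = mean(md$delta_vs_beta),
      max_delta_vs_beta = max(md$delta_vs_beta),
      mean_aio_vs_beta = mean(md$aio_vs_beta),
      max_aio_vs_beta = max(md$aio_vs_beta),
      mode_corr_mean = reps[[r]]$mode_corr_mean,
      delta_corr_mean = reps[[r]]$delta_corr_mean,
      aio_age_r = reps[[r]]$aio_age_r)
  }))
  rmse_by_mode <- function(err) {
    tapply(err, cells$mode, function(e) sqrt(mean(e^2)))
  }
  summary <- data.frame(
    parameter = c("E", "B", "Ef", "Bf"),
    cod_mean = c(mean(per_rep$cod_E), mean(per_rep$cod_B),
                 mean(per_rep$cod_Ef), mean(per_rep$cod_Bf)),
    cod_sd = c(stats::sd(per_rep$cod_E), stats::sd(per_rep$cod_B),
               stats::sd(per_rep$cod_Ef), stats::sd(per_rep$cod_Bf)),
    r_mean = c(mean(per_rep$r_E), mean(per_rep$r_B),
               mean(per_rep$r_Ef), mean(per_rep$r_Bf)),
    r_sd = c(stats::sd(per_rep$r_E), stats::sd(per_rep$r_B),
             stats::sd(per_rep$r_Ef), stats::sd(per_rep$r_Bf)),
    se_theory_mean = c(mean(cells$se_E), mean(cells$se_B),
                       mean(cells$se_Ef), mean(cells$se_Bf)),
    se_actual_mean = c(mean(rmse_by_mode(cells$E_est - cells$E_true)),
                       mean(rmse_by_mode(cells$B_est - cells$B_true)),
                       mean(rmse_by_mode(cells$ef_est - cells$ef_true)),
                       mean(rmse_by_mode(cells$Bf_est - cells$Bf_true))))
  delta_truth <- data.frame(
    model = c("modes", "all_in_one"),
    mean_r = c(mean(per_rep$mean_delta_vs_beta), mean(per_rep$mean_aio_vs_beta)),
    max_r = c(mean(per_rep$max_delta_vs_beta), mean(per_rep$max_aio_vs_beta)))
  structure(list(summary = summary, delta_truth = delta_truth,
                 per_replicate = per_rep, cells = cells,
                 data_checks = c(mode_corr = mean(per_rep$mode_corr_mean),
                                 delta_corr = mean(per_rep$delta_corr_mean),
                                 aio_age_r = mean(per_rep$aio_age_r)),
                 config = config, seed = as.integer(seed),
                 truth_corr = truth_corr, n_replicates = n_replicates),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report:", x$n_replicates, "replicates, truth_corr =",
      x$truth_corr, "\n")
  print(transform(x$summary,
                  cod = sprintf("%.2f +/- %.2f", cod_mean, cod_sd),
                  r = sprintf("%.2f +/- %.2f", r_mean, r_sd))[
                    c("parameter", "cod", "r", "se_theory_mean",
                      "se_actual_mean")],
        row.names = FALSE)
  cat("delta vs true aging rate: modes mean",
      sprintf("%.3f", x$delta_truth$mean_r[1]),
      "max", sprintf("%.3f", x$delta_truth$max_r[1]),
      "| all-in-one mean", sprintf("%.3f", x$delta_truth$mean_r[2]),
      "max", sprintf("%.3f", x$delta_truth$max_r[2]), "\n")
  invisible(x)
}

#' Ef/Bf estimation bias under correlated baseline and rate
#'
#' Reruns the recovery battery at each requested within-mode correlation
#' between true baseline and true aging rate (1 is the worst case for the
#' model's uncorrelatedness assumption) and summarises the distribution of
#' the signed fractional-expansion estimation error across all mode x
#' replicate cells: exceedance rates over |bias| 0.15 (all cells) and 0.05
#' (cells with true Ef > 0.4), plus the matching 95th and 99th percentiles.
#'
#' @param config a [default_params()] configuration.
#' @param truth_corr_values correlations to evaluate (default 0 and 1).
#' @param n_replicates replicates per correlation value.
#' @param seed base seed.
#' @return list with `summary` (one row per truth_corr) and `cells`
#'   (per-cell ef_true, ef_bias, bf_bias).
#' @export
bias_under_correlated_truth <- function(config = default_params(),
                                        truth_corr_values = c(0, 1),
                                        n_replicates = config$n_replicates,
                                        seed = 1L) {
  if (any(truth_corr_values < 0 | truth_corr_values > 1))
    stop("'truth_corr_values' must lie in [0, 1]")
  all_cells <- list()
  for (v in truth_corr_values) {
    rep <- recovery_table(config, n_replicates = n_replicates,
                          seed = seed, truth_corr = v)
    cl <- rep$cells
    all_cells[[length(all_cells) + 1L]] <- data.frame(
      truth_corr = v, replicate = cl$replicate, mode = cl$mode,
      ef_true = abs(cl$ef_true),
      ef_bias = cl$ef_est - cl$ef_true,
      bf_bias = cl$Bf_est - cl$Bf_true)
  }
  cells <- do.call(rbind, all_cells)
  summary <- do.call(rbind, lapply(split(cells, cells$truth_corr), function(s) {
    hi <- s$ef_true > 0.4
    data.frame(
      truth_corr = s$truth_corr[1],
      n_cells = nrow(s),
      rate_above_0.15 = mean(abs(s$ef_bias) > 0.15),
      q95_abs_bias = unname(stats::quantile(abs(s$ef_bias), 0.95)),
      n_high_ef = sum(hi),
      rate_high_ef_above_0.05 = if (any(hi)) mean(abs(s$ef_bias[hi]) > 0.05)
                                else NA_real_,
      q99_abs_bias_high_ef = if (any(hi))
        unname(stats::quantile(abs(s$ef_bias[hi]), 0.99)) else NA_real_)
  }))
  rownames(summary) <- NULL
  list(summary = summary, cells = cells)
}
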