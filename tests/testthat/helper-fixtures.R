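# shared fixture builders; all data are generated in code at test time

# population (1/N) variance, matching the zero-mean delta convention
popvar <- function(v) mean((v - mean(v))^2)

# small two-timepoint cohort with a single hand-controlled feature:
# x = curve(Y) + x0 + Y*beta + noise, x0/beta shared between timepoints
toy_paired_cohort <- function(n_subjects = 500, b_sd = 0, e_sd = 0,
                              noise_sd = 0, interval = 0.05, seed = 1,
                              curve = function(y) 2 * y - 0.5 * y^2) {
  set.seed(seed)
  y1 <- runif(n_subjects, 0, 1 - interval)
  y <- c(y1, y1 + interval)
  x0 <- rnorm(n_subjects, 0, b_sd)
  beta <- rnorm(n_subjects, 0, e_sd)
  x <- curve(y) + rep(x0, 2) + y * rep(beta, 2) +
    rnorm(2 * n_subjects, 0, noise_sd)
  cohort(features = matrix(x, ncol = 1, dimnames = list(NULL, "m1")),
         age_years = 46.1 + y * 34.7,
         subject_id = rep(sprintf("s%04d", seq_len(n_subjects)), 2),
         timepoint = rep(1:2, each = n_subjects),
         interval_years = rep(interval * 34.7, 2 * n_subjects),
         paired = TRUE)
}

# tiny simulation settings for fast evaluation-module tests
small_config <- function(n_subjects = 400L, ...) {
  default_params(n_subjects = n_subjects, n_modes = 6L,
                 ef_targets = c(0.05, 0.15, 0.25, 0.4, 0.55, 0.68),
                 age_corr_targets = seq(0.5, 0.3, length.out = 6),
                 n_replicates = 2L, ...)
}
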