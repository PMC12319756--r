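#' Pool two-timepoint data into one cross-sectional cohort
#'
#' Keeps subjects with exactly two timepoints and stacks their samples as
#' independent rows (so an N-subject paired dataset yields 2N rows),
#' ensuring the cross-sectional fits are not biased towards either
#' timepoint. Subjects with one or more than two timepoints are excluded
#' with a message. The returned cohort carries `paired = TRUE` so
#' downstream standard errors are sqrt(2)-inflated.
#'
#' @param x a [cohort] with `subject_id` and `timepoint` set.
#' @return a [cohort] restricted to complete pairs, with ages renormalised
#'   over the retained rows.
#' @export
pool_timepoints <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$subject_id) || is.null(x$timepoint))
    stop("cohort has no subject/timepoint pairing")
  tab <- table(x$subject_id)
  complete <- names(tab)[tab == 2L]
  dropped <- setdiff(names(tab), complete)
  if (length(dropped))
    message("excluding ", length(dropped),
            " subject(s) without exactly two timepoints")
  if (!length(complete)) stop("no subjects with two timepoints")
  keep <- x$subject_id %in% complete
  cohort(features = x$features[keep, , drop = FALSE],
         age_years = x$age_years[keep],
         subject_id = x$subject_id[keep],
         timepoint = x$timepoint[keep],
         interval_years = x$interval_years[keep],
         confounds = if (!is.null(x$confounds))
           x$confounds[keep, , drop = FALSE] else NULL,
         paired = TRUE)
}

#' Split pooled deltas into cross-sectional and longitudinal parts
#'
#' For each subject with two timepoints, forms the cross-sectional delta
#' `delta_cross = (delta_t1 + delta_t2) / 2` and the longitudinal rate
#' `delta_long = (delta_t2 - delta_t1) / interval_years`, and quantifies
#' their consistency with the Pearson correlation `rxl` across subjects.
#' Correlating against the two-timepoint average (not a single timepoint)
#' is essential: a single timepoint's measurement noise enters both sides
#' and induces a spurious correlation.
#'
#' @param delta a `delta_set` computed on the pooled cohort.
#' @param x the pooled [cohort] (subject_id, timepoint, interval_years).
#' @return object of class `longitudinal_summary`: `mode_id`, `table`
#'   (per-subject subject_id, delta_cross, delta_long, interval_years),
#'   `rxl`, `p_value`, `n_subjects`.
#' @export
cross_long_split <- function(delta, x) {
  stopifnot(inherits(x, "cohort"))
  d <- if (inherits(delta, "delta_set")) delta$delta else as.numeric(delta)
  mode_id <- if (inherits(delta, "delta_set")) delta$feature_id else "delta"
  if (length(d) != x$n) stop("delta length does not match cohort")
  if (is.null(x$subject_id) || is.null(x$timepoint))
    stop("cohort has no subject/timepoint pairing")
  if (is.null(x$interval_years)) stop("cohort has no scan intervals")
  i1 <- x$timepoint == 1L
  i2 <- x$timepoint == 2L
  s1 <- x$subject_id[i1]
  m2 <- match(s1, x$subject_id[i2])
  if (anyNA(m2)) stop("unpaired subjects present; run pool_timepoints() first")
  d1 <- d[i1]
  d2 <- d[i2][m2]
  iv <- x$interval_years[i1]
  bad <- !is.finite(iv) | iv <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " subject(s) with non-positive interval")
    d1 <- d1[!bad]; d2 <- d2[!bad]; iv <- iv[!bad]; s1 <- s1[!bad]
  }
  dc <- (d1 + d2) / 2
  dl <- (d2 - d1) / iv
  ct <- stats::cor.test(dc, dl)
  structure(list(mode_id = mode_id,
                 table = data.frame(subject_id = s1, delta_cross = dc,
                                    delta_long = dl, interval_years = iv),
                 rxl = unname(ct$estimate), p_value = ct$p.value,
                 n_subjects = length(dc)),
            class = "longitudinal_summary")
}

#' @export
print.longitudinal_summary <- function(x, ...) {
  cat(sprintf("longitudinal_summary '%s': rxl = %.3f (p = %.3g, n = %d)\n",
              x$mode_id, x$rxl, x$p_value, x$n_subjects))
  invisible(x)
}

#' Benjamini-Hochberg significance flags across modes
#'
#' @param p_values per-mode two-sided p-values.
#' @param q FDR level (default 0.05).
#' @return logical vector of significance flags.
#' @export
fdr_across_modes <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("need at least one p-value")
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Correlation between expansion fraction and cross/long consistency
#'
#' Across modes, correlates the signed fractional expansion with the
#' cross-sectional/longitudinal consistency `rxl`; strong positive values
#' indicate that modes flagged as expanding really do change over time.
#'
#' @param summaries list of `longitudinal_summary` objects, or a numeric
#'   vector of rxl values.
#' @param fits list of `expansion_fit` objects, or a numeric vector of
#'   signed Ef values.
#' @return Pearson correlation (scalar).
#' @export
rxl_vs_ef <- function(summaries, fits) {
  rxl <- if (is.numeric(summaries)) summaries
         else vapply(summaries, `[[`, numeric(1), "rxl")
  ef <- if (is.numeric(fits)) fits
        else vapply(fits, `[[`, numeric(1), "signed_Ef")
  if (length(rxl) != length(ef)) stop("length mismatch")
  if (length(rxl) < 3) stop("need at least 3 modes")
  stats::cor(ef, rxl)
}

#' Longitudinal consistency table for all modes
#'
#' Runs [cross_long_split()] on each delta set and applies the
#' across-mode FDR correction.
#'
#' @param deltas list of `delta_set` objects on the pooled cohort.
#' @param x the pooled [cohort].
#' @param q FDR level.
#' @return data.frame: mode_id, rxl, p_value, fdr_significant, n_subjects.
#' @export
longitudinal_table <- function(deltas, x, q = 0.05) {
  sums <- lapply(deltas, cross_long_split, x = x)
  out <- data.frame(
    mode_id = vapply(sums, `[[`, character(1), "mode_id"),
    rxl = vapply(sums, `[[`, numeric(1), "rxl"),
    p_value = vapply(sums, `[[`, numeric(1), "p_value"),
    n_subjects = vapply(sums, `[[`, numeric(1), "n_subjects"),
    row.names = NULL)
  out$fdr_significant <- fdr_across_modes(out$p_value, q = q)
  out
}
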