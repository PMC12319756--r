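#' Construct a cohort object
#'
#' A cohort bundles a samples x features matrix of imaging-derived
#' phenotypes (IDPs) or pre-extracted mode scores with per-sample age and
#' optional pairing information for two-timepoint data. Ages are stored
#' both in years and min-max normalised to \[0, 1\] (the convention used by
#' all model fitting in this package); the affine transform is kept so
#' all-in-one deltas can be reported back in years.
#'
#' @param features numeric matrix (samples x features); missing values
#'   allowed. A data.frame of numeric columns is accepted and converted.
#' @param age_years numeric vector of ages in years, one per row.
#' @param subject_id optional per-sample subject labels.
#' @param timepoint optional per-sample timepoint labels in `{1, 2}`.
#' @param interval_years optional per-sample between-scan interval (years);
#'   constant within subject.
#' @param confounds optional numeric matrix of per-sample confounds.
#' @param paired logical; TRUE when rows are two pooled timepoints per
#'   subject (downstream standard errors are then inflated by sqrt(2)).
#' @return An object of class `cohort`: a list with elements `features`,
#'   `age_years`, `age_norm`, `age_transform`, `subject_id`, `timepoint`,
#'   `interval_years`, `confounds`, `paired`, `n`.
#' @export
cohort <- function(features, age_years, subject_id = NULL, timepoint = NULL,
                   interval_years = NULL, confounds = NULL, paired = FALSE) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features))
    stop("'features' must be a numeric matrix")
  n <- nrow(features)
  age_years <- as.numeric(age_years)
  if (length(age_years) != n)
    stop("feature matrix has ", n, " rows but 'age_years' has length ",
         length(age_years))
  if (anyNA(age_years) || any(!is.finite(age_years)))
    stop("non-finite values in 'age_years'")
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("feature_%02d", seq_len(ncol(features)))
  age_norm <- normalize_age(age_years)
  if (!is.null(timepoint)) {
    timepoint <- as.integer(timepoint)
    if (is.null(subject_id))
      stop("'timepoint' requires 'subject_id'")
    if (!all(timepoint %in% c(1L, 2L)))
      stop("'timepoint' labels must be 1 or 2")
    if (anyDuplicated(paste(subject_id, timepoint)))
      stop("a subject appears more than once per timepoint")
  }
  if (!is.null(confounds)) {
    if (is.data.frame(confounds)) confounds <- as.matrix(confounds)
    if (nrow(confounds) != n)
      stop("'confounds' row count does not match feature matrix")
  }
  structure(
    list(features = features,
         age_years = age_years,
         age_norm = as.numeric(age_norm),
         age_transform = attr(age_norm, "transform"),
         subject_id = subject_id,
         timepoint = timepoint,
         interval_years = interval_years,
         confounds = confounds,
         paired = isTRUE(paired),
         n = n),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", x$n, "samples x", ncol(x$features), "features\n")
  cat("  age range:", sprintf("%.1f-%.1f y", min(x$age_years), max(x$age_years)),
      if (x$paired) " (two pooled timepoints per subject)\n" else "\n")
  if (!is.null(x$subject_id))
    cat("  subjects:", length(unique(x$subject_id)), "\n")
  invisible(x)
}

#' Min-max normalise ages to the unit interval
#'
#' Rescales ages affinely so the youngest sample maps to 0 and the oldest
#' to 1. The transform `(offset, scale)` with
#' `age_norm = (age_years - offset) / scale` is attached as an attribute
#' so normalised quantities can be mapped back to years.
#'
#' @param age_years numeric vector with at least two distinct values.
#' @return numeric vector in \[0, 1\] with attribute `transform`
#'   (`c(offset, scale)`).
#' @export
normalize_age <- function(age_years) {
  age_years <- as.numeric(age_years)
  if (length(age_years) < 2L) stop("need at least two ages")
  if (anyNA(age_years) || any(!is.finite(age_years)))
    stop("non-finite values in 'age_years'")
  rng <- range(age_years)
  if (diff(rng) <= 0) stop("degenerate age range: all ages identical")
  out <- (age_years - rng[1]) / diff(rng)
  attr(out, "transform") <- c(offset = rng[1], scale = diff(rng))
  out
}

#' Read a cohort from a delimited text file
#'
#' Expects a header row. Column roles are identified by name:
#' `age_col` (required), optional `subject_col`, `timepoint_col`,
#' `interval_col`, columns starting with `confound_prefix` as confounds,
#' and all remaining numeric columns as features (or an explicit
#' `feature_cols` selection). Empty cells and "NA" are read as missing.
#'
#' @param path file path (TSV by default; `sep` passes through).
#' @param age_col,subject_col,timepoint_col,interval_col column names.
#' @param feature_cols optional character vector of feature column names.
#' @param confound_prefix prefix marking confound columns.
#' @param sep field separator.
#' @return a [cohort].
#' @export
read_cohort <- function(path, age_col = "age_years", subject_col = "subject_id",
                        timepoint_col = "timepoint", interval_col = "interval_years",
                        feature_cols = NULL, confound_prefix = "confound_",
                        sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("", "NA"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!age_col %in% names(df))
    stop("required column '", age_col, "' not found in ", path)
  reserved <- c(age_col, subject_col, timepoint_col, interval_col)
  conf_cols <- grep(paste0("^", confound_prefix), names(df), value = TRUE)
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(df), c(reserved, conf_cols))
  missing_feat <- setdiff(feature_cols, names(df))
  if (length(missing_feat))
    stop("feature columns not found: ", paste(missing_feat, collapse = ", "))
  feat <- as.matrix(df[feature_cols])
  if (!is.numeric(feat))
    stop("non-numeric values in feature columns of ", path)
  cohort(
    features = feat,
    age_years = df[[age_col]],
    subject_id = if (subject_col %in% names(df)) df[[subject_col]] else NULL,
    timepoint = if (timepoint_col %in% names(df)) df[[timepoint_col]] else NULL,
    interval_years = if (interval_col %in% names(df)) df[[interval_col]] else NULL,
    confounds = if (length(conf_cols)) as.matrix(df[conf_cols]) else NULL)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]; row order and missing cells are preserved.
#'
#' @param x a [cohort].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "cohort"))
  df <- data.frame(row.names = seq_len(x$n))
  if (!is.null(x$subject_id)) df$subject_id <- x$subject_id
  if (!is.null(x$timepoint)) df$timepoint <- x$timepoint
  df$age_years <- x$age_years
  if (!is.null(x$interval_years)) df$interval_years <- x$interval_years
  if (!is.null(x$confounds)) {
    conf <- as.data.frame(x$confounds)
    names(conf) <- if (is.null(colnames(x$confounds)))
      sprintf("confound_%02d", seq_len(ncol(conf))) else colnames(x$confounds)
    df <- cbind(df, conf)
  }
  df <- cbind(df, as.data.frame(x$features))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
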