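#' Orthogonalise a delta vector with respect to age
#'
#' Regresses normalised age (with intercept) out of an initial delta,
#' removing the underfitting-induced age bias so that the returned delta
#' has exactly zero mean and zero correlation with age. The operation is
#' idempotent.
#'
#' @param delta numeric vector of initial deltas.
#' @param age_norm normalised age vector of the same length.
#' @return numeric vector of age-orthogonalised deltas.
#' @export
orthogonalize_age <- function(delta, age_norm) {
  if (length(delta) != length(age_norm))
    stop("length mismatch between delta and age")
  fit <- stats::lm.fit(cbind(1, age_norm), delta)
  as.numeric(fit$residuals)
}

new_delta_set <- function(delta, feature_id, is_all_in_one = FALSE,
                          delta_years = NULL) {
  structure(list(feature_id = feature_id,
                 delta = as.numeric(delta),
                 is_all_in_one = isTRUE(is_all_in_one),
                 delta_years = delta_years),
            class = "delta_set")
}

#' @export
print.delta_set <- function(x, ...) {
  cat("delta_set '", x$feature_id, "': n = ", length(x$delta),
      ", sd = ", signif(stats::sd(x$delta), 4),
      if (x$is_all_in_one) " (all-in-one)" else "", "\n", sep = "")
  invisible(x)
}

#' Fit the all-in-one brain age model
#'
#' Regresses normalised age on all features jointly via the pseudoinverse
#' (least squares), giving a predicted "brain age" per sample, then forms
#' the brain age delta as predicted minus true age, orthogonalised against
#' age to remove the regression-dilution bias. An intercept column is
#' included so feature offsets do not leak into the prediction.
#'
#' @param x a [cohort] (all feature columns are used) or a numeric matrix.
#' @param age_norm normalised ages; taken from the cohort when `x` is one.
#' @param age_transform optional `c(offset, scale)` transform used to also
#'   report deltas in years.
#' @return list with elements `model` (class `all_in_one_model`: `alpha`
#'   coefficients incl. intercept, `fitted_on` feature names), `ybrain`
#'   (predicted normalised age), and `delta` (a `delta_set`; `delta_years`
#'   holds the same deltas in years when the transform is known).
#' @export
fit_all_in_one <- function(x, age_norm = NULL, age_transform = NULL) {
  if (inherits(x, "cohort")) {
    age_norm <- x$age_norm
    age_transform <- x$age_transform
    x <- x$features
  }
  if (is.null(age_norm)) stop("'age_norm' required when 'x' is a matrix")
  if (!all(is.finite(x))) {
    bad <- colnames(x)[colSums(!is.finite(x)) > 0]
    stop("non-finite entries in features: ", paste(bad, collapse = ", "))
  }
  n <- nrow(x); p <- ncol(x)
  if (p < 1) stop("need at least one feature")
  if (n <= p)
    warning("fewer samples (", n, ") than features + 1 (", p + 1,
            "); pseudoinverse fit proceeds but is underdetermined")
  xa <- cbind(`(intercept)` = 1, x)
  sv <- svd(xa)
  tol <- max(dim(xa)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (sum(pos) < ncol(xa))
    warning("rank-deficient feature matrix (rank ", sum(pos), " of ",
            ncol(xa), "); minimum-norm pseudoinverse solution used")
  alpha <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], age_norm)) / sv$d[pos])
  alpha <- as.numeric(alpha)
  names(alpha) <- colnames(xa)
  ybrain <- as.numeric(xa %*% alpha)
  delta <- orthogonalize_age(ybrain - age_norm, age_norm)
  delta_years <- if (!is.null(age_transform)) delta * age_transform[["scale"]]
  list(model = structure(list(alpha = alpha, fitted_on = colnames(x)),
                         class = "all_in_one_model"),
       ybrain = ybrain,
       delta = new_delta_set(delta, "all_in_one", is_all_in_one = TRUE,
                             delta_years = delta_years))
}

#' Fit the population mean aging curve of one feature
#'
#' Least-squares polynomial (default quadratic) fit of a feature on
#' normalised age, capturing the population-average age dependence that is
#' subtracted before variance decomposition.
#'
#' @param feature numeric vector of per-sample values (NA allowed; fit uses
#'   observed samples).
#' @param age_norm normalised ages.
#' @param order polynomial order (>= 1; default 2).
#' @return object of class `age_curve` with `coefficients` (intercept
#'   first) and `order`.
#' @export
fit_mean_curve <- function(feature, age_norm, order = 2L) {
  if (length(feature) != length(age_norm)) stop("length mismatch")
  if (order < 1) stop("'order' must be >= 1")
  ok <- is.finite(feature) & is.finite(age_norm)
  if (length(unique(age_norm[ok])) < order + 1)
    stop("need at least order + 1 distinct ages")
  basis <- stats::poly(age_norm[ok], degree = order, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, basis), feature[ok])
  if (fit$rank < order + 1) stop("rank-deficient mean-curve design")
  cf <- as.numeric(fit$coefficients)
  names(cf) <- c("intercept", paste0("age^", seq_len(order)))
  structure(list(coefficients = cf, order = as.integer(order)),
            class = "age_curve")
}

#' @export
predict.age_curve <- function(object, age_norm, ...) {
  basis <- cbind(1, stats::poly(age_norm, degree = object$order, raw = TRUE))
  as.numeric(basis %*% object$coefficients)
}

#' @export
print.age_curve <- function(x, ...) {
  cat("age_curve (order ", x$order, "): ",
      paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-mode delta: subtract the mean aging curve and de-bias
#'
#' Computes `delta_i = x_i - curve(Y_i)` for one feature or mode score,
#' then (by default) orthogonalises the result against age, so every
#' returned delta has zero mean and zero age correlation. When `curve` is
#' NULL the quadratic mean curve is fitted to the feature itself first.
#'
#' @param feature numeric vector of per-sample values.
#' @param age_norm normalised ages.
#' @param curve an [age_curve][fit_mean_curve]; fitted on the fly if NULL.
#' @param orthogonalize orthogonalise against age after curve subtraction
#'   (default TRUE; set FALSE for the raw Eq.-style residual).
#' @param order curve order when fitting on the fly.
#' @param feature_id label stored in the result.
#' @return a `delta_set`.
#' @export
compute_mode_delta <- function(feature, age_norm, curve = NULL,
                               orthogonalize = TRUE, order = 2L,
                               feature_id = "mode") {
  if (length(feature) != length(age_norm))
    stop("length mismatch between feature and age")
  if (is.null(curve)) curve <- fit_mean_curve(feature, age_norm, order = order)
  stopifnot(inherits(curve, "age_curve"))
  delta <- feature - predict(curve, age_norm)
  if (orthogonalize) delta <- orthogonalize_age(delta, age_norm)
  new_delta_set(delta, feature_id)
}

#' Per-mode deltas for every column of a cohort
#'
#' Applies [compute_mode_delta()] to each feature column.
#'
#' @param x a [cohort] or numeric matrix.
#' @param age_norm normalised ages (taken from the cohort when given one).
#' @param ... passed to [compute_mode_delta()].
#' @return named list of `delta_set` objects, one per column.
#' @export
compute_mode_deltas <- function(x, age_norm = NULL, ...) {
  if (inherits(x, "cohort")) {
    age_norm <- x$age_norm
    x <- x$features
  }
  out <- lapply(seq_len(ncol(x)), function(j)
    compute_mode_delta(x[, j], age_norm, feature_id = colnames(x)[j], ...))
  names(out) <- colnames(x)
  out
}
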