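#' Median/MAD outlier removal for one feature
#'
#' Marks values missing when their absolute deviation from the median
#' exceeds `thresh` times the (unscaled) median absolute deviation from
#' the median. A zero MAD with deviations present would flag almost
#' everything, so such features are left untouched and reported via a
#' message for review.
#'
#' @param feature numeric vector (NA allowed).
#' @param thresh threshold in MAD units (default 5).
#' @return the vector with outliers set to NA.
#' @export
remove_outliers <- function(feature, thresh = 5) {
  ok <- is.finite(feature)
  if (sum(ok) < 3) stop("need at least 3 non-missing values")
  med <- stats::median(feature[ok])
  madv <- stats::median(abs(feature[ok] - med))
  if (madv == 0) {
    if (any(abs(feature[ok] - med) > 0))
      message("zero MAD with deviations present; feature left unfiltered")
    return(feature)
  }
  feature[ok & abs(feature - med) > thresh * madv] <- NA
  feature
}

#' Regress confounds out of every feature column
#'
#' Each feature is replaced by its residual from an OLS fit on the
#' confounds plus an intercept, fitted on that feature's observed rows so
#' missing cells are preserved. Collinear confound columns are dropped
#' with a warning.
#'
#' @param x numeric matrix (samples x features), NA allowed.
#' @param confounds numeric matrix (samples x k).
#' @return residualised matrix of the same shape.
#' @export
regress_confounds <- function(x, confounds) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.data.frame(confounds)) confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(x)) stop("row count mismatch")
  design <- cbind(1, confounds)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    dropped <- setdiff(seq_len(ncol(design)), keep)
    warning("dropping ", length(dropped),
            " collinear confound column(s): ",
            paste(dropped - 1L, collapse = ", "))
    design <- design[, keep, drop = FALSE]
  }
  out <- x
  for (j in seq_len(ncol(x))) {
    ok <- is.finite(x[, j]) & rowSums(!is.finite(design)) == 0
    if (sum(ok) <= ncol(design)) next
    fit <- stats::lm.fit(design[ok, , drop = FALSE], x[ok, j])
    out[ok, j] <- fit$residuals
  }
  out
}

#' Rescale features by their squared age correlation
#'
#' Multiplies each column by the square of its Pearson correlation with
#' age (computed on observed entries), focusing a subsequent SVD on
#' age-related population variation. Zero-variance columns get weight 0.
#'
#' @param x numeric matrix, NA allowed.
#' @param age_norm normalised ages.
#' @return the rescaled matrix, with the per-column weights attached as
#'   attribute `weights`.
#' @export
age_weighting <- function(x, age_norm) {
  if (length(unique(age_norm)) < 2) stop("degenerate age vector")
  w <- vapply(seq_len(ncol(x)), function(j) {
    ok <- is.finite(x[, j])
    if (sum(ok) < 3 || stats::sd(x[ok, j]) == 0) return(0)
    stats::cor(x[ok, j], age_norm[ok])^2
  }, numeric(1))
  names(w) <- colnames(x)
  out <- sweep(x, 2, w, `*`)
  attr(out, "weights") <- w
  out
}

#' Low-rank SVD completion with soft eigenvalue shrinkage
#'
#' Iterative SVD-based imputation: missing cells start at column means,
#' then the matrix is repeatedly decomposed, its leading `rank` singular
#' values soft-thresholded (the remainder zeroed), and the low-rank
#' reconstruction written back into the missing cells only, until the
#' imputed values stabilise. The default shrinkage
#' level is the median singular value of the tail beyond the requested
#' rank (scale-free, mild); `lambda = 0` gives hard-rank iterative
#' imputation.
#'
#' @param x numeric matrix with (possibly) missing cells.
#' @param rank target rank of the completed representation.
#' @param lambda soft-threshold for singular values; NULL for the default.
#' @param tol relative-change convergence tolerance on imputed cells.
#' @param max_iter iteration cap (a warning is raised if reached).
#' @param max_missing maximum allowed missing fraction per column.
#' @return list with `completed` (matrix), `basis` (rank x features
#'   right-singular-vector basis of the completed matrix), `d` (its
#'   leading singular values), `iterations`, `converged`.
#' @export
svd_soft_impute <- function(x, rank, lambda = NULL, tol = 1e-6,
                            max_iter = 200L, max_missing = 0.02) {
  if (is.data.frame(x)) x <- as.matrix(x)
  rank <- as.integer(rank)
  if (rank < 1 || rank > min(dim(x))) stop("invalid rank")
  miss <- !is.finite(x)
  frac <- colMeans(miss)
  if (any(frac > max_missing))
    stop(sum(frac > max_missing), " column(s) exceed the ", max_missing * 100,
         "% missing-data bound")
  if (!any(miss)) {
    sv <- svd(x, nu = 0, nv = rank)
    return(list(completed = x, basis = t(sv$v), d = sv$d[seq_len(rank)],
                iterations = 0L, converged = TRUE))
  }
  xc <- x
  cm <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(miss) > 0)) xc[miss[, j], j] <- cm[j]
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    sv <- svd(xc)
    lam <- if (is.null(lambda)) {
      tail_d <- sv$d[-seq_len(min(rank, length(sv$d)))]
      if (length(tail_d)) stats::median(tail_d) else 0
    } else lambda
    dshr <- pmax(sv$d - lam, 0)
    if (length(dshr) > rank) dshr[-seq_len(rank)] <- 0  # rank-restricted
    recon <- sv$u %*% (dshr * t(sv$v))
    old <- xc[miss]
    xc[miss] <- recon[miss]
    rel <- sqrt(sum((xc[miss] - old)^2)) / max(sqrt(sum(old^2)), 1e-300)
    if (rel < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning("SVD imputation did not converge in ", max_iter,
            " iterations; returning last iterate")
  sv <- svd(xc, nu = 0, nv = rank)
  list(completed = xc, basis = t(sv$v), d = sv$d[seq_len(rank)],
       iterations = it, converged = converged)
}

# logistic/log-cosh contrast derivatives used by FastICA
.ica_g <- function(u) tanh(u)
.ica_dg <- function(u) 1 - tanh(u)^2

#' FastICA unmixing (deflation, log-cosh contrast)
#'
#' Minimal FastICA: rows of `x` are channels, columns are observations.
#' Rows are centred and whitened, then components are extracted one at a
#' time by fixed-point iteration with Gram-Schmidt deflation. Restarts
#' with fresh random initialisation are attempted on non-convergence.
#'
#' @param x numeric matrix (channels x observations).
#' @param n_comp number of components (default all channels).
#' @param tol convergence tolerance on the unmixing vectors.
#' @param max_iter fixed-point iteration cap per component.
#' @param restarts random restarts before giving up.
#' @param seed integer seed controlling the random initialisations.
#' @return list with `sources` (n_comp x observations), `unmixing` (in the
#'   whitened space), `whitening`, `seeds_tried`.
#' @export
fast_ica <- function(x, n_comp = nrow(x), tol = 1e-6, max_iter = 500L,
                     restarts = 5L, seed = 1L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  n_comp <- as.integer(n_comp)
  p <- ncol(x)
  xc <- x - rowMeans(x)
  cv <- tcrossprod(xc) / p
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (sum(pos) < n_comp)
    stop("input matrix rank (", sum(pos), ") below requested components")
  K <- diag(1 / sqrt(eg$values[pos]), sum(pos)) %*% t(eg$vectors[, pos, drop = FALSE])
  z <- K %*% xc  # whitened: cov = I
  seeds_tried <- integer(0)
  for (r in seq_len(restarts)) {
    s <- as.integer(seed) + (r - 1L) * 1000L
    seeds_tried <- c(seeds_tried, s)
    set.seed(s)
    W <- matrix(0, n_comp, nrow(z))
    failed <- FALSE
    for (k in seq_len(n_comp)) {
      w <- stats::rnorm(nrow(z))
      w <- w / sqrt(sum(w^2))
      ok <- FALSE
      for (i in seq_len(max_iter)) {
        wz <- drop(w %*% z)
        w_new <- z %*% .ica_g(wz) / p - mean(.ica_dg(wz)) * w
        if (k > 1) {
          prev <- W[seq_len(k - 1), , drop = FALSE]
          w_new <- w_new - t(prev) %*% (prev %*% w_new)
        }
        w_new <- w_new / sqrt(sum(w_new^2))
        conv <- abs(abs(sum(w_new * w)) - 1)
        w <- drop(w_new)
        if (conv < tol) { ok <- TRUE; break }
      }
      if (!ok) { failed <- TRUE; break }
      W[k, ] <- w
    }
    if (!failed)
      return(list(sources = W %*% z, unmixing = W, whitening = K,
                  seeds_tried = seeds_tried))
  }
  stop("FastICA failed to converge after ", restarts,
       " restarts (seeds tried: ", paste(seeds_tried, collapse = ", "), ")")
}

#' ICA modes from an SVD row-space basis
#'
#' Feeds the feature-direction (right singular vector) basis into FastICA
#' to find independent sources in the feature direction, then projects the
#' data onto the ICA mixing structure to obtain per-sample mode scores.
#' Each mode is sign-flipped so its subject weights correlate positively
#' with age, and modes are sorted by decreasing age correlation.
#'
#' @param basis rank x features row-space basis (e.g. from
#'   [svd_soft_impute()]).
#' @param data samples x features matrix the basis was derived from (the
#'   age-weighted, confound-cleaned matrix).
#' @param age_norm normalised ages for the sign/sort conventions.
#' @param n_modes number of modes (default the basis rank).
#' @param seed seed for the ICA restarts.
#' @param feature_weights optional per-feature scaling used before the
#'   SVD (stored for reporting).
#' @return object of class `mode_decomposition`: `n_modes`, `idp_weights`
#'   (modes x features), `subject_weights` (samples x modes), `age_corr`,
#'   `feature_scaling`.
#' @export
ica_modes <- function(basis, data, age_norm, n_modes = nrow(basis),
                      seed = 1L, feature_weights = NULL) {
  ica <- fast_ica(basis, n_comp = n_modes, seed = seed)
  src <- ica$sources                      # n_modes x features
  # subject weights: project the decomposed matrix onto the sources
  # (equivalently U * D * A, the ICA mixing matrix mapped back to samples)
  sw <- data %*% t(src) %*% solve(tcrossprod(src))
  ac <- as.numeric(stats::cor(sw, age_norm))
  flip <- ifelse(ac < 0, -1, 1)
  sw <- sweep(sw, 2, flip, `*`)
  src <- sweep(src, 1, flip, `*`)
  ac <- abs(ac)
  ord <- order(ac, decreasing = TRUE)
  sw <- sw[, ord, drop = FALSE]
  src <- src[ord, , drop = FALSE]
  ac <- ac[ord]
  if (qr(sw)$rank < n_modes)
    warning("subject-weight matrix is rank deficient")
  colnames(sw) <- rownames(src) <- sprintf("mode_%02d", seq_len(n_modes))
  structure(list(n_modes = as.integer(n_modes), idp_weights = src,
                 subject_weights = sw, age_corr = ac,
                 feature_scaling = feature_weights),
            class = "mode_decomposition")
}

#' @export
print.mode_decomposition <- function(x, ...) {
  cat("mode_decomposition:", x$n_modes, "modes x", ncol(x$idp_weights),
      "features\n  age correlations:",
      paste(sprintf("%.2f", x$age_corr), collapse = " "), "\n")
  invisible(x)
}

#' Full mode-extraction pipeline
#'
#' Turns a raw IDP matrix into a small set of brain-aging modes:
#' per-feature median/MAD outlier removal, confound regression, age-r2
#' feature weighting, SVD with soft-shrinkage imputation of missing cells,
#' and FastICA in the feature direction, with the sign/sort conventions of
#' [ica_modes()]. Quantile normalisation is deliberately not applied by
#' default (it can skew longitudinal delta estimation); set
#' `quantile_normalize = TRUE` to force it.
#'
#' @param x a [cohort] (confounds, ages taken from it) or numeric matrix.
#' @param n_modes number of modes to extract (default 16).
#' @param age_norm,confounds used when `x` is a matrix.
#' @param seed ICA seed.
#' @param outlier_thresh MAD threshold (default 5).
#' @param quantile_normalize rank-based inverse-normal transform each
#'   feature before analysis (off by default).
#' @param ... passed to [svd_soft_impute()].
#' @return a `mode_decomposition` (see [ica_modes()]); the cleaned,
#'   completed matrix is attached as attribute `completed`.
#' @export
extract_modes <- function(x, n_modes = 16L, age_norm = NULL, confounds = NULL,
                          seed = 1L, outlier_thresh = 5,
                          quantile_normalize = FALSE, ...) {
  if (inherits(x, "cohort")) {
    age_norm <- x$age_norm
    if (is.null(confounds)) confounds <- x$confounds
    x <- x$features
  }
  if (is.null(age_norm)) stop("'age_norm' required when 'x' is a matrix")
  x <- apply(x, 2, remove_outliers, thresh = outlier_thresh)
  if (quantile_normalize)
    x <- apply(x, 2, function(v) {
      ok <- is.finite(v)
      v[ok] <- stats::qnorm((rank(v[ok]) - 0.5) / sum(ok))
      v
    })
  if (!is.null(confounds)) x <- regress_confounds(x, confounds)
  xw <- age_weighting(x, age_norm)
  w <- attr(xw, "weights")
  keep <- w > 0
  imp <- svd_soft_impute(xw[, keep, drop = FALSE], rank = n_modes, ...)
  dec <- ica_modes(imp$basis, imp$completed, age_norm, n_modes = n_modes,
                   seed = seed, feature_weights = w[keep])
  # map idp weights back over any dropped zero-weight columns
  if (!all(keep)) {
    full <- matrix(0, n_modes, length(w))
    full[, keep] <- dec$idp_weights
    rownames(full) <- rownames(dec$idp_weights)
    dec$idp_weights <- full
    dec$feature_scaling <- w
  }
  attr(dec, "completed") <- imp$completed
  dec
}
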