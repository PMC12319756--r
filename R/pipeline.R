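#' Write per-sample deltas as a TSV table
#'
#' @param deltas a `delta_set` or list of them (same length).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_delta_table <- function(deltas, path) {
  if (inherits(deltas, "delta_set")) deltas <- list(deltas)
  df <- as.data.frame(lapply(deltas, `[[`, "delta"))
  names(df) <- vapply(deltas, `[[`, character(1), "feature_id")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' End-to-end analysis of a two-timepoint IDP cohort
#'
#' Orchestrates the full method: outlier removal, confound regression and
#' mode extraction ([extract_modes()]), timepoint pooling, all-in-one and
#' per-mode delta estimation, baseline/expansion decomposition per mode,
#' and the cross-sectional/longitudinal consistency table. All tables plus
#' a provenance record (package version, seed, config echo and its file
#' hash) are written under `out_dir`. Stages run in a fixed order and any
#' stage error aborts with the stage named.
#'
#' @param x a [cohort] (or path to one readable by [read_cohort()]).
#' @param out_dir output directory (created if needed).
#' @param n_modes modes to extract; when `skip_extraction` the feature
#'   columns are treated as already-extracted mode scores.
#' @param seed seed for the ICA.
#' @param skip_extraction treat columns of `x` as mode scores directly.
#' @param use_confounds include the cohort's confound table (default TRUE).
#' @param orthogonalize_mode_deltas passed through to the delta step.
#' @return invisible list of the main results (`modes`, `aio`,
#'   `expansion`, `longitudinal`, `files`).
#' @export
run_pipeline <- function(x, out_dir, n_modes = 16L, seed = 1L,
                         skip_extraction = FALSE, use_confounds = TRUE,
                         orthogonalize_mode_deltas = TRUE) {
  stage <- "read"
  result <- tryCatch({
    if (is.character(x)) x <- read_cohort(x)
    stopifnot(inherits(x, "cohort"))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "pool_timepoints"
    pooled <- if (!is.null(x$timepoint)) pool_timepoints(x) else x

    stage <- "mode_extraction"
    if (skip_extraction) {
      scores <- pooled$features
      dec <- NULL
    } else {
      dec <- extract_modes(pooled, n_modes = n_modes, seed = seed,
                           confounds = if (use_confounds) pooled$confounds)
      scores <- dec$subject_weights
    }
    mode_cohort <- cohort(features = scores, age_years = pooled$age_years,
                          subject_id = pooled$subject_id,
                          timepoint = pooled$timepoint,
                          interval_years = pooled$interval_years,
                          paired = pooled$paired)

    stage <- "delta_estimation"
    aio <- fit_all_in_one(mode_cohort)
    em <- fit_expansion_modes(mode_cohort,
                              orthogonalize = orthogonalize_mode_deltas)

    stage <- "longitudinal"
    longi <- if (!is.null(mode_cohort$timepoint) &&
                 !is.null(mode_cohort$interval_years)) {
      lt <- longitudinal_table(em$deltas, mode_cohort)
      lt$signed_Ef <- em$table$signed_Ef
      lt
    }

    stage <- "write_outputs"
    files <- c(
      deltas = file.path(out_dir, "deltas.tsv"),
      expansion = file.path(out_dir, "expansion.tsv"),
      aio_model = file.path(out_dir, "all_in_one.json"),
      provenance = file.path(out_dir, "provenance.json"))
    write_delta_table(c(em$deltas, list(aio$delta)), files[["deltas"]])
    utils::write.table(em$table, files[["expansion"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(alpha = as.list(aio$model$alpha),
                              fitted_on = aio$model$fitted_on),
                         files[["aio_model"]], auto_unbox = TRUE, digits = NA)
    if (!is.null(longi)) {
      files["longitudinal"] <- file.path(out_dir, "longitudinal.tsv")
      utils::write.table(longi, files[["longitudinal"]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(dec)) {
      files["idp_weights"] <- file.path(out_dir, "idp_weights.tsv")
      utils::write.table(dec$idp_weights, files[["idp_weights"]], sep = "\t",
                         quote = FALSE, row.names = TRUE, col.names = NA)
    }
    cfg <- list(package = "agedelta",
                version = as.character(utils::packageVersion("agedelta")),
                seed = seed, n_modes = n_modes,
                skip_extraction = skip_extraction,
                use_confounds = use_confounds,
                orthogonalize_mode_deltas = orthogonalize_mode_deltas,
                n_samples = mode_cohort$n)
    jsonlite::write_json(cfg, files[["provenance"]], auto_unbox = TRUE)
    hash <- unname(tools::md5sum(files[["provenance"]]))
    cfg$config_hash <- hash
    jsonlite::write_json(cfg, files[["provenance"]], auto_unbox = TRUE)
    list(modes = dec, aio = aio, expansion = em, longitudinal = longi,
         files = files)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  invisible(result)
}
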