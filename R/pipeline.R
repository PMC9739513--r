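# End-to-end pipeline: synthesize (or ingest) a cohort, resample, crop the
# VOI, segment, extract the registry features, and fit/evaluate the
# invasiveness model — all reproducible from one config and one seed.

#' Pipeline configuration
#'
#' A fully serializable description of a run: cohort size and class balance,
#' the phantom template, the segmentation configuration, registry version and
#' model options. A run is reproducible from the config alone.
#'
#' @param n cohort size.
#' @param invasive_fraction invasive class fraction.
#' @param seed master seed; stage seeds derive from it.
#' @param base_spec template [phantom_spec()].
#' @param segmentation a [seg_config()].
#' @param registry registry version for [extract_features()].
#' @param n_levels quantization levels.
#' @param max_features selection cap for [sfs_select()].
#' @param nested nested (per-fold) feature selection?
#' @param out_dir optional output directory; when set, run artifacts
#'   (features CSV, model and metrics JSON, ROC points CSV) are written
#'   there, each named with the run id.
#' @param run_id run identifier; default derives from `n` and `seed`.
#' @param overwrite allow overwriting existing output files?
#' @return A `ggn_pipeline_config`.
#' @export
pipeline_config <- function(n = 40L, invasive_fraction = 77 / 338, seed = 7L,
                            base_spec = phantom_spec(),
                            segmentation = seg_config(),
                            registry = "v1", n_levels = 32L,
                            max_features = 5L, nested = FALSE,
                            out_dir = NULL, run_id = NULL,
                            overwrite = FALSE) {
  structure(list(
    n = as.integer(n), invasive_fraction = invasive_fraction,
    seed = as.integer(seed), base_spec = base_spec,
    segmentation = segmentation, registry = registry,
    n_levels = as.integer(n_levels), max_features = as.integer(max_features),
    nested = isTRUE(nested), out_dir = out_dir,
    run_id = run_id %||% sprintf("ggn-n%d-s%d", as.integer(n), as.integer(seed)),
    overwrite = isTRUE(overwrite)
  ), class = "ggn_pipeline_config")
}

#' Serialize / load a pipeline config
#'
#' YAML round trip: `read_pipeline_config(write_pipeline_config(cfg, path))`
#' reproduces the config exactly.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "ggn_pipeline_config"))
  ser <- unclass(config)
  ser$base_spec <- unclass(config$base_spec)
  ser$segmentation <- unclass(config$segmentation)
  yaml::write_yaml(ser, path, precision = 17)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    n = raw$n, invasive_fraction = raw$invasive_fraction, seed = raw$seed,
    base_spec = do.call(phantom_spec, list(
      nodule_radius_mm = raw$base_spec$nodule_radius_mm,
      nodule_density_hu = raw$base_spec$nodule_density_hu,
      density_sd_hu = raw$base_spec$density_sd_hu,
      background_hu = raw$base_spec$background_hu,
      background_sd_hu = raw$base_spec$background_sd_hu,
      heterogeneity = raw$base_spec$heterogeneity,
      vessel = raw$base_spec$vessel,
      vessel_radius_mm = raw$base_spec$vessel_radius_mm,
      vessel_density_hu = raw$base_spec$vessel_density_hu,
      shape_axes_ratio = unlist(raw$base_spec$shape_axes_ratio),
      volume_shape = unlist(raw$base_spec$volume_shape),
      spacing_mm = unlist(raw$base_spec$spacing_mm),
      seed = raw$base_spec$seed)),
    segmentation = do.call(seg_config, raw$segmentation[
      setdiff(names(raw$segmentation), character(0))]),
    registry = raw$registry, n_levels = raw$n_levels,
    max_features = raw$max_features, nested = raw$nested,
    out_dir = raw$out_dir, run_id = raw$run_id, overwrite = raw$overwrite
  )
}

pipeline_output_path <- function(config, what, ext) {
  file.path(config$out_dir, sprintf("%s_%s.%s", config$run_id, what, ext))
}

write_run_artifact <- function(config, what, ext, writer) {
  path <- pipeline_output_path(config, what, ext)
  if (file.exists(path) && !config$overwrite)
    stop("output exists (set overwrite = TRUE): ", path)
  writer(path)
  path
}

#' Run the full pipeline
#'
#' Generates a labelled phantom cohort, then for each phantom: resamples to
#' 1 mm isotropic, crops the 64-cube VOI at the nodule centre, segments
#' (level set + vessel removal), and extracts the registry features. The
#' feature table then flows through the statistical core: t-test screen,
#' z-scoring, forward selection, logistic fit, LOOCV with Youden cutoff.
#'
#' @param config a [pipeline_config()].
#' @return A `ggn_run_report`: class counts, the per-patient feature tibble,
#'   the screen, the trained model, the LOOCV evaluation, and provenance
#'   (config, timings, package version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "ggn_pipeline_config"))
  t_start <- Sys.time()
  cohort <- generate_cohort_phantoms(
    config$n, config$invasive_fraction,
    seed = config$seed, base_spec = config$base_spec)

  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    ph <- cohort[[i]]
    iso <- resample_isotropic(ph$volume)
    ctr <- round((dim(iso$values) + 1) / 2)
    voi <- extract_voi(iso, ctr)
    mask <- segment_nodule(voi, config$segmentation)
    fv <- extract_features(voi, mask, version = config$registry,
                           n_levels = config$n_levels)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(patient_id = ph$patient_id, label = ph$label), fv)
  }
  features <- dplyr::bind_rows(rows)

  # model stage: only complete (non-degenerate) feature columns compete
  feat_cols <- setdiff(names(features), c("patient_id", "label"))
  complete <- feat_cols[!vapply(features[feat_cols],
                                function(x) anyNA(x), logical(1))]
  model_data <- features[, c("label", complete)]
  screen <- ttest_screen(model_data)
  trained <- train_invasiveness_model(model_data,
                                      max_features = config$max_features)
  report <- structure(list(
    run_id = config$run_id,
    config = config,
    class_counts = table(features$label),
    features = features,
    screen = screen,
    model = trained$model,
    loocv = trained$loocv,
    n_features = length(feat_cols),
    n_complete_features = length(complete),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    package_version = as.character(utils::packageVersion("ggnrad"))
  ), class = "ggn_run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_artifact(config, "features", "csv", function(p)
      utils::write.csv(features, p, row.names = FALSE))
    write_run_artifact(config, "model", "json", function(p)
      jsonlite::write_json(list(
        selected_features = trained$model$selected_features,
        coefficients = as.list(trained$model$coefficients),
        intercept = trained$model$intercept,
        cutoff = trained$model$cutoff,
        normalization = list(
          center = as.list(trained$model$normalization$center[
            trained$model$selected_features]),
          scale = as.list(trained$model$normalization$scale[
            trained$model$selected_features]))
      ), p, auto_unbox = TRUE, digits = NA))
    write_run_artifact(config, "metrics", "json", function(p)
      jsonlite::write_json(as.list(glance(trained$loocv)), p,
                           auto_unbox = TRUE, digits = NA))
    write_run_artifact(config, "roc", "csv", function(p)
      utils::write.csv(trained$loocv$roc_points, p, row.names = FALSE))
  }
  report
}

#' @export
print.ggn_run_report <- function(x, ...) {
  cc <- x$class_counts
  cat(sprintf("<ggn_run_report> %s\n", x$run_id))
  cat(sprintf("  cohort: n = %d (%s)\n", sum(cc),
              paste(sprintf("%s %d", names(cc), cc), collapse = ", ")))
  cat(sprintf("  features: %d (%d complete), %d significant at p < 0.05\n",
              x$n_features, x$n_complete_features, sum(x$screen$significant)))
  cat(sprintf("  selected: %s\n",
              paste(x$model$selected_features, collapse = ", ")))
  cat(sprintf("  LOOCV: AUC %.4f, accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$loocv$auc, x$loocv$accuracy, x$loocv$sensitivity,
              x$loocv$specificity))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
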