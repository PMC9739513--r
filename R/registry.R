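# The feature registry: a declared, versioned manifest of exactly which
# features the characterizing step emits, in which order. The default ("v1")
# registry has 404 entries: 14 morphology + 20 extended percentiles computed
# once, plus 74 intensity/texture features (20 histogram, 24 GLCM, 16 GLRLM,
# 14 GLSZM) on each of five image variants — the original VOI, three
# Laplacian-of-Gaussian scales and one Gaussian smoothing.

.morph_names <- c(
  "Elongation", "Flatness", "MajorAxisLength", "MinorAxisLength",
  "LeastAxisLength", "MeshVolume", "SurfaceArea", "Sphericity",
  "SurfaceVolumeRatio", "Compactness1", "Compactness2",
  "SphericalDisproportion", "VoxelVolume", "Maximum3DDiameter")

.hist_names <- c(
  "Mean", "Median", "Minimum", "Maximum", "Range", "Variance", "Skewness",
  "Kurtosis", "Energy", "TotalEnergy", "RootMeanSquared",
  "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation", "Uniformity",
  "Entropy", "P10", "P25", "P75", "P90", "InterquartileRange")

.glcm_names <- c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "Homogeneity", "ID", "IDMN", "IDN", "InverseVariance",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares",
  "SumVariance", "Imc1", "Imc2")

.glrlm_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunLengthVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

.glszm_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis")

.registry_variants <- c("original", "log_1", "log_2", "log_3", "smooth_1")

#' The feature registry manifest
#'
#' @param version registry version token; only `"v1"` is defined.
#' @return A tibble with one row per feature: `name`, `family`
#'   (morphology/percentiles/histogram/glcm/glrlm/glszm) and `variant`
#'   (`""` for mask-only and original-image blocks computed once).
#' @export
feature_registry <- function(version = "v1") {
  if (!identical(version, "v1")) stop("unknown registry version: ", version)
  rows <- list(
    tibble::tibble(name = paste0("morphology_", .morph_names),
                   family = "morphology", variant = ""),
    tibble::tibble(name = paste0("percentiles_P", seq(5, 100, 5)),
                   family = "percentiles", variant = "")
  )
  for (v in .registry_variants) {
    rows <- c(rows, list(
      tibble::tibble(name = paste0(v, "_histogram_", .hist_names),
                     family = "histogram", variant = v),
      tibble::tibble(name = paste0(v, "_glcm_", .glcm_names),
                     family = "glcm", variant = v),
      tibble::tibble(name = paste0(v, "_glrlm_", .glrlm_names),
                     family = "glrlm", variant = v),
      tibble::tibble(name = paste0(v, "_glszm_", .glszm_names),
                     family = "glszm", variant = v)
    ))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "registry_version") <- version
  out
}

# Laplacian of Gaussian at scale sigma_mm, gamma = 2 normalized
log_filter <- function(v, spacing, sigma_mm) {
  sv <- sigma_mm / spacing
  out <- 0
  for (a in 1:3) {
    term <- v
    for (b in 1:3) {
      ord <- if (a == b) 2L else 0L
      term <- conv_axis(term, gauss_deriv_kernel(sv[b], ord), b)
    }
    out <- out + term / spacing[a]^2
  }
  sigma_mm^2 * out
}

variant_image <- function(v, spacing, variant) {
  switch(variant,
    original = v,
    log_1 = log_filter(v, spacing, 1),
    log_2 = log_filter(v, spacing, 2),
    log_3 = log_filter(v, spacing, 3),
    smooth_1 = gauss_smooth3(v, 1 / spacing),
    stop("unknown variant: ", variant)
  )
}

#' Extract the full radiomic feature vector
#'
#' Runs the characterizing step on a VOI and its segmentation mask through
#' the versioned registry: 404 named features by default. Deterministic;
#' families that cannot be computed on a degenerate mask (e.g. morphology of
#' a flat mask, co-occurrence of a single voxel) are reported as `NA` with
#' reasons in the `missing` attribute.
#'
#' @param voi a `ggn_volume` (typically the 64-cube from [extract_voi()]).
#' @param mask logical array, same shape.
#' @param version registry version (default `"v1"`).
#' @param n_levels gray levels for quantization (default 32).
#' @return A one-row tibble with one column per registry feature, in registry
#'   order; attributes `registry_version` and `missing`.
#' @export
extract_features <- function(voi, mask, version = "v1", n_levels = 32L) {
  v <- if (inherits(voi, "ggn_volume")) voi$values else voi
  spacing <- if (inherits(voi, "ggn_volume")) voi$spacing_mm else c(1, 1, 1)
  stopifnot(all(dim(v) == dim(mask)))
  if (!any(mask)) stop("mask is empty")
  reg <- feature_registry(version)
  vals <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)
  missing <- list()

  morph <- tryCatch(morphology_features(mask, spacing), error = function(e) e)
  if (inherits(morph, "error")) {
    missing$morphology <- conditionMessage(morph)
  } else {
    vals[paste0("morphology_", names(morph))] <- morph
  }

  x <- v[mask]
  vals[paste0("percentiles_P", seq(5, 100, 5))] <-
    stats::quantile(x, seq(0.05, 1, 0.05), names = FALSE, type = 7)

  for (variant in .registry_variants) {
    img <- variant_image(v, spacing, variant)
    hf <- histogram_features(img, mask, n_levels = n_levels,
                             voxel_volume_mm3 = prod(spacing))
    vals[paste0(variant, "_histogram_", names(hf))] <- hf
    q <- quantize(img, mask, n_levels = n_levels)
    gl <- tryCatch(glcm_features(glcm_compute(q)), error = function(e) e)
    if (inherits(gl, "error")) {
      missing[[paste0(variant, "_glcm")]] <- conditionMessage(gl)
    } else {
      vals[paste0(variant, "_glcm_", names(gl))] <- gl
    }
    rl <- glrlm_features(glrlm_compute(q))
    vals[paste0(variant, "_glrlm_", names(rl))] <- rl
    sz <- glszm_features(glszm_compute(q))
    vals[paste0(variant, "_glszm_", names(sz))] <- sz
  }

  out <- tibble::as_tibble(as.list(vals))
  attr(out, "registry_version") <- version
  attr(out, "missing") <- missing
  out
}

#' Published feature-table name map
#'
#' Maps the 26 row labels of the published radiomic feature table (including
#' its "homogenity" spelling, an inverse-difference-moment homogeneity) to
#' the canonical registry names.
#'
#' @return A tibble with columns `label` and `feature`.
#' @export
table4_features <- function() {
  tibble::tribble(
    ~label, ~feature,
    "Elongation", "morphology_Elongation",
    "Flatness", "morphology_Flatness",
    "MeshVolume", "morphology_MeshVolume",
    "Sphericity", "morphology_Sphericity",
    "SurfaceArea", "morphology_SurfaceArea",
    "Skewness", "original_histogram_Skewness",
    "Kurtosis", "original_histogram_Kurtosis",
    "Uniformity", "original_histogram_Uniformity",
    "Entropy", "original_histogram_Entropy",
    "75th percentile (HU)", "original_histogram_P75",
    "Autocorrelation", "original_glcm_Autocorrelation",
    "Contrast", "original_glcm_Contrast",
    "Correlation", "original_glcm_Correlation",
    "ClusterProminence", "original_glcm_ClusterProminence",
    "ClusterShade", "original_glcm_ClusterShade",
    "MaximumProbability", "original_glcm_MaximumProbability",
    "homogenity", "original_glcm_Homogeneity",
    "ShortRunEmphasis", "original_glrlm_ShortRunEmphasis",
    "LongRunEmphasis", "original_glrlm_LongRunEmphasis",
    "LowGrayLevelRunEmphasis", "original_glrlm_LowGrayLevelRunEmphasis",
    "HighGrayLevelRunEmphasis", "original_glrlm_HighGrayLevelRunEmphasis",
    "RunLengthVariance", "original_glrlm_RunLengthVariance",
    "SmallAreaEmphasis", "original_glszm_SmallAreaEmphasis",
    "LargeAreaEmphasis", "original_glszm_LargeAreaEmphasis",
    "LowGrayLevelZoneEmphasis", "original_glszm_LowGrayLevelZoneEmphasis",
    "HighGrayLevelZoneEmphasis", "original_glszm_HighGrayLevelZoneEmphasis"
  )
}

#' Write the registry manifest as YAML
#'
#' @param path output file.
#' @param version registry version.
#' @return `path`, invisibly.
#' @export
write_registry_manifest <- function(path, version = "v1") {
  reg <- feature_registry(version)
  yaml::write_yaml(list(registry_version = version,
                        n_features = nrow(reg),
                        features = purrr::pmap(reg, function(name, family, variant)
                          list(name = name, family = family, variant = variant))),
                   path)
  invisible(path)
}
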