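# Gray-level size-zone matrix: zones are 26-connected components of constant
# gray level within the mask; the matrix counts zones by (level, size).

#' Gray-level size-zone matrix
#'
#' @param q a [quantize()] result.
#' @return A `ggn_glszm`: count matrix `counts` (`n_levels` rows, zone-size
#'   columns) plus the in-mask voxel count. The invariant
#'   `sum(size * count) == n_voxels` holds by construction.
#' @export
glszm_compute <- function(q) {
  stopifnot(inherits(q, "ggn_quantized"))
  lab <- label_equal_components(q$levels, q$mask)
  zone_sizes <- dplyr::count(lab, .data$label, .data$level, name = "size")
  zones <- dplyr::count(zone_sizes, .data$level, .data$size)
  max_size <- max(zones$size)
  counts <- matrix(0, q$n_levels, max_size)
  counts[cbind(zones$level, zones$size)] <- zones$n
  structure(list(counts = counts, n_voxels = sum(q$mask)),
            class = "ggn_glszm")
}

#' GLSZM scalar features
#'
#' The 14 size-zone statistics of the default registry (small/large area
#' emphasis, low/high gray-level zone emphasis and their combinations, zone
#' counts and entropy).
#'
#' @param m a [glszm_compute()] result.
#' @return Named numeric vector of length 14.
#' @export
glszm_features <- function(m) {
  counts <- m$counts
  N <- sum(counts)
  p <- counts / N
  nl <- nrow(counts); ns <- ncol(counts)
  i <- matrix(seq_len(nl), nl, ns)
  s <- matrix(seq_len(ns), nl, ns, byrow = TRUE)
  pi_ <- rowSums(p); ps <- colSums(p)
  mu_i <- sum(seq_len(nl) * pi_); mu_s <- sum(seq_len(ns) * ps)
  pe <- p[p > 0]
  c(
    SmallAreaEmphasis = sum(p / s^2),
    LargeAreaEmphasis = sum(p * s^2),
    GrayLevelNonUniformity = sum(rowSums(counts)^2) / N,
    GrayLevelNonUniformityNormalized = sum(pi_^2),
    SizeZoneNonUniformity = sum(colSums(counts)^2) / N,
    SizeZoneNonUniformityNormalized = sum(ps^2),
    ZonePercentage = N / m$n_voxels,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    ZoneVariance = sum(p * (s - mu_s)^2),
    ZoneEntropy = -sum(pe * log2(pe)),
    LowGrayLevelZoneEmphasis = sum(p / i^2),
    HighGrayLevelZoneEmphasis = sum(p * i^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (i^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = sum(p * i^2 / s^2)
  )
}
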