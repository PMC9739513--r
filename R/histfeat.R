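#' First-order (histogram) features of the in-mask intensities
#'
#' Moments use the population convention (kurtosis is not excess-corrected, so
#' a Gaussian scores 3); Uniformity and Entropy are computed on the same
#' equal-width quantized histogram as the texture matrices; percentiles use
#' linear interpolation (R type 7).
#'
#' @param voi a `ggn_volume` or 3D array of HU.
#' @param mask logical array, nonempty.
#' @param n_levels histogram bins for Uniformity/Entropy (default 32).
#' @param voxel_volume_mm3 voxel volume used by TotalEnergy (default 1).
#' @return Named numeric vector of length 20.
#' @export
histogram_features <- function(voi, mask, n_levels = 32L, voxel_volume_mm3 = 1) {
  v <- if (inherits(voi, "ggn_volume")) voi$values else voi
  stopifnot(all(dim(v) == dim(mask)))
  x <- v[mask]
  if (length(x) == 0L) stop("mask is empty")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 else 0
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inner <- x[x >= q[1] & x <= q[4]]
  prob <- tabulate(quantize(v, mask, n_levels = max(2L, n_levels))$levels[mask],
                   nbins = max(2L, n_levels))
  prob <- prob / sum(prob)
  pe <- prob[prob > 0]
  c(
    Mean = m,
    Median = stats::median(x),
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    Variance = m2,
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(x^2),
    TotalEnergy = sum(x^2) * voxel_volume_mm3,
    RootMeanSquared = sqrt(mean(x^2)),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    Uniformity = sum(prob^2),
    Entropy = -sum(pe * log2(pe)),
    P10 = q[1],
    P25 = q[2],
    P75 = q[3],
    P90 = q[4],
    InterquartileRange = q[3] - q[2]
  )
}
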