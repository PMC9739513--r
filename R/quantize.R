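#' Quantize in-mask intensities to gray levels
#'
#' Equal-width binning of the in-mask HU range into `n_levels` levels:
#' `level = floor((x - min) / width) + 1`, with the maximum value assigned to
#' `n_levels` (lower-half-open bins, top bin closed). A constant in-mask image
#' maps entirely to level 1. Because bins are relative to the in-mask range,
#' quantization — and every texture feature built on it — is invariant to
#' adding a constant to the image.
#'
#' @param voi a `ggn_volume` or 3D array.
#' @param mask logical array of the same shape; must be nonempty.
#' @param n_levels number of gray levels, at least 2 (default 32).
#' @return A `ggn_quantized` list: integer `levels` array (`NA` outside the
#'   mask), `mask`, `n_levels`, `bin_edges`.
#' @export
quantize <- function(voi, mask, n_levels = 32L) {
  v <- if (inherits(voi, "ggn_volume")) voi$values else voi
  stopifnot(all(dim(v) == dim(mask)))
  if (!any(mask)) stop("mask is empty")
  if (n_levels < 2L) stop("n_levels must be at least 2")
  x <- v[mask]
  lo <- min(x); hi <- max(x)
  levels <- array(NA_integer_, dim(v))
  if (hi == lo) {
    levels[mask] <- 1L
    edges <- c(lo, hi)
  } else {
    w <- (hi - lo) / n_levels
    levels[mask] <- pmin(as.integer(floor((x - lo) / w)) + 1L, as.integer(n_levels))
    edges <- lo + w * 0:n_levels
  }
  structure(list(levels = levels, mask = mask, n_levels = as.integer(n_levels),
                 bin_edges = edges),
            class = "ggn_quantized")
}
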