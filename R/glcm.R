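# Gray-level co-occurrence matrix and its scalar features. Counts are pooled
# over the 13 unique distance-1 directions of the 3D lattice, symmetrized,
# then normalized to a joint probability matrix — one matrix per image, the
# convention the feature oracles in the test suite also follow.

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of in-mask voxel levels at each offset, symmetrizes (both
#' voxel orders), pools counts over all offsets and normalizes to
#' probabilities.
#'
#' @param q a [quantize()] result.
#' @param offsets integer matrix of `(dz, dy, dx)` rows; default the 13 unique
#'   distance-1 directions.
#' @return A `ggn_glcm`: probability matrix `p` (`n_levels` square), the
#'   offsets used, and the raw pair count.
#' @export
glcm_compute <- function(q, offsets = NULL) {
  stopifnot(inherits(q, "ggn_quantized"))
  if (is.null(offsets)) offsets <- neighbor_offsets(26L, half = TRUE)
  offsets <- matrix(as.integer(offsets), ncol = 3)
  d <- dim(q$levels)
  n <- q$n_levels
  vox <- which(q$mask)
  co <- arrayInd(vox, d)
  lev <- q$levels[vox]
  counts <- matrix(0, n, n)
  total <- 0L
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    nz <- co[, 1] + o[1]; ny <- co[, 2] + o[2]; nx <- co[, 3] + o[3]
    ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] & nx >= 1L & nx <= d[3]
    if (!any(ok)) next
    nb <- nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2]
    nb_lev <- q$levels[nb]
    keep <- !is.na(nb_lev)
    if (!any(keep)) next
    a <- lev[ok][keep]; b <- nb_lev[keep]
    tab <- tabulate((a - 1L) * n + b, nbins = n * n)
    counts <- counts + matrix(tab, n, n, byrow = TRUE)
    total <- total + length(a)
  }
  if (total == 0L) stop("mask admits no voxel pair at the requested offsets")
  counts <- counts + t(counts)          # symmetrize
  structure(list(p = counts / sum(counts), offsets = offsets,
                 n_pairs = 2L * total),
            class = "ggn_glcm")
}

#' GLCM scalar features
#'
#' The 24 co-occurrence statistics of the default registry, including every
#' GLCM row of the published feature table (autocorrelation, contrast,
#' correlation, cluster prominence/shade, maximum probability, homogeneity).
#' Homogeneity is the inverse difference moment
#' `sum p / (1 + (i - j)^2)`. Correlation of a degenerate (single-level)
#' matrix is defined as 1.
#'
#' @param m a [glcm_compute()] result.
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(m) {
  p <- m$p
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(p)
  mux <- sum(seq_len(n) * px)
  sx2 <- sum((seq_len(n) - mux)^2 * px)
  # by symmetry the marginals coincide
  ipj <- i + j; imj <- i - j
  # difference and sum distributions
  pd <- vapply(0:(n - 1), function(k) sum(p[abs(imj) == k]), numeric(1))
  ps <- vapply(2:(2 * n), function(k) sum(p[ipj == k]), numeric(1))
  ent <- function(w) { w <- w[w > 0]; -sum(w * log2(w)) }
  da <- sum(0:(n - 1) * pd)
  sa <- sum(2:(2 * n) * ps)
  hx <- ent(px)
  hxy <- ent(p)
  q_indep <- outer(px, px)
  hxy1 <- -sum(p[q_indep > 0] * log2(q_indep[q_indep > 0]))
  hxy2 <- ent(q_indep)
  corr <- if (sx2 > 0) (sum(i * j * p) - mux^2) / sx2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(
    Autocorrelation = sum(i * j * p),
    JointAverage = mux,
    ClusterProminence = sum((ipj - 2 * mux)^4 * p),
    ClusterShade = sum((ipj - 2 * mux)^3 * p),
    ClusterTendency = sum((ipj - 2 * mux)^2 * p),
    Contrast = sum(imj^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pd),
    DifferenceVariance = sum((0:(n - 1) - da)^2 * pd),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Homogeneity = sum(p / (1 + imj^2)),
    ID = sum(p / (1 + abs(imj))),
    IDMN = sum(p / (1 + imj^2 / n^2)),
    IDN = sum(p / (1 + abs(imj) / n)),
    InverseVariance = sum(p[imj != 0] / imj[imj != 0]^2),
    MaximumProbability = max(p),
    SumAverage = sa,
    SumEntropy = ent(ps),
    SumSquares = sum((i - mux)^2 * p),
    SumVariance = sum((2:(2 * n) - sa)^2 * ps),
    Imc1 = imc1,
    Imc2 = imc2
  )
}
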