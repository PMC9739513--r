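# Gray-level run-length matrix: maximal runs of equal level along each of the
# 13 unique lattice directions. Out-of-mask voxels break runs. Features are
# computed per direction and averaged, the stated aggregation convention.

# decompose mask voxels into lines along direction d and count runs
glrlm_one_direction <- function(co, lev, d, dims, n_levels) {
  # parameter along the line: first nonzero component of d advances by +-1
  ax <- which(d != 0)[1]
  s <- co[, ax] * d[ax]
  # line identifier: project out the direction
  base <- co - outer(s, d)
  key <- (base[, 1] + dims[1]) * (2 * dims[2] + 1) * (2 * dims[3] + 1) +
    (base[, 2] + dims[2]) * (2 * dims[3] + 1) + (base[, 3] + dims[3])
  ord <- order(key, s)
  k <- key[ord]; ss <- s[ord]; lv <- lev[ord]
  nn <- length(k)
  if (nn == 0L) return(NULL)
  new_run <- c(TRUE, k[-1] != k[-nn] | ss[-1] != ss[-nn] + 1L | lv[-1] != lv[-nn])
  run_id <- cumsum(new_run)
  len <- tabulate(run_id)
  run_lev <- lv[new_run]
  list(level = run_lev, length = len)
}

#' Gray-level run-length matrix
#'
#' @param q a [quantize()] result.
#' @return A `ggn_glrlm`: list with one count matrix (`n_levels` rows, run
#'   length columns) per direction, the direction set, and the in-mask voxel
#'   count.
#' @export
glrlm_compute <- function(q) {
  stopifnot(inherits(q, "ggn_quantized"))
  dirs <- neighbor_offsets(26L, half = TRUE)
  d <- dim(q$levels)
  vox <- which(q$mask)
  co <- arrayInd(vox, d)
  lev <- q$levels[vox]
  max_run <- max(d)
  mats <- vector("list", nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    runs <- glrlm_one_direction(co, lev, dirs[r, ], d, q$n_levels)
    counts <- matrix(0, q$n_levels, max_run)
    idx <- cbind(runs$level, runs$length)
    for (i in seq_along(runs$level))
      counts[idx[i, 1], idx[i, 2]] <- counts[idx[i, 1], idx[i, 2]] + 1
    mats[[r]] <- counts
  }
  structure(list(per_direction = mats, directions = dirs,
                 n_voxels = length(vox)),
            class = "ggn_glrlm")
}

glrlm_features_one <- function(counts, n_voxels) {
  N <- sum(counts)
  p <- counts / N
  nl <- nrow(counts); nr <- ncol(counts)
  i <- matrix(seq_len(nl), nl, nr)
  l <- matrix(seq_len(nr), nl, nr, byrow = TRUE)
  pi_ <- rowSums(p); pl <- colSums(p)
  mu_i <- sum(seq_len(nl) * pi_); mu_l <- sum(seq_len(nr) * pl)
  pe <- p[p > 0]
  c(
    ShortRunEmphasis = sum(p / l^2),
    LongRunEmphasis = sum(p * l^2),
    GrayLevelNonUniformity = sum(rowSums(counts)^2) / N,
    GrayLevelNonUniformityNormalized = sum(pi_^2),
    RunLengthNonUniformity = sum(colSums(counts)^2) / N,
    RunLengthNonUniformityNormalized = sum(pl^2),
    RunPercentage = N / n_voxels,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    RunLengthVariance = sum(p * (l - mu_l)^2),
    RunEntropy = -sum(pe * log2(pe)),
    LowGrayLevelRunEmphasis = sum(p / i^2),
    HighGrayLevelRunEmphasis = sum(p * i^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * l^2)),
    ShortRunHighGrayLevelEmphasis = sum(p * i^2 / l^2),
    LongRunLowGrayLevelEmphasis = sum(p * l^2 / i^2),
    LongRunHighGrayLevelEmphasis = sum(p * i^2 * l^2)
  )
}

#' GLRLM scalar features
#'
#' The 16 run-length statistics of the default registry (including
#' RunLengthVariance, a selected predictor of the invasiveness model),
#' computed per direction and averaged over the 13 directions.
#'
#' @param m a [glrlm_compute()] result.
#' @return Named numeric vector of length 16.
#' @export
glrlm_features <- function(m) {
  per_dir <- vapply(m$per_direction, glrlm_features_one,
                    numeric(16), n_voxels = m$n_voxels)
  rowMeans(per_dir)
}
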