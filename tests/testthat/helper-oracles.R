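# Brute-force enumeration oracles for the texture matrices, written as plain
# voxel-by-voxel walks so they stay independent of the vectorized
# implementations they check.

all_directions_13 <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  unname(g[keep, , drop = FALSE])
}

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

# exhaustive pair counting over every voxel and offset, both orders
oracle_glcm_matrix <- function(levels, mask, n_levels) {
  d <- dim(levels)
  dirs <- all_directions_13()
  counts <- matrix(0, n_levels, n_levels)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (!mask[z, y, x]) next
    for (r in seq_len(nrow(dirs))) {
      q <- c(z, y, x) + dirs[r, ]
      if (!in_bounds(q, d) || !mask[q[1], q[2], q[3]]) next
      a <- levels[z, y, x]; b <- levels[q[1], q[2], q[3]]
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

# walk every line voxel by voxel, recording maximal runs
oracle_glrlm_matrices <- function(levels, mask, n_levels) {
  d <- dim(levels)
  dirs <- all_directions_13()
  max_run <- max(d)
  lapply(seq_len(nrow(dirs)), function(r) {
    dir <- dirs[r, ]
    counts <- matrix(0, n_levels, max_run)
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      p <- c(z, y, x)
      if (!mask[z, y, x]) next
      prev <- p - dir
      # only start a run where no same-level mask voxel precedes it
      if (in_bounds(prev, d) && mask[prev[1], prev[2], prev[3]] &&
          levels[prev[1], prev[2], prev[3]] == levels[z, y, x]) next
      len <- 0L
      q <- p
      while (in_bounds(q, d) && mask[q[1], q[2], q[3]] &&
             levels[q[1], q[2], q[3]] == levels[z, y, x]) {
        len <- len + 1L
        q <- q + dir
      }
      counts[levels[z, y, x], len] <- counts[levels[z, y, x], len] + 1
    }
    counts
  })
}

# stack-based flood fill over 26-neighbourhoods
oracle_glszm_matrix <- function(levels, mask, n_levels) {
  d <- dim(levels)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  seen <- array(FALSE, d)
  zones <- list()
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (!mask[z, y, x] || seen[z, y, x]) next
    lv <- levels[z, y, x]
    stack <- list(c(z, y, x))
    seen[z, y, x] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (in_bounds(q, d) && mask[q[1], q[2], q[3]] &&
            !seen[q[1], q[2], q[3]] && levels[q[1], q[2], q[3]] == lv) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lv, size)
  }
  zs <- do.call(rbind, zones)
  counts <- matrix(0, n_levels, max(zs[, 2]))
  for (i in seq_len(nrow(zs)))
    counts[zs[i, 1], zs[i, 2]] <- counts[zs[i, 1], zs[i, 2]] + 1
  counts
}

# random quantized image fixture
random_quantized <- function(shape, n_levels, p_mask = 0.85) {
  lv <- array(sample.int(n_levels, prod(shape), replace = TRUE), shape)
  mask <- array(stats::runif(prod(shape)) < p_mask, shape)
  if (!any(mask)) mask[1] <- TRUE
  lv[!mask] <- NA_integer_
  structure(list(levels = lv, mask = mask, n_levels = as.integer(n_levels),
                 bin_edges = 0:n_levels),
            class = "ggn_quantized")
}

# quantized image from explicit level values (NA = outside mask)
quantized_from <- function(levels_array, n_levels) {
  structure(list(levels = levels_array, mask = !is.na(levels_array),
                 n_levels = as.integer(n_levels), bin_edges = 0:n_levels),
            class = "ggn_quantized")
}

# Mann-Whitney pairwise-concordance AUC (ties count one half)
oracle_auc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  dif <- outer(pos, neg, `-`)
  (sum(dif > 0) + 0.5 * sum(dif == 0)) / (length(pos) * length(neg))
}

# resample a phantom's truth (or vessel) mask onto the VOI grid
phantom_mask_in_voi <- function(ph, mask, centre = NULL, size = 64L) {
  iso <- resample_isotropic(new_volume(mask + 0, ph$volume$spacing_mm))
  centre <- centre %||% round((dim(iso$values) + 1) / 2)
  extract_voi(iso, centre, size = size, pad_hu = 0)$values >= 0.5
}

phantom_voi <- function(ph, size = 64L) {
  iso <- resample_isotropic(ph$volume)
  extract_voi(iso, round((dim(iso$values) + 1) / 2), size = size)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
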