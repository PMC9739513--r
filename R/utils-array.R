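# Low-level 3D array helpers shared by the phantom generator, segmentation and
# texture code. Internal convention everywhere: arrays are indexed [z, y, x]
# (z fastest) and spacing vectors follow the same (z, y, x) order.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
gauss_kernel <- function(sigma, order = 0L) {
  # discrete Gaussian (or its 2nd derivative) sampled on an integer grid,
  # truncated at 4 sigma; order 0 kernels sum to 1
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 2L) {
    k <- g * (x^2 - sigma^2) / sigma^4
    # enforce zero response to constants
    return(k - mean(k))
  }
  stop("unsupported derivative order")
}

# Edge-clamped convolution along one axis, realized as a dense banded-matrix
# multiply; cheap because axes are at most a few hundred voxels long.
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    src <- clamp(seq_len(n) + off, 1L, n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + kernel[j]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = n)
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

#' @noRd
gauss_smooth3 <- function(arr, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (a in 1:3) {
    if (sigma_vox[a] > 0) arr <- conv_axis(arr, gauss_kernel(sigma_vox[a]), a)
  }
  arr
}

# 3x3x3 box mean, used as the curvature/smoothing operator in the level set
box_mean3 <- function(arr) {
  k <- rep(1 / 3, 3)
  conv_axis(conv_axis(conv_axis(arr, k, 1), k, 2), k, 3)
}

# The 26 neighbour offsets (or 6, or the 13 unique half-space directions)
neighbor_offsets <- function(connectivity = 26L, half = FALSE) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (half) {
    keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
      (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
    g <- g[keep, , drop = FALSE]
  }
  unname(g)
}

# One binary dilation step
dilate3 <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  out <- mask
  offs <- neighbor_offsets(connectivity)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    sz <- seq_len(d[1]); sy <- seq_len(d[2]); sx <- seq_len(d[3])
    tz <- clamp(sz - o[1], 1L, d[1])
    ty <- clamp(sy - o[2], 1L, d[2])
    tx <- clamp(sx - o[3], 1L, d[3])
    shifted <- mask[tz, ty, tx, drop = FALSE]
    # voxels whose clamped source equals themselves at the border must not
    # self-seed: zero out the wrapped border slabs
    if (o[1] != 0) shifted[if (o[1] > 0) 1L else d[1], , ] <- FALSE
    if (o[2] != 0) shifted[, if (o[2] > 0) 1L else d[2], ] <- FALSE
    if (o[3] != 0) shifted[, , if (o[3] > 0) 1L else d[3]] <- FALSE
    out <- out | shifted
  }
  out
}

# Region growing: the connected component(s) of `mask` reachable from `seed`
grow_from <- function(mask, seed, connectivity = 26L) {
  cur <- seed & mask
  repeat {
    nxt <- dilate3(cur, connectivity) & mask
    if (sum(nxt) == sum(cur)) return(cur)
    cur <- nxt
  }
}

# Fill cavities: complement components (6-connectivity) not reachable from the
# array border become part of the mask
fill_holes3 <- function(mask) {
  d <- dim(mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- grow_from(!mask, border & !mask, connectivity = 6L)
  mask | (!mask & !outside)
}

# Largest connected component (26-connectivity), via igraph on the voxel graph
largest_component <- function(mask) {
  lab <- label_equal_components(array(1L, dim(mask)), mask)
  if (is.null(lab)) return(mask)
  best <- as.integer(names(which.max(table(lab$label))))
  out <- array(FALSE, dim(mask))
  out[lab$voxel[lab$label == best]] <- TRUE
  out
}

# Connected components of equal `values` within `mask` (26-connectivity).
# Returns a data.frame with linear voxel index and component label, or NULL for
# an empty mask. This is the workhorse for GLSZM zones and mask post-processing.
label_equal_components <- function(values, mask, connectivity = 26L) {
  vox <- which(mask)
  if (length(vox) == 0L) return(NULL)
  d <- dim(mask)
  idmap <- array(0L, d)
  idmap[vox] <- seq_along(vox)
  co <- arrayInd(vox, d)
  val <- values[vox]
  offs <- neighbor_offsets(connectivity, half = TRUE)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    nz <- co[, 1] + o[1]; ny <- co[, 2] + o[2]; nx <- co[, 3] + o[3]
    ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] & nx >= 1L & nx <= d[3]
    if (!any(ok)) next
    nb_lin <- nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2]
    nb_id <- idmap[nb_lin]
    keep <- nb_id > 0L & values[nb_lin] == val[ok]
    if (!any(keep)) next
    from <- c(from, which(ok)[keep])
    to <- c(to, nb_id[keep])
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  data.frame(voxel = vox, level = val, label = as.integer(memb))
}
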