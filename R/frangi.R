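# Multiscale Frangi vesselness: Hessian eigenvalue analysis of the
# Gaussian-smoothed VOI at several scales; bright tubular structures (vessels)
# score near 1, blobs and plates near 0. Used to strip vessels attached to the
# ground-glass nodule from the initial segmentation.

# Gaussian derivative kernel for correlation, calibrated so that the response
# to x (order 1) or x^2/2 (order 2) has unit gain.
gauss_deriv_kernel <- function(sigma, order) {
  r <- max(2L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0L) return(g / sum(g))
  if (order == 1L) {
    k <- x * g
    return(k / sum(x * k))
  }
  if (order == 2L) {
    k <- (x^2 - sigma^2) * g
    k <- k - mean(k)                 # zero response to constants
    return(k / sum(x^2 / 2 * k))     # unit response to x^2/2
  }
  stop("unsupported order")
}

# Hessian (physical mm units) of a 3D array at Gaussian scale sigma_mm
hessian3 <- function(v, spacing, sigma_mm) {
  sv <- sigma_mm / spacing # per-axis sigma in voxels
  kern <- function(axis, order) gauss_deriv_kernel(sv[axis], order)
  dconv <- function(orders) {
    out <- v
    for (a in 1:3) out <- conv_axis(out, kern(a, orders[a]), a)
    out / prod(spacing^orders)
  }
  list(
    zz = dconv(c(2L, 0L, 0L)), yy = dconv(c(0L, 2L, 0L)), xx = dconv(c(0L, 0L, 2L)),
    zy = dconv(c(1L, 1L, 0L)), zx = dconv(c(1L, 0L, 1L)), yx = dconv(c(0L, 1L, 1L))
  )
}

# eigenvalues of a field of symmetric 3x3 matrices, closed-form (trig method),
# returned sorted by increasing |lambda|
sym_eigen3 <- function(H) {
  a11 <- H$zz; a22 <- H$yy; a33 <- H$xx
  a12 <- H$zy; a13 <- H$zx; a23 <- H$yx
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  ps <- ifelse(p > 0, p, 1)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detB <- b11 * b22 * b33 + 2 * b12 * b13 * b23 -
    b11 * b23^2 - b22 * b13^2 - b33 * b12^2
  phi <- acos(clamp(detB / 2, -1, 1)) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  E <- cbind(as.vector(e1), as.vector(e2), as.vector(e3))
  A <- abs(E)
  ord1 <- max.col(-A, ties.method = "first")
  ord3 <- max.col(A, ties.method = "last")
  # when ord1 == ord3 the three coincide; middle index works out regardless
  ord2 <- 6L - ord1 - ord3
  ord2[ord1 == ord3] <- ord1[ord1 == ord3]
  n <- nrow(E)
  list(l1 = E[cbind(seq_len(n), ord1)],
       l2 = E[cbind(seq_len(n), ord2)],
       l3 = E[cbind(seq_len(n), ord3)])
}

#' Multiscale Frangi vesselness of a VOI
#'
#' For each scale the VOI is differentiated with Gaussian-derivative filters,
#' the Hessian eigenvalues `|l1| <= |l2| <= |l3|` are combined into the
#' classic tube score (bright structures: `l2, l3 < 0`), with
#' gamma = 2 scale normalization, and the per-voxel maximum over scales is
#' returned. `frangi_c = NULL` sets the structureness scale per filter scale
#' to half the maximal Hessian norm, so responses are normalized to `[0, 1]`.
#'
#' @param voi a `ggn_volume` (or bare 3D array, assumed 1 mm spacing).
#' @param config a [seg_config()] carrying the Frangi parameters.
#' @return Array of vesselness scores in `[0, 1]`, same shape as the VOI.
#' @export
frangi_vesselness <- function(voi, config = seg_config()) {
  v <- if (inherits(voi, "ggn_volume")) voi$values else voi
  spacing <- if (inherits(voi, "ggn_volume")) voi$spacing_mm else c(1, 1, 1)
  d <- dim(v)
  best <- array(0, d)
  a2 <- 2 * config$frangi_alpha^2
  b2 <- 2 * config$frangi_beta^2
  for (sig in config$frangi_scales_mm) {
    H <- hessian3(v, spacing, sig)
    H <- lapply(H, function(x) sig^2 * x) # gamma = 2 scale normalization
    ev <- sym_eigen3(H)
    S2 <- ev$l1^2 + ev$l2^2 + ev$l3^2
    # guard against pure float noise (e.g. constant input): the Hessian of a
    # real structure is orders of magnitude above machine eps times the scale
    if (sqrt(max(S2)) < 1e-8 * max(1, max(abs(v)))) next
    c_val <- config$frangi_c %||% (sqrt(max(S2)) / 2)
    if (c_val <= 0) next
    al2 <- abs(ev$l2); al3 <- abs(ev$l3)
    RA2 <- ifelse(al3 > 0, (al2 / al3)^2, 0)
    RB2 <- ifelse(al2 * al3 > 0, ev$l1^2 / (al2 * al3), 0)
    vness <- (1 - exp(-RA2 / a2)) * exp(-RB2 / b2) * (1 - exp(-S2 / (2 * c_val^2)))
    vness[ev$l2 > 0 | ev$l3 > 0] <- 0
    best <- pmax(best, array(vness, d))
  }
  clamp(best, 0, 1)
}
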