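# Semi-automatic nodule segmentation: a hybrid level set (region term
# thresholded at the user-adjustable lower intensity bound mu, plus curvature
# regularization) initialized at the VOI centre, followed by Frangi-based
# vessel removal and mask post-processing. Every stage is deterministic.

#' Segmentation configuration
#'
#' @param mu_hu lower bound of the lesion gray level in HU; voxels at or above
#'   `mu_hu` attract the contour, voxels below repel it. `NULL` (default)
#'   estimates it from the VOI histogram as the midpoint between the
#'   parenchyma and lesion modes (Otsu split of the class means).
#' @param levelset_iterations iteration budget of the level-set evolution.
#' @param curvature_weight non-negative weight of the curvature/smoothing
#'   term; 0 reduces the stage to a pure seed-connected threshold.
#' @param convergence_tol stop when the fraction of voxels changing sign in
#'   one iteration drops below this.
#' @param frangi_scales_mm increasing Gaussian scales (mm) of the multiscale
#'   vesselness filter; defaults span the calibre of vessels that reach a
#'   peripheral nodule (about 0.5-2 mm radius).
#' @param frangi_alpha,frangi_beta,frangi_c vesselness sensitivity parameters;
#'   `frangi_c = NULL` sets it per scale to half the maximal Hessian norm.
#' @param vesselness_threshold value in `[0, 1]`; voxels whose vesselness
#'   reaches it seed the vessel removal.
#' @param vesselness_hysteresis fraction of `vesselness_threshold` used as the
#'   weak bound: removal grows from strong seeds through connected voxels
#'   whose vesselness reaches `threshold * hysteresis`.
#' @return A list of class `ggn_seg_config`.
#' @export
seg_config <- function(mu_hu = NULL,
                       levelset_iterations = 60L,
                       curvature_weight = 0.2,
                       convergence_tol = 5e-4,
                       frangi_scales_mm = c(0.5, 1, 1.5, 2),
                       frangi_alpha = 0.5, frangi_beta = 0.5, frangi_c = NULL,
                       vesselness_threshold = 0.5,
                       vesselness_hysteresis = 0.5) {
  if (length(frangi_scales_mm) == 0L || any(diff(frangi_scales_mm) <= 0) ||
      any(frangi_scales_mm <= 0))
    stop("frangi_scales_mm must be nonempty, positive and increasing")
  if (vesselness_threshold < 0 || vesselness_threshold > 1)
    stop("vesselness_threshold must lie in [0, 1]")
  if (curvature_weight < 0) stop("curvature_weight must be non-negative")
  structure(list(
    mu_hu = mu_hu, levelset_iterations = as.integer(levelset_iterations),
    curvature_weight = curvature_weight, convergence_tol = convergence_tol,
    frangi_scales_mm = frangi_scales_mm, frangi_alpha = frangi_alpha,
    frangi_beta = frangi_beta, frangi_c = frangi_c,
    vesselness_threshold = vesselness_threshold,
    vesselness_hysteresis = vesselness_hysteresis
  ), class = "ggn_seg_config")
}

# Data-driven default for the user-adjustable lower lesion bound mu: midpoint
# between the background mode (histogram mode of the VOI outside a central
# ball — the lesion is a sub-percent minority of the 64-cube, so the global
# mode is parenchyma) and the lesion mode (median inside a central 4 mm ball,
# the seed being the lesion centre by construction).
default_mu <- function(values) {
  d <- dim(values)
  core <- voi_centre_ball(d, 4)
  lesion_mode <- stats::median(values[core])
  bg <- values[!core]
  # exclude air (and VOI padding, -1000): the background of interest is lung
  # parenchyma, not the air outside the thorax
  if (any(bg > -950)) bg <- bg[bg > -950]
  breaks <- seq(min(bg), max(bg) + 1e-9, length.out = 129)
  h <- tabulate(findInterval(bg, breaks, all.inside = TRUE), nbins = 128)
  bg_mode <- (breaks[which.max(h)] + breaks[which.max(h) + 1L]) / 2
  (bg_mode + lesion_mode) / 2
}

voi_centre_ball <- function(d, radius_vox = 3) {
  c0 <- (d + 1) / 2
  z <- seq_len(d[1]) - c0[1]; y <- seq_len(d[2]) - c0[2]; x <- seq_len(d[3]) - c0[3]
  outer(outer(z^2, y^2, "+"), x^2, "+") <= radius_vox^2
}

# connected component of `mask` containing (or nearest to) the VOI centre
seed_component <- function(mask) {
  d <- dim(mask)
  seed <- voi_centre_ball(d, 3)
  comp <- grow_from(mask, seed)
  if (!any(comp)) comp <- largest_component(mask)
  comp
}

#' Hybrid level-set initial segmentation
#'
#' Evolves a clamped level-set function from a 3 mm ball at the VOI centre
#' under a region force (+1 where the intensity is at or above `mu_hu`, -1
#' below) and a curvature force (`curvature_weight` times a discrete
#' mean-curvature proxy). Iteration stops at the budget or when the fraction
#' of voxels changing sign falls below `convergence_tol`; the final mask is
#' the seed-connected component of the positive set. With
#' `curvature_weight = 0` this converges exactly to the seed-connected
#' component of the `>= mu_hu` threshold set.
#'
#' @param voi a 64-cube VOI from [extract_voi()] (any `ggn_volume` works).
#' @param config a [seg_config()].
#' @return Logical mask array with attributes `mu_hu`, `converged` and
#'   `iterations`.
#' @export
hybrid_level_set <- function(voi, config = seg_config()) {
  v <- if (inherits(voi, "ggn_volume")) voi$values else voi
  mu <- config$mu_hu %||% default_mu(v)
  if (!any(v >= mu))
    stop(sprintf("empty target: no voxel at or above mu = %.1f HU", mu))
  d <- dim(v)
  region <- ifelse(v >= mu, 1, -1)
  u <- ifelse(voi_centre_ball(d, 3), 1, -1)
  dt <- 0.5
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(config$levelset_iterations)) {
    iters <- it
    curv <- box_mean3(u) - u
    u_new <- clamp(u + dt * (region + config$curvature_weight * curv), -1, 1)
    changed <- mean((u_new > 0) != (u > 0))
    u <- u_new
    # a sign flip takes ceiling(2/dt) updates, so convergence is only
    # meaningful once the front has had a chance to move
    if (it > 2 / dt && changed < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  mask <- seed_component(u > 0)
  attr(mask, "mu_hu") <- mu
  attr(mask, "converged") <- converged
  attr(mask, "iterations") <- iters
  mask
}

#' Remove vessel voxels from a mask
#'
#' Vessels are extracted by hysteresis on the vesselness map: voxels at or
#' above `vesselness_threshold` seed the vessel set, which then grows through
#' connected voxels at or above `threshold * hysteresis` (vessels are
#' contiguous, so the weak halo around a confident core belongs to the same
#' structure). A deep nodule core — mask voxels more than two 6-connectivity
#' erosions from the boundary — is protected, since an attached vessel can
#' only overlap the peripheral shell. The mask is then post-processed: keep
#' the component connected to the VOI centre (26-connectivity) and fill
#' interior holes (6-connectivity).
#'
#' @param mask logical mask array.
#' @param vesselness array in `[0, 1]` from [frangi_vesselness()], same shape.
#' @param config a [seg_config()].
#' @return Post-processed logical mask.
#' @export
remove_vessels <- function(mask, vesselness, config = seg_config()) {
  stopifnot(all(dim(mask) == dim(vesselness)))
  strong <- vesselness >= config$vesselness_threshold
  if (any(strong)) {
    # a real vessel core is one sizeable, straight, elongated structure;
    # scattered rim responses are small, and curved shell/ring artifacts at a
    # high-contrast nodule boundary fail the linearity test
    lab <- label_equal_components(array(1L, dim(strong)), strong)
    for (lb in unique(lab$label)) {
      vox <- lab$voxel[lab$label == lb]
      drop <- length(vox) < 10
      if (!drop) {
        co <- arrayInd(vox, dim(strong))
        ev <- sort(eigen(stats::cov(co), symmetric = TRUE,
                         only.values = TRUE)$values, decreasing = TRUE)
        drop <- sqrt(max(ev[2], 0) / ev[1]) > 0.4
      }
      if (drop) strong[vox] <- FALSE
    }
  }
  if (any(strong)) {
    weak <- vesselness >= config$vesselness_threshold * config$vesselness_hysteresis
    removed <- grow_from(weak, strong)
    core <- mask
    for (i in 1:2) core <- core & !dilate3(!core, 6L)
    kept <- mask & !(removed & !core)
  } else {
    kept <- mask
  }
  if (!any(kept)) stop("vessel removal emptied the mask")
  fill_holes3(seed_component(kept))
}

#' Segment a nodule in a VOI
#'
#' The full three-step semi-automatic procedure: hybrid level set, Frangi
#' vessel removal, post-processing, and an optional manual mask edit applied
#' as an XOR delta (mimicking specialist correction). The returned mask
#' carries a provenance attribute with the configuration and per-stage
#' statistics.
#'
#' @param voi a VOI volume.
#' @param config a [seg_config()].
#' @param manual_edit optional logical array (same shape); voxels set `TRUE`
#'   are toggled in the automatic result.
#' @return Logical mask with attribute `provenance`.
#' @export
segment_nodule <- function(voi, config = seg_config(), manual_edit = NULL) {
  initial <- hybrid_level_set(voi, config)
  vness <- frangi_vesselness(voi, config)
  mask <- remove_vessels(initial, vness, config)
  if (!is.null(manual_edit)) {
    stopifnot(all(dim(manual_edit) == dim(mask)))
    mask <- xor(mask, manual_edit)
  }
  attr(mask, "provenance") <- list(
    config = config,
    mu_hu = attr(initial, "mu_hu"),
    levelset_converged = attr(initial, "converged"),
    levelset_iterations = attr(initial, "iterations"),
    initial_voxels = sum(initial),
    removed_as_vessel = sum(initial) - sum(initial & (vness < config$vesselness_threshold)),
    final_voxels = sum(mask)
  )
  mask
}

#' Dice overlap between two masks
#'
#' @param a,b logical arrays of identical shape.
#' @return `2|A∩B| / (|A| + |B|)`, or `NA` when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(NA_real_)
  2 * sum(a & b) / s
}

`%||%` <- function(x, y) if (is.null(x)) y else x
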