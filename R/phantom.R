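# Synthetic pGGN phantoms: ellipsoidal ground-glass nodules with optional
# radial warping, low-frequency intra-nodule texture, an optionally attached
# vessel tube, all embedded in noisy lung-parenchyma background and quantized
# to integer HU as CT convention demands.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specify a synthetic ground-glass nodule phantom
#'
#' Parameters describe one pure ground-glass nodule inside a lung-parenchyma
#' background. Defaults emulate the published pGGN cohort statistics: a nodule
#' of about 1.1 cm diameter at a mean attenuation near -723 HU over a -850 HU
#' parenchyma, scanned with a thin slice (1 mm) and sub-millimetre in-plane
#' pixels.
#'
#' @param nodule_radius_mm geometric-mean semi-axis of the nodule (mm).
#' @param nodule_density_hu target mean HU inside the nodule.
#' @param density_sd_hu within-nodule voxel noise SD (HU).
#' @param background_hu,background_sd_hu parenchyma mean and noise SD (HU).
#' @param heterogeneity value in `[0, 1]`; amplitude of a low-frequency
#'   intra-nodule intensity modulation and of the smooth radial warping of the
#'   nodule boundary.
#' @param vessel attach a tangent vessel tube?
#' @param vessel_radius_mm,vessel_density_hu tube radius and attenuation.
#' @param shape_axes_ratio positive triple; relative semi-axes `(z, y, x)`,
#'   internally normalized to geometric mean 1 so `nodule_radius_mm` fixes the
#'   nodule volume.
#' @param volume_shape integer triple, grid size `(z, y, x)`.
#' @param spacing_mm voxel spacing `(z, y, x)` in mm; the default mimics a
#'   thin-slice acquisition (1 mm slices, 0.7 mm pixels).
#' @param seed integer; all phantom randomness flows from it.
#' @return A validated list of class `ggn_phantom_spec`.
#' @export
phantom_spec <- function(nodule_radius_mm = 5.5,
                         nodule_density_hu = -722.7,
                         density_sd_hu = 30,
                         background_hu = -850,
                         background_sd_hu = 25,
                         heterogeneity = 0.3,
                         vessel = FALSE,
                         vessel_radius_mm = 1.5,
                         vessel_density_hu = -600,
                         shape_axes_ratio = c(1, 1, 1),
                         volume_shape = c(72, 108, 108),
                         spacing_mm = c(1, 0.7, 0.7),
                         seed = 1L) {
  spec <- list(
    nodule_radius_mm = nodule_radius_mm, nodule_density_hu = nodule_density_hu,
    density_sd_hu = density_sd_hu, background_hu = background_hu,
    background_sd_hu = background_sd_hu, heterogeneity = heterogeneity,
    vessel = isTRUE(vessel), vessel_radius_mm = vessel_radius_mm,
    vessel_density_hu = vessel_density_hu,
    shape_axes_ratio = as.numeric(shape_axes_ratio),
    volume_shape = as.integer(volume_shape),
    spacing_mm = as.numeric(spacing_mm), seed = as.integer(seed)
  )
  validate_phantom_spec(spec)
  structure(spec, class = "ggn_phantom_spec")
}

phantom_semiaxes <- function(spec) {
  ratio <- spec$shape_axes_ratio / prod(spec$shape_axes_ratio)^(1 / 3)
  spec$nodule_radius_mm * ratio
}

validate_phantom_spec <- function(spec) {
  if (spec$nodule_radius_mm <= 0) stop("nodule_radius_mm must be positive")
  if (spec$density_sd_hu < 0 || spec$background_sd_hu < 0)
    stop("noise standard deviations must be non-negative")
  if (spec$nodule_density_hu <= spec$background_hu)
    stop("nodule_density_hu must exceed background_hu (ground-glass over parenchyma)")
  if (spec$heterogeneity < 0 || spec$heterogeneity > 1)
    stop("heterogeneity must lie in [0, 1]")
  if (any(spec$shape_axes_ratio <= 0)) stop("shape_axes_ratio must be positive")
  if (spec$vessel && spec$vessel_radius_mm <= 0)
    stop("vessel_radius_mm must be positive")
  # the (possibly warped) nodule must fit with a >= 2-voxel margin
  a <- phantom_semiaxes(spec) * (1 + 0.5 * spec$heterogeneity)
  half_extent <- (spec$volume_shape - 1) * spec$spacing_mm / 2
  if (any(a + 2 * spec$spacing_mm > half_extent))
    stop(sprintf(
      "nodule (max extent %.1f mm) does not fit in the volume with a 2-voxel margin",
      max(a)))
  invisible(spec)
}

# smooth unit-variance random field: white noise, Gaussian-filtered, rescaled
smooth_field <- function(shape, sigma_vox) {
  f <- gauss_smooth3(array(stats::rnorm(prod(shape)), shape), sigma_vox)
  f <- f - mean(f)
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

#' Generate one synthetic pGGN phantom
#'
#' Deterministic for a fixed spec and seed. The nodule is an ellipsoid,
#' optionally warped by a smooth radial perturbation whose amplitude grows
#' with `heterogeneity`; interior intensity is the target mean plus Gaussian
#' voxel noise plus a mean-centred low-frequency modulation. If a vessel is
#' requested, a straight tube of the given attenuation is laid tangent to the
#' nodule surface; the tube is *not* part of the ground-truth mask. All
#' intensities are rounded to integer HU.
#'
#' @param spec a [phantom_spec()].
#' @param label invasiveness label carried by the phantom
#'   (`"AIS_MIA"` or `"INVASIVE"`).
#' @return A `ggn_phantom`: list with `volume` ([new_volume()]), logical
#'   `truth_mask` array, `label` and `spec`.
#' @export
generate_phantom <- function(spec, label = c("AIS_MIA", "INVASIVE")) {
  stopifnot(inherits(spec, "ggn_phantom_spec"))
  label <- match.arg(label)
  validate_phantom_spec(spec)
  d <- spec$volume_shape
  sp <- spec$spacing_mm

  with_seed(spec$seed, {
    centre <- (d - 1) * sp / 2
    z <- (seq_len(d[1]) - 1) * sp[1] - centre[1]
    y <- (seq_len(d[2]) - 1) * sp[2] - centre[2]
    x <- (seq_len(d[3]) - 1) * sp[3] - centre[3]
    a <- phantom_semiaxes(spec)
    U2 <- outer(outer((z / a[1])^2, (y / a[2])^2, "+"), (x / a[3])^2, "+")
    u <- sqrt(U2)

    if (spec$heterogeneity > 0) {
      pert <- clamp(smooth_field(d, 4 / mean(sp)), -2.5, 2.5)
      u <- u / (1 + 0.2 * spec$heterogeneity * pert)   # warped radius
    }
    truth <- u <= 1

    vol <- array(spec$background_hu, d)
    if (spec$background_sd_hu > 0)
      vol <- vol + stats::rnorm(prod(d), sd = spec$background_sd_hu)

    # ground-glass edge haze: a sigmoid radial profile (in the warped radius)
    # whose width grows with heterogeneity (hard edge in the homogeneous
    # limit), recentred so the in-mask mean equals the target density exactly
    contrast <- spec$nodule_density_hu - spec$background_hu
    edge_w <- 0.08 * spec$heterogeneity
    profile <- if (edge_w > 0) {
      1 / (1 + exp((u - 1) / edge_w))
    } else {
      (u <= 1) * 1
    }
    nod <- spec$background_hu + contrast * profile
    nod <- nod + (spec$nodule_density_hu - mean(nod[truth]))
    if (spec$density_sd_hu > 0)
      nod <- nod + stats::rnorm(prod(d), sd = spec$density_sd_hu)
    if (spec$heterogeneity > 0) {
      h <- smooth_field(d, 3 / mean(sp))
      h_in <- h[truth]
      h <- (h - mean(h_in)) / max(stats::sd(h_in), 1e-12)
      nod <- nod + 60 * spec$heterogeneity * h
    }
    vol[truth] <- nod[truth]

    if (spec$vessel) {
      w <- stats::rnorm(3); w <- w / sqrt(sum(w^2))
      t_surf <- 1 / sqrt(sum((w / a)^2))
      p <- t_surf * w                          # tangent point on the ellipsoid
      tv <- stats::rnorm(3)
      tv <- tv - sum(tv * w) * w               # tube axis perpendicular to w
      tv <- tv / sqrt(sum(tv^2))
      Pz <- outer(outer(z - p[1], rep(1, d[2])), rep(1, d[3]))
      Py <- outer(outer(rep(1, d[1]), y - p[2]), rep(1, d[3]))
      Px <- outer(outer(rep(1, d[1]), rep(1, d[2])), x - p[3])
      proj <- Pz * tv[1] + Py * tv[2] + Px * tv[3]
      dist2 <- (Pz - proj * tv[1])^2 + (Py - proj * tv[2])^2 + (Px - proj * tv[3])^2
      vessel_mask <- dist2 <= spec$vessel_radius_mm^2 & !truth
      vol[vessel_mask] <- spec$vessel_density_hu
    } else {
      vessel_mask <- NULL
    }

    vol <- round(vol)                           # integer HU, CT convention
    out <- structure(
      list(volume = new_volume(vol, spacing_mm = sp),
           truth_mask = truth, label = label, spec = spec),
      class = "ggn_phantom"
    )
    if (!is.null(vessel_mask)) attr(out, "vessel_mask") <- vessel_mask
    out
  })
}

#' @export
print.ggn_phantom <- function(x, ...) {
  cat(sprintf("<ggn_phantom> label %s, %d mask voxels, nodule %.1f mm @ %.1f HU\n",
              x$label, sum(x$truth_mask), x$spec$nodule_radius_mm,
              x$spec$nodule_density_hu))
  invisible(x)
}

default_class_effects <- function() {
  # invasive nodules are larger, denser, more heterogeneous (cohort Table-level
  # contrast: diameters 1.1 vs 1.3 cm, densities -727.0 vs -691.0 HU)
  list(radius_mm = 1.0, radius_sd_mm = 1.0,
       density_hu = 36.0, density_sd_hu = -1.2,
       heterogeneity = 0.15)
}

#' Generate a labelled cohort of phantoms
#'
#' Draws per-patient nodule size and density from class-specific normal
#' distributions and renders one phantom per patient. The non-invasive class
#' is centred on a 1.1 cm / -727 HU nodule (between-patient SDs 0.4 cm and
#' 46.3 HU); `class_effects` shifts the invasive class (defaults: +2 mm
#' diameter, +36 HU, +0.15 heterogeneity, slightly wider size spread). Setting
#' all effects to zero makes the two classes exchangeable.
#'
#' @param n cohort size (>= 2).
#' @param invasive_fraction fraction in `(0, 1)`; `round(n * invasive_fraction)`
#'   phantoms are labelled `INVASIVE`.
#' @param class_effects named list of additive deltas applied to the invasive
#'   class: `radius_mm`, `radius_sd_mm`, `density_hu`, `density_sd_hu`,
#'   `heterogeneity`.
#' @param seed master seed; per-phantom seeds are derived from it.
#' @param base_spec template [phantom_spec()] (geometry, noise, grid).
#' @return A list of `ggn_phantom` objects (class `ggn_cohort`); see
#'   [cohort_table()] for the tabular view.
#' @export
generate_cohort_phantoms <- function(n, invasive_fraction = 77 / 338,
                                     class_effects = default_class_effects(),
                                     seed = 1L,
                                     base_spec = phantom_spec()) {
  stopifnot(n >= 2, invasive_fraction > 0, invasive_fraction < 1)
  n_inv <- round(n * invasive_fraction)
  if (n_inv == 0L || n_inv == n)
    stop("degenerate cohort: round(n * invasive_fraction) is 0 or n")
  eff <- utils::modifyList(default_class_effects(), as.list(class_effects))

  base <- list(radius_mm = 5.5, radius_sd_mm = 2.0,
               density_hu = -727.0, density_sd_hu = 46.3,
               heterogeneity = 0.25)
  labels <- rep(c("INVASIVE", "AIS_MIA"), c(n_inv, n - n_inv))

  # truncation keeps every drawn nodule inside the template grid
  half_extent <- (base_spec$volume_shape - 1) * base_spec$spacing_mm / 2
  ratio <- base_spec$shape_axes_ratio / prod(base_spec$shape_axes_ratio)^(1 / 3)
  h_max <- clamp(base$heterogeneity + max(0, eff$heterogeneity), 0, 1)
  r_max <- min((half_extent - 2 * base_spec$spacing_mm) /
                 (ratio * (1 + 0.5 * h_max)))

  with_seed(seed, {
    phantom_seeds <- sample.int(.Machine$integer.max - 1L, n)
    radii <- stats::rnorm(n)
    densities <- stats::rnorm(n)
    cohort <- vector("list", n)
    for (i in seq_len(n)) {
      inv <- labels[i] == "INVASIVE"
      r_mu <- base$radius_mm + if (inv) eff$radius_mm else 0
      r_sd <- max(0, base$radius_sd_mm + if (inv) eff$radius_sd_mm else 0)
      d_mu <- base$density_hu + if (inv) eff$density_hu else 0
      d_sd <- max(0, base$density_sd_hu + if (inv) eff$density_sd_hu else 0)
      h <- clamp(base$heterogeneity + if (inv) eff$heterogeneity else 0, 0, 1)
      r_i <- clamp(r_mu + r_sd * radii[i], 2.5, r_max)
      den_i <- clamp(d_mu + d_sd * densities[i],
                     base_spec$background_hu + 40, -550)
      spec_i <- phantom_spec(
        nodule_radius_mm = r_i, nodule_density_hu = den_i,
        density_sd_hu = base_spec$density_sd_hu,
        background_hu = base_spec$background_hu,
        background_sd_hu = base_spec$background_sd_hu,
        heterogeneity = h, vessel = base_spec$vessel,
        vessel_radius_mm = base_spec$vessel_radius_mm,
        vessel_density_hu = base_spec$vessel_density_hu,
        shape_axes_ratio = base_spec$shape_axes_ratio,
        volume_shape = base_spec$volume_shape,
        spacing_mm = base_spec$spacing_mm,
        seed = phantom_seeds[i]
      )
      cohort[[i]] <- generate_phantom(spec_i, label = labels[i])
      cohort[[i]]$patient_id <- sprintf("P%03d", i)
    }
    structure(cohort, class = "ggn_cohort")
  })
}

#' Tabular view of a phantom cohort
#'
#' @param cohort result of [generate_cohort_phantoms()].
#' @return A tibble with one row per phantom: id, label, nodule radius and
#'   density, heterogeneity, seed, and the observed within-mask mean HU.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "ggn_cohort"))
  purrr::map_dfr(cohort, function(p) {
    tibble::tibble(
      patient_id = p$patient_id,
      label = p$label,
      nodule_radius_mm = p$spec$nodule_radius_mm,
      nodule_density_hu = p$spec$nodule_density_hu,
      heterogeneity = p$spec$heterogeneity,
      seed = p$spec$seed,
      mean_hu_in_mask = mean(p$volume$values[p$truth_mask])
    )
  })
}
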