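# Hybrid level set, Frangi vesselness, vessel removal and the composed
# segmentation, checked against phantom ground truth and noiseless oracles.

noiseless_sphere_voi <- function(radius = 8, hu = -650, bg = -850, d = 64) {
  p <- generate_phantom(phantom_spec(
    nodule_radius_mm = radius, nodule_density_hu = hu, background_hu = bg,
    density_sd_hu = 0, background_sd_hu = 0, heterogeneity = 0,
    volume_shape = c(d, d, d), spacing_mm = c(1, 1, 1), seed = 1))
  list(voi = new_volume(p$volume$values, c(1, 1, 1)), truth = p$truth_mask)
}

test_that("level set recovers a noiseless sphere almost exactly", {
  s <- noiseless_sphere_voi()
  m <- hybrid_level_set(s$voi, seg_config(mu_hu = -750))
  expect_gte(dice(m, s$truth), 0.95)
})

test_that("a VOI entirely below mu is an empty-target error", {
  voi <- new_volume(array(-900, c(16, 16, 16)), c(1, 1, 1))
  expect_error(hybrid_level_set(voi, seg_config(mu_hu = -750)), "empty target")
})

test_that("zero curvature reduces to the seed-connected threshold component", {
  s <- noiseless_sphere_voi()
  m <- hybrid_level_set(s$voi, seg_config(mu_hu = -750, curvature_weight = 0))
  thr <- s$voi$values >= -750
  ref <- ggnrad:::grow_from(thr, ggnrad:::voi_centre_ball(dim(thr), 3))
  expect_identical(as.vector(m), as.vector(ref))
})

test_that("raising mu never enlarges the mask on two-level phantoms", {
  s <- noiseless_sphere_voi()
  sizes <- vapply(c(-800, -750, -700, -660), function(mu)
    sum(hybrid_level_set(s$voi, seg_config(mu_hu = mu))), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("vesselness of a constant VOI is zero and always within [0, 1]", {
  flat <- new_volume(array(-800, c(32, 32, 32)), c(1, 1, 1))
  expect_equal(max(frangi_vesselness(flat)), 0)
  set.seed(4)
  noisy <- new_volume(array(rnorm(32^3, -800, 30), c(32, 32, 32)), c(1, 1, 1))
  vn <- frangi_vesselness(noisy)
  expect_gte(min(vn), 0)
  expect_lte(max(vn), 1)
})

test_that("tubes score higher vesselness than blobs of equal contrast", {
  d <- 48; cc <- 24.5
  mk <- function(type) {
    arr <- array(-850, c(d, d, d))
    z <- slice.index(arr, 1) - cc; y <- slice.index(arr, 2) - cc
    x <- slice.index(arr, 3) - cc
    if (type == "cyl") arr[(y^2 + x^2) <= 1.5^2] <- -600
    else arr[(z^2 + y^2 + x^2) <= 6^2] <- -600
    new_volume(arr, c(1, 1, 1))
  }
  vc <- frangi_vesselness(mk("cyl"))
  vb <- frangi_vesselness(mk("ball"))
  axis_scores <- vc[, 24, 24]
  expect_gt(median(axis_scores), vb[24, 24, 24])
})

test_that("vessel removal is a no-op without vessel signal", {
  s <- noiseless_sphere_voi()
  m <- hybrid_level_set(s$voi, seg_config(mu_hu = -750))
  zero <- array(0, dim(m))
  expect_equal(sum(xor(remove_vessels(m, zero), m)), 0)
  # threshold 1.0: only post-processing
  set.seed(2)
  vn <- array(runif(length(m)) * 0.99, dim(m))
  out <- remove_vessels(m, vn, seg_config(vesselness_threshold = 1))
  expect_equal(sum(xor(out, m)), 0)
})

test_that("attached tubes are removed while the nodule is retained", {
  for (s in c(11, 13)) {
    ph <- generate_phantom(phantom_spec(vessel = TRUE, seed = s))
    voi <- phantom_voi(ph)
    truth <- phantom_mask_in_voi(ph, ph$truth_mask)
    vess <- phantom_mask_in_voi(ph, attr(ph, "vessel_mask"))
    initial <- hybrid_level_set(voi)
    vn <- frangi_vesselness(voi)
    cleaned <- remove_vessels(initial, vn)
    tube_in <- initial & vess
    expect_gte(sum(!cleaned & tube_in) / sum(tube_in), 0.8)
    expect_gte(sum(cleaned & truth) / sum(initial & truth), 0.95)
  }
})

test_that("vessel removal changes few voxels on vessel-free phantoms", {
  for (s in 1:3) {
    ph <- generate_phantom(phantom_spec(seed = s))
    voi <- phantom_voi(ph)
    initial <- hybrid_level_set(voi)
    cleaned <- remove_vessels(initial, frangi_vesselness(voi))
    expect_lte(sum(xor(cleaned, initial)) / sum(initial), 0.02)
  }
})

test_that("segment_nodule hits Dice >= 0.90 on default phantoms", {
  ds <- vapply(1:6, function(s) {
    ph <- generate_phantom(phantom_spec(seed = s))
    voi <- phantom_voi(ph)
    dice(segment_nodule(voi), phantom_mask_in_voi(ph, ph$truth_mask))
  }, numeric(1))
  expect_true(all(ds >= 0.90))
})

test_that("segmented volume tracks the analytic ellipsoid volume", {
  for (ratio in list(c(1, 1, 1), c(1.4, 1, 0.8), c(0.7, 1.2, 1.2))) {
    p <- generate_phantom(phantom_spec(
      nodule_radius_mm = 8, nodule_density_hu = -650, density_sd_hu = 0,
      background_sd_hu = 0, heterogeneity = 0, shape_axes_ratio = ratio,
      volume_shape = c(64, 64, 64), spacing_mm = c(1, 1, 1), seed = 1))
    voi <- new_volume(p$volume$values, c(1, 1, 1))
    m <- hybrid_level_set(voi, seg_config(mu_hu = -750))
    expect_lt(abs(sum(m) - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.10)
  }
})

test_that("manual edits toggle voxels and runs are deterministic", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  voi <- phantom_voi(ph)
  auto <- segment_nodule(voi)
  delta <- array(FALSE, dim(auto))
  delta[30:34, 30:34, 30:34] <- TRUE
  edited <- segment_nodule(voi, manual_edit = delta)
  expect_identical(as.vector(edited), as.vector(xor(auto, delta)))
  again <- segment_nodule(voi)
  expect_identical(as.vector(auto), as.vector(again))
  prov <- attr(auto, "provenance")
  expect_true(is.list(prov$config) || inherits(prov$config, "ggn_seg_config"))
  expect_true(is.numeric(prov$mu_hu))
})
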