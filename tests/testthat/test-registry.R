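# Registry conformance: 404 deterministic named features, published-table
# names resolvable, manifest consistency.

test_that("the default registry declares 404 unique features", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 404L)
  expect_identical(anyDuplicated(reg$name), 0L)
  expect_error(feature_registry("v0"), "unknown registry")
})

test_that("feature names in the registry match what the extractors emit", {
  set.seed(10)
  arr <- array(rnorm(8^3, -700, 50), c(8, 8, 8))
  mask <- digital_mask <- array(FALSE, c(8, 8, 8)); mask[2:7, 2:7, 2:7] <- TRUE
  q <- quantize(arr, mask, 8)
  expect_setequal(paste0("original_glcm_", names(glcm_features(glcm_compute(q)))),
                  feature_registry()$name[feature_registry()$family == "glcm" &
                                            feature_registry()$variant == "original"])
  expect_setequal(paste0("original_glrlm_", names(glrlm_features(glrlm_compute(q)))),
                  feature_registry()$name[feature_registry()$family == "glrlm" &
                                            feature_registry()$variant == "original"])
  expect_setequal(paste0("original_glszm_", names(glszm_features(glszm_compute(q)))),
                  feature_registry()$name[feature_registry()$family == "glszm" &
                                            feature_registry()$variant == "original"])
  expect_setequal(paste0("morphology_", names(morphology_features(mask))),
                  feature_registry()$name[feature_registry()$family == "morphology"])
  expect_setequal(paste0("original_histogram_", names(histogram_features(arr, mask))),
                  feature_registry()$name[feature_registry()$family == "histogram" &
                                            feature_registry()$variant == "original"])
})

test_that("extraction yields 404 finite features, twice identically", {
  ph <- generate_phantom(phantom_spec(seed = 21))
  voi <- phantom_voi(ph)
  mask <- phantom_mask_in_voi(ph, ph$truth_mask)
  fv1 <- extract_features(voi, mask)
  expect_identical(ncol(fv1), 404L)
  expect_identical(names(fv1), feature_registry()$name)
  expect_true(all(is.finite(unlist(fv1))))
  fv2 <- extract_features(voi, mask)
  expect_identical(fv1, fv2)
})

test_that("every published feature-table row label resolves to one feature", {
  map <- table4_features()
  expect_identical(nrow(map), 26L)
  expect_identical(anyDuplicated(map$label), 0L)
  expect_true(all(map$feature %in% feature_registry()$name))
})

test_that("degenerate masks record missing families with reasons", {
  arr <- array(rnorm(6^3, -700, 10), c(6, 6, 6))
  lone <- array(FALSE, c(6, 6, 6)); lone[3, 3, 3] <- TRUE
  fv <- extract_features(arr, lone)
  expect_identical(ncol(fv), 404L)
  miss <- attr(fv, "missing")
  expect_true("morphology" %in% names(miss))
  expect_true(any(is.na(unlist(fv))))
})

test_that("the shipped manifest matches the in-code registry", {
  path <- system.file("extdata", "registry_v1.yaml", package = "ggnrad")
  expect_true(nzchar(path))
  man <- yaml::read_yaml(path)
  expect_identical(man$n_features, 404L)
  expect_identical(vapply(man$features, `[[`, "", "name"),
                   feature_registry()$name)
})

test_that("texture and shape features ignore a global HU shift", {
  ph <- generate_phantom(phantom_spec(seed = 3, volume_shape = c(48, 64, 64)))
  voi <- phantom_voi(ph, size = 48)
  mask <- phantom_mask_in_voi(ph, ph$truth_mask, size = 48)
  a <- extract_features(voi, mask)
  voi_shift <- new_volume(voi$values + 50, voi$spacing_mm)
  b <- extract_features(voi_shift, mask)
  reg <- feature_registry()
  texture <- reg$name[reg$family %in% c("glcm", "glrlm", "glszm") |
                        reg$family == "morphology"]
  expect_equal(as.numeric(b[texture]), as.numeric(a[texture]), tolerance = 1e-8)
  expect_equal(b[["original_histogram_P75"]],
               a[["original_histogram_P75"]] + 50, tolerance = 1e-8)
})
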