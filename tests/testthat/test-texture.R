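# Quantization and the three texture matrix families, against closed-form
# examples and brute-force enumeration oracles.

test_that("quantization follows the stated edge rule", {
  arr <- array(0, c(3, 1, 1)); arr[, 1, 1] <- c(-800, -700, -600)
  mask <- array(TRUE, c(3, 1, 1))
  expect_identical(quantize(arr, mask, 2)$levels[mask], c(1L, 2L, 2L))
  # shift invariance
  q1 <- quantize(arr, mask, 2)
  q2 <- quantize(arr + 123.4, mask, 2)
  expect_identical(q1$levels, q2$levels)
  # constant image: everything level 1
  expect_true(all(quantize(array(5, c(2, 2, 2)),
                           array(TRUE, c(2, 2, 2)), 8)$levels == 1L))
  expect_error(quantize(arr, mask, 1), "at least 2")
  expect_error(quantize(arr, array(FALSE, c(3, 1, 1)), 2), "empty")
})

test_that("GLCM pair counts match the worked single-slice example", {
  lv <- array(NA_integer_, c(1, 2, 3))
  lv[1, 1, ] <- c(1L, 1L, 2L); lv[1, 2, ] <- c(2L, 2L, 1L)
  q <- quantized_from(lv, 2)
  m <- glcm_compute(q, offsets = matrix(c(0, 0, 1), 1))
  expect_equal(m$p, matrix(0.25, 2, 2))
  f <- glcm_features(m)
  expect_equal(unname(f["Contrast"]), 0.5)
  expect_equal(unname(f["Homogeneity"]), 0.75)
  expect_equal(unname(f["ClusterShade"]), 0)
})

test_that("GLCM degenerate and diagonal matrices behave", {
  q <- quantize(array(7, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 4)
  f <- glcm_features(glcm_compute(q))
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Homogeneity"]), 1)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["ClusterShade"]), 0)
  # perfectly diagonal two-level matrix: correlation 1
  lv <- array(NA_integer_, c(1, 1, 4)); lv[1, 1, ] <- c(1L, 1L, 2L, 2L)
  m <- glcm_compute(quantized_from(lv, 2), offsets = matrix(c(0, 0, 1), 1))
  # pairs (1,1), (1,2), (2,2) -> not perfectly diagonal; build directly
  md <- list(p = diag(c(0.5, 0.5)))
  expect_equal(unname(glcm_features(md)["Correlation"]), 1)
  # symmetry holds for any input
  set.seed(1)
  qr <- random_quantized(c(4, 4, 4), 3)
  expect_equal(glcm_compute(qr)$p, t(glcm_compute(qr)$p))
  # single in-mask voxel admits no pair
  lone <- array(NA_integer_, c(3, 3, 3)); lone[2, 2, 2] <- 1L
  expect_error(glcm_compute(quantized_from(lone, 2)), "no voxel pair")
})

test_that("GLRLM run statistics match closed-form rows", {
  # constant row of length 4: one run, variance 0
  lv <- array(NA_integer_, c(1, 1, 4)); lv[1, 1, ] <- 1L
  m <- glrlm_compute(quantized_from(lv, 2))
  along <- which(apply(m$directions, 1, function(d) all(d == c(0, 0, 1))))
  expect_equal(m$per_direction[[along]][1, 4], 1)
  expect_equal(sum(m$per_direction[[along]]), 1)
  f1 <- ggnrad:::glrlm_features_one(m$per_direction[[along]], m$n_voxels)
  expect_equal(unname(f1["RunLengthVariance"]), 0)
  # alternating 1,2,1,2: four unit runs in every direction touching the row
  lv2 <- array(NA_integer_, c(1, 1, 4)); lv2[1, 1, ] <- c(1L, 2L, 1L, 2L)
  f <- glrlm_features(glrlm_compute(quantized_from(lv2, 2)))
  expect_equal(unname(f["ShortRunEmphasis"]), 1)
  expect_equal(unname(f["LongRunEmphasis"]), 1)
  expect_equal(unname(f["RunLengthVariance"]), 0)
})

test_that("GLSZM zones match closed-form cases", {
  # constant cube: one zone of size 27, LargeAreaEmphasis 27^2
  q <- quantize(array(1, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 2)
  f <- glszm_features(glszm_compute(q))
  expect_equal(unname(f["LargeAreaEmphasis"]), 729)
  expect_equal(unname(f["SmallAreaEmphasis"]), 1 / 729)
  # two disjoint single-voxel zones: SmallAreaEmphasis 1
  lv <- array(NA_integer_, c(3, 3, 3))
  lv[1, 1, 1] <- 1L; lv[3, 3, 3] <- 2L
  f2 <- glszm_features(glszm_compute(quantized_from(lv, 2)))
  expect_equal(unname(f2["SmallAreaEmphasis"]), 1)
  # voxel conservation invariant
  set.seed(2)
  qr <- random_quantized(c(5, 5, 5), 4)
  m <- glszm_compute(qr)
  sizes <- matrix(seq_len(ncol(m$counts)), nrow(m$counts), ncol(m$counts),
                  byrow = TRUE)
  expect_equal(sum(sizes * m$counts), sum(qr$mask))
})

test_that("texture matrices match brute-force enumeration on random images", {
  set.seed(31)
  for (rep in 1:12) {
    shape <- sample(3:6, 3, replace = TRUE)
    nl <- sample(2:6, 1)
    q <- random_quantized(shape, nl)
    expect_equal(glcm_compute(q)$p,
                 oracle_glcm_matrix(q$levels, q$mask, nl), tolerance = 1e-12)
    got <- glrlm_compute(q)
    want <- oracle_glrlm_matrices(q$levels, q$mask, nl)
    for (k in seq_along(want)) {
      nc <- ncol(want[[k]])
      expect_equal(got$per_direction[[k]][, 1:nc, drop = FALSE][, ],
                   want[[k]][, ], tolerance = 1e-12)
      if (ncol(got$per_direction[[k]]) > nc)
        expect_true(all(got$per_direction[[k]][, (nc + 1):ncol(got$per_direction[[k]])] == 0))
    }
    mz <- glszm_compute(q)
    oz <- oracle_glszm_matrix(q$levels, q$mask, nl)
    expect_equal(mz$counts[, seq_len(ncol(oz)), drop = FALSE][, ], oz[, ],
                 tolerance = 1e-12)
  }
})

test_that("pooled texture features are invariant to axis-aligned rotations", {
  set.seed(5)
  arr <- array(rnorm(6^3, -700, 40), c(6, 6, 6))
  mask <- array(runif(6^3) < 0.9, c(6, 6, 6))
  feats <- function(a, m) {
    q <- quantize(a, m, 8)
    c(glcm_features(glcm_compute(q)), glrlm_features(glrlm_compute(q)),
      glszm_features(glszm_compute(q)))
  }
  base <- feats(arr, mask)
  rot <- function(a) aperm(a, c(2, 1, 3))[rev(seq_len(dim(a)[2])), , , drop = FALSE]
  expect_equal(feats(rot(arr), rot(mask)), base, tolerance = 1e-9)
  rot2 <- function(a) aperm(a, c(1, 3, 2))[, rev(seq_len(dim(a)[3])), , drop = FALSE]
  expect_equal(feats(rot2(arr), rot2(mask)), base, tolerance = 1e-9)
})
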