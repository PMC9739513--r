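# Volume I/O, isotropic resampling, VOI extraction.

test_that("NIfTI and NRRD round trips preserve values and spacing", {
  vol <- new_volume(array(rnorm(3 * 4 * 5, -700, 50), c(3, 4, 5)),
                    spacing_mm = c(1.25, 0.7, 0.7))
  for (ext in c(".nii.gz", ".nrrd")) {
    path <- withr::local_tempfile(fileext = ext)
    write_volume(vol, path)
    back <- read_volume(path)
    expect_equal(back$values, vol$values, tolerance = 1e-7)
    expect_equal(back$spacing_mm, vol$spacing_mm, tolerance = 1e-6)
  }
})

test_that("non-3D input is rejected", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), path)
  expect_error(read_volume(path), "3D")
  expect_error(new_volume(array(0, c(2, 2)), c(1, 1, 1)), "3D")
})

test_that("NRRD axis order converts to the internal (z,y,x) convention", {
  # NRRD stores x fastest with spacings (x, y, z) = (0.7, 0.7, 1.25)
  path <- withr::local_tempfile(fileext = ".nrrd")
  con <- file(path, "wb")
  writeLines(c("NRRD0004", "type: double", "dimension: 3",
               "sizes: 2 3 4", "spacings: 0.7 0.7 1.25",
               "endian: little", "encoding: raw", ""), con)
  writeBin(as.numeric(1:24), con, size = 8, endian = "little")
  close(con)
  vol <- read_volume(path)
  expect_equal(vol$spacing_mm, c(1.25, 0.7, 0.7))
  expect_equal(dim(vol$values), c(4L, 3L, 2L))
  # first on-disk value is voxel (x=1, y=1, z=1)
  expect_equal(vol$values[1, 1, 1], 1)
  expect_equal(vol$values[1, 1, 2], 2)  # second fastest-axis (x) sample
})

test_that("resampling an already isotropic volume is the identity", {
  vol <- new_volume(array(rnorm(6^3), c(6, 6, 6)), spacing_mm = c(1, 1, 1))
  out <- resample_isotropic(vol)
  expect_equal(out$values, vol$values)
  # idempotence for a genuinely resampled volume
  aniso <- new_volume(array(rnorm(5 * 7 * 9), c(5, 7, 9)),
                      spacing_mm = c(1.6, 0.8, 0.6))
  once <- resample_isotropic(aniso)
  twice <- resample_isotropic(once)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
})

test_that("trilinear resampling reproduces affine intensity fields exactly", {
  d <- c(9, 9, 9)
  z <- (seq_len(d[1]) - 1) * 2; y <- (seq_len(d[2]) - 1) * 2
  x <- (seq_len(d[3]) - 1) * 2
  ramp <- outer(outer(3 * z, 2 * y, `+`), -1 * x, `+`)
  out <- resample_isotropic(new_volume(ramp, spacing_mm = c(2, 2, 2)))
  dd <- dim(out$values)
  zz <- (seq_len(dd[1]) - 1); yy <- (seq_len(dd[2]) - 1); xx <- (seq_len(dd[3]) - 1)
  expected <- outer(outer(3 * zz, 2 * yy, `+`), -1 * xx, `+`)
  expect_equal(out$values, expected, tolerance = 1e-12)
})

test_that("an interior point matches the 8-neighbour trilinear oracle", {
  set.seed(7)
  vol <- new_volume(array(rnorm(9^3), c(9, 9, 9)), spacing_mm = c(2, 2, 2))
  out <- resample_isotropic(vol)
  # output voxel (6,6,6) sits at 5 mm = input index 3.5 on every axis
  v <- vol$values
  w <- 0.5
  oracle <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    oracle <- oracle + v[3 + dz, 3 + dy, 3 + dx] * 0.5^3
  expect_equal(out$values[6, 6, 6], oracle, tolerance = 1e-12)
})

test_that("resampled values stay inside the input range", {
  set.seed(8)
  vol <- new_volume(array(rnorm(8 * 10 * 12), c(8, 10, 12)),
                    spacing_mm = c(1.1, 0.63, 0.87))
  out <- resample_isotropic(vol)
  expect_gte(min(out$values), min(vol$values))
  expect_lte(max(out$values), max(vol$values))
})

test_that("VOI extraction crops, pads and re-embeds correctly", {
  set.seed(9)
  vol <- new_volume(array(rnorm(128^3 / 8, -800, 100), c(64, 64, 64)),
                    spacing_mm = c(1, 1, 1))
  # corner seed: mostly padding
  voi <- extract_voi(vol, c(1, 1, 1))
  expect_equal(dim(voi$values), c(64L, 64L, 64L))
  expect_equal(voi$values[1, 1, 1], -1000)
  # centre seed of a large volume: pure crop
  big <- new_volume(array(rnorm(96^3), c(96, 96, 96)), spacing_mm = c(1, 1, 1))
  ctr <- c(48, 48, 48)
  voi2 <- extract_voi(big, ctr)
  off <- attr(voi2, "source_offset")
  expect_equal(voi2$values,
               big$values[(off[1] + 1):(off[1] + 64),
                          (off[2] + 1):(off[2] + 64),
                          (off[3] + 1):(off[3] + 64)])
  # seed lands at output index 32
  expect_equal(voi2$values[32, 32, 32], big$values[48, 48, 48])
  expect_error(extract_voi(big, c(0, 4, 4)), "outside")
  aniso <- new_volume(array(0, c(8, 8, 8)), spacing_mm = c(2, 1, 1))
  expect_error(extract_voi(aniso, c(4, 4, 4)), "isotropic")
})
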