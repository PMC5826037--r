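test_that("NIfTI round-trip preserves data, voxel size and bit depth", {
  set.seed(11)
  a <- array(sample(c(0, 100, 30000, 65535), 3 * 4 * 5, replace = TRUE),
             c(3, 4, 5))
  v <- mia_volume(a, voxel_size_um = 7.86, bit_depth = 16)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_identical(r$data, v$data)
  expect_lt(abs(r$voxel_size_um - 7.86) / 7.86, 1e-6)
  expect_identical(max(r$data), max(v$data))  # no rescaling
})

test_that("TIFF round-trip preserves data with a voxel-size override", {
  a <- array(c(0, 1, 255, 7), c(2, 3, 3))
  v <- mia_volume(a, voxel_size_um = 22.6, bit_depth = 8)
  f <- tempfile(fileext = ".tif")
  write_volume(v, f)
  expect_error(read_volume(f), "voxel size")
  r <- read_volume(f, voxel_size_um = 22.6)
  expect_identical(r$data, v$data)
  expect_equal(r$voxel_size_um, 22.6)
})

test_that("label volumes round-trip exactly in both formats", {
  lab <- mia_labels(array(rep(0:3, length.out = 27), c(3, 3, 3)),
                    n_classes = 3, voxel_size_um = 5)
  for (ext in c(".nii", ".tif")) {
    f <- tempfile(fileext = ext)
    write_volume(lab, f)
    r <- read_labels(f, voxel_size_um = 5)
    expect_identical(r$labels, lab$labels)
  }
})

test_that("membership channels round-trip within 1e-6", {
  u <- array(c(0, 0.5, 1, 0.25), c(2, 2, 2))
  u[2, 2, 2] <- 0.125
  for (ext in c(".nii", ".tif")) {
    f <- tempfile(fileext = ext)
    write_volume(u, f, voxel_size_um = 1)
    r <- read_volume(f, voxel_size_um = 1)
    expect_lt(max(abs(r$data - u)), 1e-6)
  }
})

test_that("insufficient dimensionality and anisotropy are rejected", {
  f2d <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(1, 4, 4)), f2d)
  expect_error(read_volume(f2d), "3D")

  fa <- tempfile(fileext = ".nii")
  img <- RNifti::asNifti(array(1, c(3, 3, 3)))
  RNifti::pixdim(img) <- c(1, 1, 2)
  RNifti::writeNifti(img, fa)
  expect_error(read_volume(fa), "[Aa]nisotropic")
})

test_that("4D volumes with a trailing singleton are squeezed", {
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(1:24, c(2, 3, 4, 1))), f)
  r <- read_volume(f, voxel_size_um = 1)
  expect_identical(dim(r$data), c(2L, 3L, 4L))
})

test_that("voxel-size override wins over the header, with a warning", {
  v <- mia_volume(array(7, c(3, 3, 3)), voxel_size_um = 5)
  f <- tempfile(fileext = ".nii")
  write_volume(v, f)
  expect_equal(read_volume(f)$voxel_size_um, 5)
  expect_warning(r <- read_volume(f, voxel_size_um = 7.86), "override")
  expect_equal(r$voxel_size_um, 7.86)
})

test_that("corrupt files and invalid construction are rejected", {
  f <- tempfile(fileext = ".nii")
  writeLines("not an image", f)
  suppressWarnings(expect_error(read_volume(f), "cannot read"))
  expect_error(mia_volume(array(-1, c(2, 2, 2)), 1), "non-negative")
  expect_error(mia_volume(array(300, c(2, 2, 2)), 1, bit_depth = 8), "bit_depth")
  expect_error(mia_volume(array(1, c(2, 2, 2)), -1), "positive")
})
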