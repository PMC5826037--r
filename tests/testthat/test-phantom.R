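test_that("a clean coiled plate has two levels and an exact truth mask", {
  ph <- make_phantom(phantom_spec("plate_coil", shape = c(8, 64, 64),
                                  thickness_vox = 5, seed = 1))
  vals <- sort(unique(as.vector(ph$volume$data)))
  expect_identical(vals, c(0, 30000))
  expect_identical(ph$true_mask, ph$volume$data == 30000)
  expect_identical(ph$true_labels$labels, array(ifelse(ph$true_mask, 2L, 1L),
                                                dim(ph$true_mask)))
})

test_that("phantom generation is deterministic in the seed", {
  sp <- phantom_spec("plate_coil", shape = c(6, 48, 48), thickness_vox = 3,
                     noise_sd = 1000, inclusion_density = 0.001, seed = 9)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  sp2 <- sp; sp2$seed <- 10L
  c2 <- make_phantom(sp2)
  expect_false(identical(a$volume$data, c2$volume$data))
  expect_identical(a$true_mask, c2$true_mask)   # geometry is seed-free
  # the caller's RNG stream is untouched
  set.seed(123); r1 <- runif(3)
  set.seed(123); invisible(make_phantom(sp)); r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("coil ground truth measures its nominal thickness", {
  for (t in c(3, 5)) {
    ph <- make_phantom(phantom_spec("plate_coil", shape = c(8, 72, 72),
                                    thickness_vox = t, seed = 2))
    th <- local_thickness(ph$true_mask, 1)
    expect_lte(abs(th$mean_vox - t), 0.5)
  }
})

test_that("trabecular lattice is connected across the volume and t thick", {
  ph <- make_phantom(phantom_spec("trabecular_lattice", shape = c(24, 24, 24),
                                  thickness_vox = 3, seed = 1))
  expect_true(any(ph$true_mask[1, , ]) && any(ph$true_mask[24, , ]))
  th <- local_thickness(ph$true_mask, 1)
  expect_lte(abs(median(th$thickness_map[ph$true_mask]) - 3), 1)
})

test_that("fossil phantom orders its phases and applies artifacts in range", {
  sp <- phantom_spec("fossil_like", shape = c(24, 40, 40), thickness_vox = 4,
                     foreground_level = 18000, background_level = 2000,
                     matrix_level = 24000, gradient_amplitude = 0.5,
                     noise_sd = 0, inclusion_density = 0, seed = 3)
  ph <- make_phantom(sp)
  lab <- ph$true_labels$labels
  expect_identical(sort(unique(as.vector(lab))), c(1L, 2L, 3L))
  v <- ph$volume$data
  # class ordering: background < bone < matrix at matched locations
  expect_lt(max(v[lab == 1L]), min(v[lab == 2L]))
  bone_near_center <- v[lab == 2L]
  expect_true(all(v[lab == 2L] >= 18000 - 1))
  expect_true(all(v[lab == 3L] >= 24000 - 1))
  # center-bright gradient: the brightest bone voxel exceeds the dimmest
  # by about the amplitude
  expect_gt(max(bone_near_center) / min(bone_near_center), 1.3)
})

test_that("inclusions are near saturation and tracked in their own mask", {
  sp <- phantom_spec("fossil_like", shape = c(16, 32, 32), thickness_vox = 4,
                     foreground_level = 18000, background_level = 2000,
                     matrix_level = 24000, inclusion_density = 0.01, seed = 4)
  ph <- make_phantom(sp)
  expect_gt(sum(ph$inclusion_mask), 0)
  expect_true(all(ph$volume$data[ph$inclusion_mask] >= 0.98 * 65535 - 1))
})

test_that("impossible geometry and invalid specs are rejected", {
  expect_error(phantom_spec("plate_coil", shape = c(4, 10, 10),
                            thickness_vox = 1), "thickness_vox")
  expect_error(make_phantom(phantom_spec("plate_coil", shape = c(4, 12, 12),
                                         thickness_vox = 5)), "geometry")
  expect_error(phantom_spec("fossil_like", shape = c(8, 24, 24)),
               "matrix_level")
  expect_error(phantom_spec("fossil_like", shape = c(8, 24, 24),
                            foreground_level = 20000, matrix_level = 15000),
               "matrix_level")
  expect_error(phantom_spec("plate_coil", shape = c(8, 24, 24),
                            foreground_level = 70000), "range")
})

test_that("phantom reports score perfect and empty segmentations correctly", {
  ph <- make_phantom(phantom_spec("plate_coil", shape = c(6, 48, 48),
                                  thickness_vox = 3, seed = 6))
  perfect <- ph$true_labels
  rep1 <- phantom_report(ph, perfect, 2)
  expect_equal(rep1$dice, 1)
  expect_equal(rep1$sensitivity, 1)
  empty <- mia_labels(array(0L, dim(ph$true_mask)), 2, 1)
  rep0 <- phantom_report(ph, empty, 2)
  expect_equal(rep0$sensitivity, 0)
  wrong_shape <- mia_labels(array(0L, c(2, 2, 2)), 2, 1)
  expect_error(phantom_report(ph, wrong_shape, 2), "shape")
})
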