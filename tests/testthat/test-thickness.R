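test_that("a slab spanning the volume measures its nominal thickness", {
  slab <- array(FALSE, c(16, 16, 11))
  slab[, , 4:8] <- TRUE                       # 5 voxels thick
  th <- local_thickness(slab, voxel_size_um = 7.86)
  interior <- slab
  interior[1:5, , ] <- FALSE; interior[12:16, , ] <- FALSE
  interior[, 1:5, ] <- FALSE; interior[, 12:16, ] <- FALSE
  vals <- th$thickness_map[interior]          # > 5 voxels from the cut faces
  expect_true(all(abs(vals - 5) <= 0.5))
  expect_equal(th$mean_um, th$mean_vox * 7.86, tolerance = 1e-12)
})

test_that("a digital ball of radius 8 has max thickness within 1 of 16", {
  ball <- ball_mask(c(21, 21, 21), 8)
  th <- local_thickness(ball, 1)
  expect_lte(abs(max(th$thickness_map) - 16), 1)
})

test_that("thickness matches the exhaustive sphere oracle on random masks", {
  for (s in 1:6) {
    m <- random_blob_mask(c(8, 8, 8), n_balls = 3, rmax = 2.6, seed = s)
    if (!any(m) || all(m)) next
    th <- local_thickness(m, 1)$thickness_map
    expect_lte(max(abs(th - brute_thickness(m))[m]), 1)
  }
})

test_that("thickness is invariant under axis permutations and flips", {
  m <- random_blob_mask(c(9, 11, 13), n_balls = 4, rmax = 3, seed = 42)
  th <- local_thickness(m, 1)$thickness_map
  perm <- local_thickness(aperm(m, c(2, 3, 1)), 1)$thickness_map
  expect_equal(aperm(th, c(2, 3, 1)), perm, tolerance = 1e-6)
  flip <- local_thickness(m[dim(m)[1]:1, , ], 1)$thickness_map
  expect_equal(th[dim(m)[1]:1, , ], flip, tolerance = 1e-6)
})

test_that("erosion never increases per-voxel thickness", {
  m <- ball_mask(c(15, 15, 15), 5)
  e <- erode_mask(m)
  th <- local_thickness(m, 1)$thickness_map
  the <- local_thickness(e, 1)$thickness_map
  expect_true(all(the[e] <= th[e] + 1e-9))
  # on a solid convex body the mean shrinks too
  expect_lte(mean(the[e]), mean(th[m]) + 1e-9)
})

test_that("empty masks are rejected", {
  expect_error(local_thickness(array(FALSE, c(4, 4, 4)), 1), "empty")
})

test_that("threshold sweeps are non-increasing and correctly shaped", {
  ph <- make_phantom(phantom_spec("plate_coil", shape = c(10, 64, 64),
                                  thickness_vox = 3, noise_sd = 3000,
                                  seed = 5))
  vals <- seq(50, 95, by = 15)
  tab <- thickness_sweep(ph$volume, seg_config(2, 5), vals,
                         parameter = "prob_threshold")
  expect_identical(nrow(tab), length(vals))
  expect_true(all(diff(tab$mean_um) <= 1e-9))
})

test_that("a grid-size sweep row at full extent matches the global result", {
  v <- two_phase_volume(c(8, 10, 10), noise = 2500, seed = 3)
  cfg <- seg_config(2, 10, tol = 1e-9, max_iter = 500)
  tab <- thickness_sweep(v, cfg, values = 10, parameter = "grid_size")
  chk <- local_fixed_point_check(v, cfg)
  glob_mask <- binarize(chk$seg$global$labels, "brightest")
  th <- local_thickness(glob_mask, v$voxel_size_um)
  expect_equal(tab$mean_um[1], th$mean_um, tolerance = 1e-6)
})
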