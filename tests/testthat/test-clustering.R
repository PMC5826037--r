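test_that("K-means initialization handles separated clusters and edge cases", {
  expect_equal(kmeans_init(c(0, 0, 0, 10, 10, 10), 2), c(0, 10))
  expect_equal(kmeans_init(c(1, 2, 3, 10), 1), 4)
  expect_error(kmeans_init(c(1, 1, 1), 2), "degenerate")
})

test_that("K-means matches stats::kmeans WSS on mixture data", {
  set.seed(21)
  x <- c(rnorm(80, 0, 1), rnorm(80, 10, 1), rnorm(40, 25, 2))
  ours <- kmeans_init(x, 3)
  ref <- stats::kmeans(x, centers = 3, nstart = 25)
  expect_lt(abs(centers_wss(x, ours) - ref$tot.withinss),
            1e-6 * ref$tot.withinss + 1e-9)
})

test_that("fcm memberships follow the formula, symmetry and zero-distance rule", {
  expect_equal(fcm_memberships(c(0, 10), c(0, 10)),
               matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(fcm_memberships(5, c(0, 10)), matrix(c(0.5, 0.5), 1, 2))
  expect_equal(fcm_memberships(2.5, c(0, 10)),
               matrix(c(0.9, 0.1), 1, 2))       # 1/(1 + (2.5/7.5)^2)
  # coincidence with both of two equal-distance centers never happens, but a
  # point on one center gets all of that center's mass
  expect_equal(fcm_memberships(10, c(0, 10))[1, ], c(0, 1))
})

test_that("fcm converges with a non-increasing objective and sorted centers", {
  set.seed(5)
  x <- c(rnorm(300, 2, 0.3), rnorm(200, 8, 0.5))
  fit <- fcm(x, centers = c(1, 9))
  expect_true(all(diff(fit$objective) <= 1e-9 * fit$objective[1]))
  expect_true(all(diff(fit$centers) > 0))
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
  # permutation safety: reversed initial centers give the same result
  fit2 <- fcm(x, centers = c(9, 1))
  expect_equal(fit2$centers, fit$centers, tolerance = 1e-9)
  expect_equal(fit2$memberships, fit$memberships, tolerance = 1e-9)
})

test_that("fcm supports weighted data equivalently to expanded data", {
  x <- c(1, 2, 3, 20, 21)
  w <- c(3, 1, 2, 4, 1)
  fit_w <- fcm(x, c(2, 20), weights = w)
  fit_e <- fcm(rep(x, times = w), c(2, 20))
  expect_equal(fit_w$centers, fit_e$centers, tolerance = 1e-9)
})

test_that("fcm reports center collapse naming the classes", {
  expect_error(fcm(rep(5, 10), centers = c(5 - 1e-12, 5 + 1e-12)), "collapse")
})

test_that("grid construction clamps, covers and respects the stride", {
  g1 <- build_grid(c(10, 10, 10), 10, 5)
  expect_identical(nrow(g1$origins), 1L)
  expect_identical(g1$origins[1, ], c(z = 1L, y = 1L, x = 1L))

  g2 <- build_grid(c(15, 10, 10), 10, 5)
  expect_identical(sort(unique(g2$origins[, "z"])), c(1L, 6L))
  expect_identical(unique(g2$origins[, "y"]), 1L)
  expect_identical(nrow(g2$origins), 2L)

  # grid size larger than an axis extent clamps to the extent
  g3 <- build_grid(c(4, 20, 20), 10)
  expect_identical(g3$edge, c(4L, 10L, 10L))

  # coverage between 1 and 8 for the default stride, over assorted shapes
  for (sh in list(c(7, 9, 11), c(12, 5, 8), c(20, 20, 4))) {
    for (g in c(3, 5, 7)) {
      cov <- grid_coverage(build_grid(sh, g))
      expect_gte(min(cov), 1)
      expect_lte(max(cov), 8)
    }
  }
})

test_that("label assignment applies argmax, ties and inclusive threshold", {
  u <- matrix(c(0.6, 0.3, 0.1), 1, 3)
  mk <- function(u) membership_field(array(u, c(1, 1, 1, 3)),
                                     array(TRUE, c(1, 1, 1)), 1)
  expect_equal(as.vector(assign_labels(mk(u))$labels), 1L)
  expect_equal(as.vector(assign_labels(mk(u), 0.75)$labels), 0L)
  expect_equal(as.vector(assign_labels(mk(u), 0.60)$labels), 1L)  # meet or exceed
  # argmax ties go to the lowest class index
  expect_equal(as.vector(assign_labels(mk(matrix(c(0.4, 0.4, 0.2), 1, 3)))$labels), 1L)
  expect_error(assign_labels(mk(u), 0.3), "prob_threshold")
  expect_error(assign_labels(mk(u), 101), "prob_threshold")
})

test_that("a 50% threshold is a no-op for two-class fields", {
  set.seed(9)
  u1 <- runif(64)
  u <- array(c(u1, 1 - u1), c(4, 4, 4, 2))
  mf <- membership_field(u, array(TRUE, c(4, 4, 4)), 1)
  expect_identical(assign_labels(mf, 50)$labels, assign_labels(mf)$labels)
})

test_that("the probability-threshold menu has exactly 50 active values", {
  menu <- prob_threshold_menu()
  expect_identical(menu, 51:100)
  expect_identical(length(unique(menu)), 50L)
  cfg <- seg_config(2, 5, prob_threshold = 50)
  expect_null(cfg$prob_threshold)                  # 50% alias = off
  expect_error(seg_config(2, 5, prob_threshold = 49), "prob_threshold")
  expect_error(seg_config(2, 5, prob_threshold = 75.5), "prob_threshold")
})

test_that("binarize selects classes and partitions the volume", {
  lab <- mia_labels(array(c(0L, 1L, 2L, 3L, 3L, 2L, 1L, 0L), c(2, 2, 2)),
                    n_classes = 3, voxel_size_um = 1)
  expect_identical(binarize(lab, "brightest"), lab$labels == 3L)
  expect_identical(binarize(lab, "second-brightest"), lab$labels == 2L)
  expect_error(binarize(lab, 4), "1..3")
  total <- (lab$labels == 0L) | binarize(lab, 1) | binarize(lab, 2) | binarize(lab, 3)
  expect_true(all(total))
  empty <- mia_labels(array(0L, c(2, 2, 2)), 2, 1)
  expect_false(any(binarize(empty, 1)))
})

test_that("grid-size suggestions reproduce the worked examples", {
  expect_identical(suggest_grid_size(40, voxel_size_um = 7.86, margin = 2), 7L)
  expect_identical(suggest_grid_size(15, margin = 5), 20L)
  expect_identical(suggest_grid_size(32, margin = 3), 35L)
  expect_identical(suggest_grid_size(0.5, margin = 1), 3L)  # floor at 3
  expect_error(suggest_grid_size(-4), "positive")
})

test_that("class-presence dropping gives a single-class cube the full vector", {
  # one cube of 1000 in-mask voxels with global memberships ~ (0.98, .01, .01):
  # S_2 = S_3 = 10 < 0.02 * 1000 = 20, so classes 2 and 3 are dropped
  d <- c(10, 10, 10)
  vol <- mia_volume(array(runif(1000, 0, 100), d), 1)
  u <- matrix(rep(c(0.98, 0.01, 0.01), each = 1000), 1000, 3)
  mf <- membership_field(u, array(TRUE, d), 1)
  cfg <- seg_config(3, 10, stride = 10)
  out <- local_refine(vol, array(TRUE, d), mf, c(10, 50, 90), cfg)
  expect_true(all(out$u[, , , 1] == 1))
  expect_true(all(out$u[, , , 2:3] == 0))
  expect_identical(attr(out, "refine_log")$cubes_single, 1L)
})

test_that("local refinement is a fixed point when one cube spans the volume", {
  v <- two_phase_volume(c(8, 10, 10), noise = 400, seed = 2)
  cfg <- seg_config(2, grid_size = 10, tol = 1e-9, max_iter = 500)
  seg <- local_fixed_point_check(v, cfg)
  expect_lt(seg$max_diff, 1e-6)
})

test_that("segmenting a noise-free two-level volume recovers the truth", {
  d <- c(6, 10, 10)
  a <- array(0, d); a[, 6:10, ] <- 30000
  v <- mia_volume(a, 7.86)
  for (g in c(4, 7)) {
    seg <- segment(v, seg_config(2, g))
    expect_identical(seg$labels$labels, array(ifelse(a > 0, 2L, 1L), d))
  }
})

test_that("segmentation is deterministic and membership rows sum to one", {
  v <- two_phase_volume(c(6, 12, 12), noise = 1500, seed = 4)
  cfg <- seg_config(2, 5)
  s1 <- segment(v, cfg)
  s2 <- segment(v, cfg)
  expect_identical(s1$labels$labels, s2$labels$labels)
  expect_identical(s1$memberships$u, s2$memberships$u)
  sums <- apply(s1$memberships$u, 1:3, sum)
  expect_true(all(abs(sums[s1$mask] - 1) < 1e-6))
  expect_true(all(sums[!s1$mask] == 0))
  # global objective trace non-increasing
  expect_true(all(diff(s1$objective) <= 1e-9 * abs(s1$objective[1])))
})

test_that("monotone thresholding shrinks the labeled set", {
  v <- two_phase_volume(c(6, 12, 12), noise = 4000, seed = 8)
  seg <- segment(v, seg_config(2, 5))
  prev <- NULL
  for (t in c(55, 65, 75, 85, 95)) {
    cur <- assign_labels(seg$memberships, t)$labels > 0
    if (!is.null(prev)) expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("stage errors are reported with the stage name", {
  v <- mia_volume(array(5, c(4, 4, 4)), 1)
  expect_error(segment(v, seg_config(2, 4)), "kmeans_init")
  v2 <- two_phase_volume(c(4, 6, 6))
  expect_error(segment(v2, seg_config(2, 4),
                       pp_params(background_threshold = 1e5)),
               "background_mask")
})
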