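test_that("gaussian smoothing: identity at fwhm 0, mass conservation, constants", {
  withr::with_seed(10, {
    arr <- array(stats::rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  })
  vol <- volume_series(arr, voxdim = c(2, 2, 2))
  expect_identical(gaussian_smooth(vol, 0)$data, vol$data)
  expect_error(gaussian_smooth(vol, -1), "nonnegative")
  # kernel: sd = fwhm/2.3548 mm, sums to 1
  k <- fesdcm:::gauss_kernel_1d(4, 2)
  expect_equal(sum(k), 1)
  sd_emp <- sqrt(sum(k * (seq_along(k) - (length(k) + 1) / 2)^2)) * 2
  expect_equal(sd_emp, 4 / 2.3548, tolerance = 0.02)
  # constant volume unchanged (renormalized boundaries)
  cvol <- volume_series(array(3, c(10, 10, 6, 1)), voxdim = c(2, 2, 2))
  expect_equal(gaussian_smooth(cvol, 4)$data, cvol$data, tolerance = 1e-12)
  # interior mass conservation: an impulse far from the boundary keeps its sum
  imp <- array(0, c(17, 17, 17, 1))
  imp[9, 9, 9, 1] <- 1
  sm <- gaussian_smooth(volume_series(imp, voxdim = c(2, 2, 2)), 4,
                        renormalize = FALSE)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
})

test_that("maxima selection enforces the minimum-separation rule greedily", {
  grid <- list(dim = c(20, 20, 8), voxdim = c(2, 2, 2), origin = c(0, 0, 0))
  stat <- array(0, grid$dim)
  # region A peak at (10,10,8); region B: global peak 4 mm away, second peak
  # 20 mm away
  stat[6, 6, 5] <- 10
  stat[8, 6, 5] <- 9    # 4 mm from A's peak
  stat[16, 6, 5] <- 7   # 20 mm away
  maskA <- array(0, grid$dim); maskA[1:7, , ] <- 1
  maskB <- array(0, grid$dim); maskB[8:20, , ] <- 1
  sel <- select_maxima(stat, list(A = maskA, B = maskB), min_separation = 8,
                       voxdim = grid$voxdim, origin = grid$origin)
  expect_equal(sel$A$center, c(10, 10, 8))
  expect_equal(sel$B$center, c(30, 10, 8))   # fell back past the 8 mm rule
  # with no separation constraint B takes its masked argmax
  sel0 <- select_maxima(stat, list(A = maskA, B = maskB), min_separation = 0,
                        voxdim = grid$voxdim, origin = grid$origin)
  expect_equal(sel0$B$center, c(14, 10, 8))
  # determinism
  sel2 <- select_maxima(stat, list(A = maskA, B = maskB), min_separation = 8,
                        voxdim = grid$voxdim, origin = grid$origin)
  expect_identical(sel, sel2)
  # no admissible voxel: single-voxel masks closer than the rule
  m1 <- array(0, grid$dim); m1[6, 6, 5] <- 1
  m2 <- array(0, grid$dim); m2[7, 6, 5] <- 1
  expect_error(select_maxima(stat, list(A = m1, B = m2), 8,
                             grid$voxdim, grid$origin), "no admissible voxel")
  expect_error(select_maxima(stat, list(A = array(0, grid$dim)), 8,
                             grid$voxdim, grid$origin), "empty mask")
})

test_that("first eigenvariate recovers shared and rank-1 structure", {
  lay <- roi_fixture_layout()
  Tn <- 60
  base <- sin(seq(0, 6 * pi, length.out = Tn)) + 2
  # all voxels share the same series
  arr <- array(0, c(lay$grid$dim, Tn))
  flat <- matrix(arr, prod(lay$grid$dim), Tn)
  roi <- lay$rois$M1
  g <- fesdcm:::voxel_grid_mm(lay$grid$dim, lay$grid$voxdim, lay$grid$origin)
  d2 <- outer(outer((g$x - roi$center[1])^2, (g$y - roi$center[2])^2, `+`),
              (g$z - roi$center[3])^2, `+`)
  sel <- which(d2 <= roi$radius^2)
  flat[sel, ] <- matrix(base, length(sel), Tn, byrow = TRUE)
  vol <- volume_series(array(flat, c(lay$grid$dim, Tn)),
                       voxdim = lay$grid$voxdim, origin = lay$grid$origin)
  ev <- first_eigenvariate(vol, roi)
  expect_gt(stats::cor(ev, base), 0.9999)
  expect_equal(stats::sd(ev), stats::sd(base), tolerance = 1e-8)
  # sign convention: flipping the data flips the summary
  vol2 <- vol; vol2$data <- -vol2$data
  ev2 <- first_eigenvariate(vol2, roi)
  expect_equal(ev2, -ev, tolerance = 1e-8)
  # rank-1 + noise recovers the temporal factor
  withr::with_seed(11, {
    w <- stats::runif(length(sel), 0.5, 1.5)
    flat[sel, ] <- outer(w, base) + matrix(stats::rnorm(length(sel) * Tn,
                                                        0, 0.05),
                                           length(sel))
  })
  vol3 <- volume_series(array(flat, c(lay$grid$dim, Tn)),
                        voxdim = lay$grid$voxdim, origin = lay$grid$origin)
  ev3 <- first_eigenvariate(vol3, lay$rois$M1)
  expect_gt(stats::cor(ev3, base), 0.99)
  # Rayleigh optimality: the eigenvariate explains at least as much variance
  # as the plain ROI mean
  Y <- t(matrix(vol3$data, prod(lay$grid$dim), Tn)[sel, ])
  Yc <- sweep(Y, 2, colMeans(Y))
  proj_var <- function(v) sum((Yc %*% (v / sqrt(sum(v^2))))^2)
  expect_gte(proj_var(as.numeric(crossprod(Yc, ev3 - mean(ev3)))),
             proj_var(rep(1, ncol(Yc))) - 1e-8)
  # empty sphere errors
  expect_error(first_eigenvariate(vol3, roi_spec("x", c(500, 500, 500), 4)),
               "no voxel")
})

test_that("NIfTI round trip preserves data and geometry", {
  withr::with_seed(12, {
    arr <- array(stats::rnorm(8 * 8 * 4 * 3), c(8, 8, 4, 3))
  })
  vol <- volume_series(arr, voxdim = c(1.8, 1.8, 4), tr = 3)
  tf <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, tf)
  back <- read_volume_nifti(tf)
  expect_equal(back$data, vol$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$voxdim, vol$voxdim, tolerance = 1e-6)
  expect_equal(back$tr, 3, tolerance = 1e-6)
})
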