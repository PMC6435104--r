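proto <- protocol_preset("I")

test_that("single-point grid evaluation equals direct voxel BS calls", {
  gf <- test_gradient_box(c(4, 4, 4))
  single <- build_grid(zshim_range = c(0, 0), tilt_range = c(0, 0),
                       polarities = "positive")
  ev <- evaluate_grid(gf, proto, single)
  direct <- mapply(function(x, y, z) {
    voxel_bs(x, -y, z, proto)$bs_rel   # transverse frame: (gx, -gy, gz)
  }, gf$gx, gf$gy, gf$gz)
  expect_equal(as.vector(ev$bs[1, ]), as.vector(direct), tolerance = 1e-14)
})

test_that("on a zero-gradient field, sets differ only through the z-shim", {
  dims <- c(3, 3, 3)
  gf <- make_gf(array(0, dims), array(0, dims), array(0, dims))
  grid <- build_grid(zshim_range = c(-2, 2), zshim_step = 1,
                     tilt_range = c(-30, 30), tilt_step = 30)
  ev <- evaluate_grid(gf, proto, grid)
  for (i in seq_len(nrow(ev$sets))) {
    expected <- through_plane_attenuation(0, ev$sets$zshim[i], proto)
    expect_equal(unique(as.vector(ev$bs[i, ])), expected)
  }
})

test_that("lazy evaluation returns the same rows as the dense stack", {
  gf <- test_gradient_box(c(4, 4, 4))
  grid <- build_grid(zshim_range = c(-1, 1), zshim_step = 1,
                     tilt_range = c(-15, 15), tilt_step = 15)
  dense <- evaluate_grid(gf, proto, grid)
  lazy <- evaluate_grid(gf, proto, grid, max_dense_elements = 10)
  expect_true(dense$dense)
  expect_false(lazy$dense)
  expect_null(lazy$bs)
  for (i in c(1, 5, nrow(dense$sets))) {
    expect_identical(lazy$eval(i), dense$bs[i, ])
  }
})

test_that("voxel-wise optimizer matches the exhaustive oracle with ties", {
  gf <- test_gradient_box(c(6, 6, 6), scale = 70, seed = 9)
  grid <- build_grid(zshim_range = c(-2, 2), zshim_step = 0.5,
                     tilt_range = c(-45, 45), tilt_step = 15)
  vw <- optimize_voxelwise(gf, proto, grid)
  pr <- oracle_protocol()
  oracle <- oracle_optimize(as.vector(gf$gx), as.vector(gf$gy),
                            as.vector(gf$gz), pr,
                            zshims = seq(-2, 2, 0.5),
                            tilts = seq(-45, 45, 15),
                            polarities = c("positive", "negative"))
  expect_same_optimum(vw, oracle, seq_along(oracle$bs))
})

test_that("zero-gradient voxels keep the reference set with zero gain", {
  dims <- c(2, 2, 2)
  gf <- make_gf(array(0, dims), array(0, dims), array(0, dims))
  vw <- optimize_voxelwise(gf, proto, build_grid())
  expect_equal(unique(as.vector(vw$zshim)), 0)
  expect_equal(unique(as.vector(vw$tilt)), 0)
  expect_equal(unique(as.vector(vw$polarity)), 1)
  expect_equal(unique(as.vector(vw$gain)), 0)
})

test_that("a pure slice-direction gradient recovers the closed-form z-shim", {
  ## G_SL * TE0 = -0.9 mT/m*ms: nearest grid point on a z-shim-only search
  ## is 1.0 (within half a step)
  g_sl <- -0.9e-6 / proto$te0 * 1e6          # uT/m
  dims <- c(2, 2, 2)
  gf <- make_gf(array(0, dims), array(0, dims), array(g_sl, dims))
  vw <- optimize_voxelwise(gf, proto, build_grid(tilt_range = c(0, 0)))
  expect_equal(unique(as.vector(vw$zshim)), 1.0)
  expect_equal(unique(as.vector(vw$tilt)), 0)
  ## on the full grid a tilt can trade dephasing for an echo-shift boost;
  ## the attained BS must then be at least the z-shim-only optimum
  vw_full <- optimize_voxelwise(gf, proto, build_grid())
  expect_true(all(vw_full$bs_opt >= vw$bs_opt - 1e-12))
})

test_that("every reported parameter set respects the loss bound", {
  gf <- test_gradient_box(c(6, 6, 6), scale = 80, seed = 2)
  vw <- optimize_voxelwise(gf, proto, build_grid())
  reported <- unique(data.frame(zshim = as.vector(vw$zshim),
                                tilt = as.vector(vw$tilt)))
  for (r in seq_len(nrow(reported))) {
    loss <- wellshimmed_loss(adjustable_params(zshim = reported$zshim[r]),
                             proto)
    expect_lte(loss, 0.15 + 1e-12)
  }
  ## the feasible-set filter rejects strong shims up front
  expect_false(any(abs(vw$sets$zshim) > 1.01))
})

test_that("nested-grid refinement never lowers the optimal BS", {
  gf <- test_gradient_box(c(4, 4, 4), scale = 70, seed = 13)
  coarse <- build_grid(zshim_range = c(-1, 1), zshim_step = 0.5,
                       tilt_range = c(-45, 45), tilt_step = 15)
  fine <- build_grid(zshim_range = c(-1, 1), zshim_step = 0.25,
                     tilt_range = c(-45, 45), tilt_step = 7.5)
  bc <- optimize_voxelwise(gf, proto, coarse)
  bf <- optimize_voxelwise(gf, proto, fine)
  expect_true(all(bf$bs_opt >= bc$bs_opt - 1e-12))
})

test_that("ROI optimization reduces to the voxel-wise result for one voxel", {
  gf <- test_gradient_box(c(3, 3, 3), scale = 70, seed = 4)
  labels <- array(0L, c(3, 3, 3)); labels[2, 2, 2] <- 1L
  rois <- roi_set(labels, c(single = 1))
  grid <- build_grid(zshim_range = c(-1, 1), zshim_step = 0.5,
                     tilt_range = c(-45, 45), tilt_step = 15)
  ro <- optimize_roi(gf, proto, grid, rois)
  vw <- optimize_voxelwise(gf, proto, grid)
  expect_equal(ro$table$zshim, vw$zshim[2, 2, 2])
  expect_equal(ro$table$tilt, vw$tilt[2, 2, 2])
  expect_equal(ro$table$gain, vw$gain[2, 2, 2])
})

test_that("opposed slice gradients in one ROI pull the z-shim to zero", {
  dims <- c(2, 1, 2)
  gz <- array(0, dims); gz[1, 1, 1] <- 25; gz[2, 1, 1] <- -25
  gf <- make_gf(array(0, dims), array(0, dims), gz)
  labels <- array(0L, dims); labels[, 1, 1] <- 1L
  rois <- roi_set(labels, c(pair = 1))
  ro <- optimize_roi(gf, proto, build_grid(), rois)
  expect_equal(ro$table$zshim, 0)
})

test_that("ROI optimum beats the reference and surfaces contain it", {
  spec <- default_head_phantom()
  fm <- dipole_field(spec)
  gf <- gradient_field(fm)
  labels <- phantom_rois(spec)$labels
  rois <- roi_set(labels * (labels == 1L), c(mOFC = 1))
  grid <- build_grid(zshim_range = c(-2, 2), zshim_step = 0.5,
                     tilt_range = c(-45, 45), tilt_step = 15)
  ro <- optimize_roi(gf, proto, grid, rois)
  expect_gt(ro$table$gain, 0)
  surf <- ro$surfaces$mOFC[[ro$table$polarity]]
  expect_equal(surf[as.character(ro$table$tilt),
                    as.character(ro$table$zshim)], ro$table$gain)
  ## no feasible set outscores the reported optimum
  feas <- ro$sets$feasible
  expect_true(all(ro$mean_bs[feas, 1] <=
                    max(ro$mean_bs[feas, 1]) + 1e-12))
  ## empty ROI reports a missing row, not an error
  labels2 <- array(0L, dim(labels)); labels2[1, 1, 1] <- 2L  # outside mask
  fm$mask[1, 1, 1] <- FALSE
  rois2 <- roi_set(labels2, c(void = 2))
  ro2 <- optimize_roi(gradient_field(fm), proto, grid, rois2)
  expect_true(is.na(ro2$table$zshim))
})

test_that("cross-ROI impact has non-negative diagonal and bounded WS column", {
  gf <- test_gradient_box(c(6, 6, 6), scale = 70, seed = 31)
  labels <- array(0L, c(6, 6, 6))
  labels[1:3, , 1:3] <- 1L; labels[4:6, , 4:6] <- 2L
  rois <- roi_set(labels, c(a = 1, b = 2))
  grid <- build_grid(zshim_range = c(-1, 1), zshim_step = 0.5,
                     tilt_range = c(-30, 30), tilt_step = 15)
  ro <- optimize_roi(gf, proto, grid, rois)
  imp <- cross_roi_impact(gf, proto, ro, rois)
  expect_identical(rownames(imp), c("a", "b", "Whole-Brain", "Well-Shimmed"))
  expect_gte(imp["a", "a"], 0)
  expect_gte(imp["b", "b"], 0)
  expect_true(all(imp[, "Well-Shimmed"] >= -15 - 1e-9))
  expect_equal(imp["Well-Shimmed", "Well-Shimmed"], 0)
})

test_that("antagonistic ROIs produce negative off-diagonal impact", {
  ## two ROIs needing opposite z-shims: optimizing one hurts the other
  dims <- c(2, 1, 2)
  gz <- array(0, dims); gz[1, 1, 1] <- -33; gz[2, 1, 1] <- 33
  gf <- make_gf(array(0, dims), array(0, dims), gz)
  labels <- array(0L, dims)
  labels[1, 1, 1] <- 1L; labels[2, 1, 1] <- 2L
  rois <- roi_set(labels, c(up = 1, down = 2))
  grid <- build_grid(zshim_range = c(-1, 1), zshim_step = 0.5,
                     tilt_range = c(0, 0), polarities = "positive")
  ro <- optimize_roi(gf, proto, grid, rois)
  expect_true(ro$table$zshim[1] > 0 && ro$table$zshim[2] < 0)
  imp <- cross_roi_impact(gf, proto, ro, rois)
  expect_lt(imp["up", "down"], 0)
  expect_lt(imp["down", "up"], 0)
})

test_that("per-subject analysis degenerates correctly for identical subjects", {
  gf <- test_gradient_box(c(5, 5, 5), scale = 60, seed = 17)
  labels <- array(0L, c(5, 5, 5)); labels[2:4, 2:4, 2:4] <- 1L
  rois <- roi_set(labels, c(core = 1))
  grid <- build_grid(zshim_range = c(-1, 1), zshim_step = 0.5,
                     tilt_range = c(-30, 30), tilt_step = 15)
  res <- per_subject_optima(list(gf, gf, gf), proto, grid, rois)
  expect_equal(res$gain_table$gain_sd, 0)
  h <- res$histograms$core
  expect_equal(sum(h$zshim$count), 3)
  expect_equal(max(h$zshim$count), 3)   # all subjects agree
  expect_equal(sum(h$tilt$count), 3)
  ## per-subject gain at the group optimum equals the group gain here
  expect_equal(res$gain_table$gain_mean,
               optimize_roi(gf, proto, grid, rois)$table$gain)
})

test_that("jittered cohorts concentrate optima near the group optimum", {
  spec <- default_head_phantom(seed = 3)
  cohort <- make_cohort(spec, 4, jitter = 0.03)
  gfs <- lapply(cohort, gradient_field)
  labels <- phantom_rois(spec)$labels
  rois <- roi_set(labels * (labels == 1L), c(mOFC = 1))
  grid <- build_grid(zshim_range = c(-1.5, 1.5), zshim_step = 0.5,
                     tilt_range = c(-45, 45), tilt_step = 15)
  res <- per_subject_optima(gfs, proto, grid, rois)
  h <- res$histograms$mOFC$zshim
  group_z <- res$gain_table$zshim[1]
  spread <- range(h$zshim[h$count > 0])
  expect_lte(diff(spread), 3 * 0.5)          # within 3 grid steps
  expect_lte(min(abs(h$zshim[h$count > 0] - group_z)), 0.5)
})

test_that("grids without the reference point are refused", {
  gf <- test_gradient_box(c(2, 2, 2))
  g <- build_grid()
  g$polarities <- "negative"
  expect_error(optimize_voxelwise(gf, proto, g), "reference point")
  labels <- array(1L, c(2, 2, 2))
  expect_error(optimize_roi(gf, proto, g, roi_set(labels, c(all = 1))),
               "reference point")
})
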