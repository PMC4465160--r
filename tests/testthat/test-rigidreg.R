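# Small smooth test volumes: sum of Gaussian blobs, enough structure for a
# well-conditioned registration at 32^3.
blob_volume <- function(n = 32, spacing = c(1, 1, 1), modality = "CT",
                        centers = rbind(c(-6, -4, 2), c(5, 6, -3), c(0, 2, 6)),
                        amps = c(200, 150, 180), origin = NULL) {
  if (is.null(origin)) origin <- -(n - 1) * spacing / 2
  ax <- lapply(1:3, function(a) origin[a] + (0:(n - 1)) * spacing[a])
  vox <- array(0, c(n, n, n))
  for (b in seq_len(nrow(centers))) {
    gx <- exp(-(ax[[1]] - centers[b, 1])^2 / 30)
    gy <- exp(-(ax[[2]] - centers[b, 2])^2 / 40)
    gz <- exp(-(ax[[3]] - centers[b, 3])^2 / 25)
    vox <- vox + amps[b] * (gx %o% gy %o% gz)
  }
  image_volume(vox, spacing, origin, modality)
}

test_that("NCC is 1 for identical and linearly mapped images, -1 for negated", {
  v <- blob_volume()
  expect_equal(ncc(v, v), 1, tolerance = 1e-12)
  w <- v; w$voxels <- 1.7 * v$voxels + 40   # positive linear intensity map
  expect_equal(ncc(v, w), 1, tolerance = 1e-12)
  neg <- v; neg$voxels <- -v$voxels
  expect_equal(ncc(v, neg), -1, tolerance = 1e-12)
})

test_that("masked NCC matches a loop-based oracle over exactly the masked voxels", {
  set.seed(17)
  v <- blob_volume()
  w <- v; w$voxels <- v$voxels + array(rnorm(32^3, sd = 20), c(32, 32, 32))
  fmask <- binary_mask(array(as.numeric(runif(32^3) < 0.3), c(32, 32, 32)),
                       v$spacing, v$origin)
  got <- ncc(v, w, identity_transform(), fmask)
  expect_equal(got, oracle_ncc_identity(v$voxels, w$voxels, fmask$voxels),
               tolerance = 1e-10)
  # degenerate cases
  small <- binary_mask(array(0, c(32, 32, 32)), v$spacing, v$origin)
  small$voxels[1:3, 1, 1] <- 1
  expect_error(ncc(v, w, fixed_mask = small), "insufficient mask overlap")
  flat <- v; flat$voxels[] <- 5
  expect_error(ncc(flat, w), "degenerate intensities")
})

test_that("NCC is symmetric under swapping images with the inverted transform", {
  v <- blob_volume()
  w <- blob_volume(amps = c(180, 170, 120))
  t1 <- rigid_transform(c(0.01, -0.02, 0.015), c(1.2, -0.8, 0.5))
  expect_equal(ncc(v, w, t1), ncc(w, v, invert_transform(t1)), tolerance = 5e-3)
})

test_that("gradient descent recovers a pure translation to sub-voxel accuracy", {
  v <- blob_volume()
  # moved = v translated by +2 mm along x (pull-back resampling through -2)
  moved <- resample(v, rigid_transform(translations = c(-2, 0, 0)), grid_of(v), fill = 0)
  res <- register_rigid(v, moved, cfg = reg_config(smooth_mm = c(2, 1, 0)))
  expect_equal(res$transform$translations, c(2, 0, 0), tolerance = 0.5)
  expect_true(res$converged)
  # determinism: bit-identical repeat
  res2 <- register_rigid(v, moved, cfg = reg_config(smooth_mm = c(2, 1, 0)))
  expect_identical(res$transform, res2$transform)
  expect_identical(res$final_metric, res2$final_metric)
})

test_that("analytic metric gradient agrees with metric finite differences", {
  v <- blob_volume()
  w <- v; w$voxels <- 1.3 * v$voxels + 15
  t0 <- rigid_transform(c(0.03, -0.02, 0.05), c(1.2, -0.7, 0.4), center = c(0.5, -1, 0))
  fmv <- array(0, c(32, 32, 32)); fmv[6:27, 6:27, 6:27] <- 1  # interior only
  fmask <- binary_mask(fmv, v$spacing, v$origin)
  mfull <- binary_mask(array(1, c(32, 32, 32)), v$spacing, v$origin)
  an <- cbctreg:::ncc_with_gradient(v, w, t0, fmask, mfull, 50)$gradient
  fd <- numeric(6)
  pp <- cbctreg:::transform_to_params(t0, 50)
  for (k in 1:6) {
    e <- numeric(6); e[k] <- 1e-5
    fd[k] <- (ncc(v, w, cbctreg:::params_to_transform(pp + e, t0$center, 50), fmask, mfull) -
              ncc(v, w, cbctreg:::params_to_transform(pp - e, t0$center, 50), fmask, mfull)) / 2e-5
  }
  # same descent direction and matching dominant components
  expect_gt(sum(an * fd) / sqrt(sum(an^2) * sum(fd^2)), 0.98)
  big <- abs(fd) > 0.1 * max(abs(fd))
  expect_lt(max(abs(an[big] - fd[big]) / abs(fd[big])), 0.15)
  # both gradient routes drive the registration to the same answer
  moved <- resample(v, rigid_transform(translations = c(-2, 1, 0)), grid_of(v), fill = 0)
  cfa <- reg_config(smooth_mm = c(2, 1, 0))
  cff <- reg_config(smooth_mm = c(2, 1, 0), gradient = "fd")
  ra <- register_rigid(v, moved, cfg = cfa)
  rf <- register_rigid(v, moved, cfg = cff)
  expect_equal(ra$transform$translations, rf$transform$translations, tolerance = 0.3)
})

test_that("optimizer contracts: optimum start and iteration cap", {
  v <- blob_volume()
  moved <- resample(v, rigid_transform(translations = c(2, -1, 0)), grid_of(v), fill = 0)
  truth <- rigid_transform(translations = c(2, -1, 0))
  res <- register_rigid(v, moved, init = truth, cfg = reg_config())
  expect_true(res$stop_reason %in% c("gradient_tolerance", "step_tolerance"))
  expect_gte(res$final_metric, 0.999)
  capped <- register_rigid(v, moved, cfg = reg_config(max_iter = 1))
  expect_identical(capped$stop_reason, "max_iterations")
  expect_false(capped$converged)
  expect_true(all(capped$iterations <= 1))
})

test_that("returned metric never degrades below its initialization", {
  p <- fixture_moved_pair()
  bony <- fixture_moved_bony()
  thr <- threshold_config()
  ct_b <- threshold_bone(p$ct, thr); cbct_b <- threshold_bone(p$cbct, thr)
  ct_body <- compute_body_mask(p$ct, thr); cbct_body <- compute_body_mask(p$cbct, thr)
  at_init <- ncc(cbct_b, ct_b, identity_transform(center = bony$transform$center),
                 cbct_body, ct_body)
  at_result <- ncc(cbct_b, ct_b, bony$transform, cbct_body, ct_body)
  expect_gte(at_result, at_init)
  expect_true(bony$final_metric >= -1 && bony$final_metric <= 1)
})

test_that("bony registration recovers the setup transform despite prostate motion", {
  p <- fixture_moved_pair()
  bony <- fixture_moved_bony()
  inv <- recenter_transform(invert_transform(p$truth_setup), bony$transform$center)
  expect_lt(sqrt(sum((bony$transform$translations - inv$translations)^2)), 1)
  expect_lt(max(abs(bony$transform$rotations - inv$rotations)) * 180 / pi, 1)
  # adding rectal gas barely moves the bony result (bone clamp removes gas contrast)
  sp <- p$spec; sp$gas_fraction <- 0.6
  pg <- generate_pair(sp)
  bg <- register_bony(pg$ct, pg$cbct)
  expect_lt(sqrt(sum((bg$transform$translations - bony$transform$translations)^2)), 0.2)
  # no bone at all: the clamp flattens both images -> degenerate intensities
  nobone_ct <- image_volume(array(30, c(16, 16, 16)), c(2, 2, 2), c(-15, -15, -15))
  nobone_cb <- image_volume(array(10, c(16, 16, 16)), c(2, 2, 2), c(-15, -15, -15),
                            modality = "CBCT")
  expect_error(register_bony(nobone_ct, nobone_cb), "degenerate intensities")
})

test_that("local refinement corrects the prostate offset the bony step leaves", {
  p <- fixture_moved_pair()           # prostate offset (4, -3, 0), norm 5 mm
  bony <- fixture_moved_bony()
  expect_gt(prostate_center_error(p, bony), 3.5)   # bony leaves the offset
  loc <- register_local(p$ct, p$cbct, p$ct_structs$ctv, 8, bony)
  expect_lt(prostate_center_error(p, loc), 1.5)
  # zero prostate offset: local result stays at the bony solution
  sp <- p$spec; sp$prostate_offset <- c(0, 0, 0)
  p0 <- generate_pair(sp)
  b0 <- register_bony(p0$ct, p0$cbct)
  l0 <- register_local(p0$ct, p0$cbct, p0$ct_structs$ctv, 8, b0)
  d <- recenter_transform(b0$transform, l0$transform$center)$translations -
    l0$transform$translations
  expect_lt(sqrt(sum(d^2)), 1)
})

test_that("every margin in the clinical sweep runs", {
  p <- fixture_moved_pair()
  bony <- fixture_moved_bony()
  for (margin in c(1, 3, 5, 8, 10, 12, 15, 20)) {
    res <- register_local(p$ct, p$cbct, p$ct_structs$ctv, margin, bony)
    expect_s3_class(res, "RegistrationResult")
  }
})

test_that("contour registration recovers shifts and bounds the achievable Dice", {
  m <- binary_mask(array(0, c(40, 40, 40)), c(1, 1, 1), origin = c(-20, -20, -20))
  ax <- grid_axes(m)
  dist2 <- outer(ax[[1]]^2 / 100, ax[[2]]^2 / 64, "+") %o% rep(1, 40) +
    rep(1, 40) %o% rep(1, 40) %o% (ax[[3]]^2 / 81)
  m$voxels <- array(as.numeric(dist2 <= 1), c(40, 40, 40))
  # identical masks -> identity, Dice 1 after propagation
  res <- register_contours(m, m)
  prop <- propagate_contour(m, res$transform, grid_of(m))
  expect_equal(dice(prop, m), 1)
  # 6 mm shift recovered within half a voxel, Dice >= 0.95 after propagation
  shifted <- resample(m, rigid_transform(translations = c(-6, 0, 0)), grid_of(m))
  res2 <- register_contours(m, shifted)
  expect_equal(recenter_transform(res2$transform, c(0, 0, 0))$translations,
               c(-6, 0, 0), tolerance = 0.5)
  prop2 <- propagate_contour(m, res2$transform, grid_of(shifted))
  expect_gte(dice(prop2, shifted), 0.95)
  # different shapes, same centroid: centroids stay aligned within 1 mm
  sphere <- m
  sphere$voxels <- array(as.numeric(outer(ax[[1]]^2, ax[[2]]^2, "+") %o% rep(1, 40) +
    rep(1, 40) %o% rep(1, 40) %o% ax[[3]]^2 <= 64), c(40, 40, 40))
  res3 <- register_contours(m, sphere)
  expect_lt(sqrt(sum(recenter_transform(res3$transform,
                                        c(0, 0, 0))$translations^2)), 1)
})

test_that("contour propagation is a nearest-neighbor pull-back", {
  p <- fixture_moved_pair()
  same <- propagate_contour(p$ct_structs$ctv, identity_transform(), grid_of(p$ct_structs$ctv))
  expect_identical(same$voxels, p$ct_structs$ctv$voxels)
  t1 <- rigid_transform(translations = c(6, -4, 3))
  prop <- propagate_contour(p$ct_structs$ctv, t1, grid_of(p$cbct))
  expect_true(all(prop$voxels %in% c(0, 1)))
  # pull-back through a pure translation shifts the centroid by its inverse
  expect_equal(mask_centroid(prop), mask_centroid(p$ct_structs$ctv) - c(6, -4, 3),
               tolerance = 1.1)
})
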