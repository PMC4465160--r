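test_that("phantom spec validation rejects inconsistent worlds", {
  expect_error(phantom_spec(distension_factor = 0.8), "distension_factor")
  expect_error(phantom_spec(gas_fraction = 1.2), "gas fractions")
  expect_error(phantom_spec(intensities = c(tissue = 30, prostate = 40, bladder = 10,
                                            bone = 400, gas = -1000, air = -1000)),
               "bone intensity")
  # organs pushed outside the body are refused
  expect_error(generate_pair(coarse_spec(bladder_center = c(0, -55, 0))),
               "outside the body")
  # overlapping organ specification is refused
  expect_error(generate_pair(coarse_spec(prostate_center = c(0, 15, 0))),
               "overlapping organ")
})

test_that("identical seeds give bit-identical phantoms, different seeds differ", {
  a <- generate_pair(coarse_spec(seed = 77))
  b <- generate_pair(coarse_spec(seed = 77))
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$cbct$voxels, b$cbct$voxels)
  c <- generate_pair(coarse_spec(seed = 78))
  expect_false(identical(a$cbct$voxels, c$cbct$voxels))
})

test_that("phantom intensities respect the segmentation thresholds", {
  p <- generate_pair(coarse_spec(gas_fraction_ct = 0.5, gas_fraction = 0.5, seed = 9))
  ct <- p$ct$voxels
  # every voxel above the 150 HU bone threshold is bone, and bone is well above it
  expect_true(all(ct[ct > 150] == 700))
  # gas voxels sit below the -150 HU gas threshold
  expect_true(any(ct == -1000))
  gas_ct <- replace_gas(p$ct)
  expect_true(min(gas_ct$voxels) >= -150)
  # CBCT bone clamps above its -140 au threshold, gas below -500 au
  cb <- p$cbct$voxels
  expect_gt(max(cb), -140)
  expect_lt(min(cb), -500)
})

test_that("truth masks carry the prescribed prostate displacement", {
  p <- generate_pair(coarse_spec(prostate_offset = c(5, 0, 0), noise_sigma = 0, seed = 4))
  shift <- mask_centroid(p$cbct_structs_truth$ctv) - mask_centroid(p$ct_structs$ctv)
  expect_equal(shift, c(5, 0, 0), tolerance = 1.1)  # within ~half a coarse voxel
  # truth transform composition: setup + offset
  expect_equal(p$truth_prostate$translations,
               p$truth_setup$translations + c(5, 0, 0))
})

test_that("identity-pose phantom yields a CBCT that matches the CT", {
  p <- generate_pair(coarse_spec(cbct_gain = 1, cbct_offset = 0, noise_sigma = 0, seed = 2))
  cb_on_ct <- resample(p$cbct, identity_transform(), grid_of(p$ct))
  diff <- abs(cb_on_ct$voxels - p$ct$voxels)
  # identical anatomy rasterized on different grids: agreement everywhere but
  # at shape boundaries, where interpolation across the edge differs
  expect_lt(mean(diff > 5), 0.05)
  expect_equal(median(diff), 0)
})

test_that("rasterized truth masks agree with resampled CT masks (Dice >= 0.95)", {
  # full default resolution, rigid anatomy (zero prostate offset): the truth
  # masks must match the rigidly resampled CT masks up to discretization
  p <- generate_pair(phantom_spec(
    setup_transform = rigid_transform(c(1, -2, 1.5) * pi / 180, c(5, -4, 3)),
    seed = 1401))
  reg_truth <- invert_transform(p$truth_setup)  # CBCT -> CT, registration convention
  for (nm in c("ctv", "rectum", "bladder", "body")) {
    moved <- propagate_contour(p$ct_structs[[nm]], reg_truth, grid_of(p$cbct))
    expect_gte(dice(moved, p$cbct_structs_truth[[nm]]), 0.95)
  }
})

test_that("CBCT organ means follow the linear intensity model", {
  p <- generate_pair(coarse_spec(seed = 31))  # identity setup, gain 0.9, offset -20
  s <- p$cbct_structs_truth
  ints <- c(ctv = 40, bladder = 10)
  for (nm in names(ints)) {
    vals <- p$cbct$voxels[s[[nm]]$voxels == 1]
    expected <- 0.9 * ints[[nm]] - 20
    expect_lt(abs(mean(vals) - expected), 3 * 10 / sqrt(length(vals)) + 0.5)
  }
})

test_that("empty-rectum phantom keeps rectum and prostate CT intensities close", {
  p <- generate_pair(coarse_spec(seed = 6))
  ir <- mean(p$ct$voxels[p$ct_structs$rectum$voxels == 1])
  ip <- mean(p$ct$voxels[p$ct_structs$ctv$voxels == 1])
  expect_lte(abs(ir - ip), 15)
})

test_that("cohorts are reproducible and span the distension grid", {
  g <- list(c(1, 0), c(1.3, 0.5, 0.1))
  a <- make_cohort(2, g, seed = 12, base_spec = coarse_spec())
  b <- make_cohort(2, g, seed = 12, base_spec = coarse_spec())
  expect_identical(a[[1]]$cbct$voxels, b[[1]]$cbct$voxels)
  expect_identical(a[[2]]$spec$distension_factor, 1.3)
  expect_identical(a[[2]]$spec$gas_fraction_ct, 0.1)
  expect_error(make_cohort(0, g), "n_pairs")
  expect_error(make_cohort(2, list()), "empty")
})

test_that("cohort F values track the injected gas", {
  # gas-free grid -> F clusters near zero
  quiet <- make_cohort(3, list(c(1, 0)), seed = 40, base_spec = coarse_spec(),
                       setup_trans_mm = 2, setup_rot_deg = 0.5, prostate_offset_mm = 2)
  fs <- sapply(quiet, function(p) {
    rp <- compute_rpartial(p$ct_structs$rectum, p$ct_structs$ctv, 8)
    compute_F(p$ct, p$cbct, invert_transform(p$truth_setup), p$ct_structs$ctv, rp)$F
  })
  expect_true(all(fs < 20))
  # graded gas -> F non-decreasing on average (rank correlation)
  gs <- c(0, 0.2, 0.4, 0.6, 0.8)
  fs2 <- sapply(gs, function(g) {
    p <- generate_pair(coarse_spec(gas_fraction = g, distension_factor = 1.3, seed = 41))
    rp <- compute_rpartial(p$ct_structs$rectum, p$ct_structs$ctv, 8)
    compute_F(p$ct, p$cbct, identity_transform(), p$ct_structs$ctv, rp)$F
  })
  expect_gt(cor(gs, fs2, method = "spearman"), 0.9)
})
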