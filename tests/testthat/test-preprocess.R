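test_that("isocenter offset shifts origins and nothing else", {
  p <- generate_pair(coarse_spec(seed = 3))
  out <- apply_isocenter_offset(p$ct, p$ct_structs, ct_isocenter = c(10, 0, 0))
  expect_equal(out$ct$origin, p$ct$origin - c(10, 0, 0))
  expect_identical(out$ct$voxels, p$ct$voxels)
  expect_equal(out$ct_structs$ctv$origin, p$ct_structs$ctv$origin - c(10, 0, 0))
  # equal isocenters -> identity
  same <- apply_isocenter_offset(p$ct, p$ct_structs, c(0, 0, 0), c(0, 0, 0))
  expect_equal(same$ct$origin, p$ct$origin)
  expect_error(apply_isocenter_offset(p$ct, p$ct_structs, c(NA, 0, 0)), "isocenter")
})

test_that("isocenter offset restores the no-registration overlap", {
  p <- generate_pair(coarse_spec(seed = 13))
  iso <- c(12, -8, 6)
  shifted_ct <- p$ct; shifted_ct$origin <- shifted_ct$origin + iso
  shifted_structs <- lapply(p$ct_structs, function(m) { m$origin <- m$origin + iso; m })
  class(shifted_structs) <- "StructureSet"
  d_before <- dice_noreg(shifted_structs$ctv, p$cbct_structs_truth$ctv)
  fixed <- apply_isocenter_offset(shifted_ct, shifted_structs, ct_isocenter = iso)
  d_after <- dice_noreg(fixed$ct_structs$ctv, p$cbct_structs_truth$ctv)
  expect_gt(d_after, d_before)
})

test_that("body masking keeps the largest component and fills holes", {
  # uniform tissue volume -> full-volume mask
  u <- image_volume(array(30, c(10, 10, 6)), c(1, 1, 1))
  expect_equal(sum(compute_body_mask(u)$voxels), 600)
  # two disjoint bright blobs -> only the larger survives
  v <- image_volume(array(-1000, c(24, 24, 8)), c(1, 1, 1))
  v$voxels[2:12, 2:12, 2:7] <- 30    # large blob
  v$voxels[18:21, 18:21, 2:4] <- 30  # small blob
  bm <- compute_body_mask(v)
  expect_equal(sum(bm$voxels[18:21, 18:21, ]), 0)
  expect_gt(sum(bm$voxels[2:12, 2:12, ]), 0)
  # an internal air cavity is filled
  v$voxels[5:8, 5:8, 3:5] <- -1000
  bm2 <- compute_body_mask(v)
  expect_true(all(bm2$voxels[5:8, 5:8, 3:5] == 1))
  expect_error(compute_body_mask(image_volume(array(-1000, c(4, 4, 4)), c(1, 1, 1))),
               "no body found")
})

test_that("phantom body mask matches the rasterized truth", {
  p <- fixture_moved_pair()
  for (side in c("ct", "cbct")) {
    v <- p[[side]]
    truth <- if (side == "ct") p$ct_structs$body else p$cbct_structs_truth$body
    expect_gte(dice(compute_body_mask(v), truth), 0.99)
  }
})

test_that("bone thresholding clamps from below at the modality level", {
  v <- image_volume(array(c(149, 151, -500, 700), c(2, 2, 1)), c(1, 1, 1))
  out <- threshold_bone(v)
  expect_equal(as.numeric(out$voxels), c(150, 151, 150, 700))
  # uniform soft tissue flattens to a constant: no gradient left anywhere
  u <- threshold_bone(image_volume(array(30, c(4, 4, 4)), c(1, 1, 1)))
  expect_true(all(u$voxels == 150))
  # CBCT threshold is -140 au
  vc <- image_volume(array(c(-141, -139), c(2, 1, 1)), c(1, 1, 1), modality = "CBCT")
  expect_equal(as.numeric(threshold_bone(vc)$voxels), c(-140, -139))
  # on the phantom, voxels strictly above threshold are exactly the true bone
  p <- fixture_moved_pair()
  bone_set <- p$ct$voxels > 150
  expect_true(all(p$ct$voxels[bone_set] == 700))
  expect_false(any(p$ct$voxels[!bone_set] > 150))
})

test_that("gas replacement clamps below the modality gas threshold", {
  v <- image_volume(array(c(-1000, -151, -150, 30), c(2, 2, 1)), c(1, 1, 1))
  out <- replace_gas(v)
  expect_equal(as.numeric(out$voxels), c(-150, -150, -150, 30))
  vc <- image_volume(array(c(-800, -499), c(2, 1, 1)), c(1, 1, 1), modality = "CBCT")
  expect_equal(as.numeric(replace_gas(vc)$voxels), c(-500, -499))
  # no sub-threshold voxel -> identity
  u <- image_volume(array(30, c(3, 3, 3)), c(1, 1, 1))
  expect_identical(replace_gas(u)$voxels, u$voxels)
})

test_that("clamp filters are idempotent and monotone", {
  set.seed(20)
  v <- image_volume(array(runif(6^3, -1200, 900), c(6, 6, 6)), c(1, 1, 1))
  w <- v; w$voxels <- w$voxels + abs(rnorm(6^3))  # pointwise >= v
  for (f in list(replace_gas, threshold_bone)) {
    expect_identical(f(f(v))$voxels, f(v)$voxels)
    expect_true(all(f(w)$voxels >= f(v)$voxels))
  }
})

test_that("margin expansion is exact against the brute-force oracle", {
  # single voxel, isotropic: 33 voxels within Euclidean distance 2
  m <- binary_mask(array(0, c(9, 9, 9)), c(1, 1, 1)); m$voxels[5, 5, 5] <- 1
  expect_equal(sum(expand_margin(m, 2)$voxels), 33)
  # anisotropic spacing: a 2 mm margin cannot reach the next 3 mm slice
  ma <- binary_mask(array(0, c(9, 9, 5)), c(1, 1, 3)); ma$voxels[5, 5, 3] <- 1
  e <- expand_margin(ma, 2)
  expect_equal(sum(e$voxels[, , -3]), 0)
  # margin 0 is the identity; negative margins are refused
  expect_identical(expand_margin(m, 0)$voxels, m$voxels)
  expect_error(expand_margin(m, -1), "non-negative")
  # random masks against the O(n^2) physical-distance oracle
  set.seed(14)
  for (rep in 1:3) {
    d <- c(12, 10, 8); sp <- c(1, 1.5, 3)
    r <- array(as.numeric(runif(prod(d)) < 0.05), d)
    if (sum(r) == 0) r[6, 5, 4] <- 1
    rm <- binary_mask(r, sp)
    for (margin in c(1.4, 3, 4.5))
      expect_identical(expand_margin(rm, margin)$voxels, oracle_expand(r, sp, margin))
  }
})

test_that("margin expansion is monotone and a superset of its input", {
  set.seed(15)
  r <- array(as.numeric(runif(10^3) < 0.03), c(10, 10, 10))
  r[5, 5, 5] <- 1
  m <- binary_mask(r, c(1, 2, 1))
  prev <- m
  for (margin in c(1, 2, 4, 8)) {
    e <- expand_margin(m, margin)
    expect_true(all(e$voxels >= m$voxels))
    expect_true(all(e$voxels >= prev$voxels))
    prev <- e
  }
})
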