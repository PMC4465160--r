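test_that("volume and mask constructors enforce their invariants", {
  expect_error(image_volume(array(1, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(1, c(4, 4, 4)), c(1, 0, 1)), "positive")
  expect_error(image_volume(array(c(1, NA), c(4, 4, 4)), c(1, 1, 1)), "finite")
  expect_error(binary_mask(array(0.5, c(2, 2, 2)), c(1, 1, 1)), "0 or 1")
  m <- binary_mask(array(c(1, 0), c(2, 2, 2)), c(1, 1, 3))
  expect_equal(mask_volume(m), 4 * 3)  # 4 voxels of 1x1x3 mm
  v <- image_volume(array(0, c(2, 2, 2)), c(1, 1, 1), modality = "CBCT")
  expect_identical(v$modality, "CBCT")
})

test_that("structure sets require one shared grid", {
  m <- function(sp = c(1, 1, 1), o = c(0, 0, 0))
    binary_mask(array(1, c(3, 3, 3)), sp, o)
  s <- structure_set(m(), m(), m(), m())
  expect_s3_class(s, "StructureSet")
  expect_error(structure_set(m(), m(sp = c(1, 1, 2)), m(), m()), "shared grid")
  expect_error(structure_set(m(), m(o = c(1, 0, 0)), m(), m()), "shared grid")
})

test_that("write/read round-trips preserve voxels and geometry", {
  set.seed(11)
  v <- image_volume(array(rnorm(16 * 16 * 8), c(16, 16, 8)),
                    spacing = c(1, 1, 3), origin = c(-7.5, -7.5, -10.5))
  for (ext in c(".mha", ".nii", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    v2 <- read_volume(f)
    expect_equal(v2$voxels, v$voxels, tolerance = 1e-6)  # float32 storage
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
    expect_equal(v2$origin, v$origin, tolerance = 1e-5)
    unlink(f)
  }
  # masks round-trip exactly and keep the {0,1} invariant
  m <- binary_mask(array(as.numeric(v$voxels > 0.5), dim(v$voxels)), v$spacing, v$origin)
  f <- tempfile(fileext = ".mha")
  write_volume(m, f)
  m2 <- read_volume(f, as_mask = TRUE)
  expect_identical(m2$voxels, m$voxels)
  expect_true(all(m2$voxels %in% c(0, 1)))
  unlink(f)
  expect_error(read_volume(tempfile(fileext = ".mha")), "not found")
  bad <- tempfile(fileext = ".txt"); file.create(bad)
  expect_error(read_volume(bad), "unsupported")
  unlink(bad)
})

test_that("resampling matches the integer index-shift oracle", {
  set.seed(3)
  v <- image_volume(array(rnorm(12 * 10 * 8), c(12, 10, 8)), c(2, 1, 3))
  # identity on the same grid is exact
  expect_identical(resample(v)$voxels, v$voxels)
  expect_identical(resample(v, interp = "nearest")$voxels, v$voxels)
  # translation by exactly one voxel spacing along x = index shift + fill
  t1 <- rigid_transform(translations = c(v$spacing[1], 0, 0))
  r <- resample(v, t1)
  expect_equal(r$voxels[1:11, , ], v$voxels[2:12, , ])
  expect_true(all(r$voxels[12, , ] == -1000))  # CT air fill at the vacated face
  # nearest-neighbor mask resampling preserves the value set
  m <- binary_mask(array(as.numeric(v$voxels > 0), dim(v$voxels)), v$spacing)
  rm <- resample(m, rigid_transform(translations = c(0.4, -0.7, 1.2)), grid_of(m))
  expect_true(all(rm$voxels %in% c(0, 1)))
  expect_error(resample(v, rigid_transform(translations = c(NaN, 0, 0))), "non-finite")
})

test_that("resampling composes like the composed transform on smooth volumes", {
  g <- seq(-15, 15)
  vox <- outer(exp(-g^2 / 80), exp(-g^2 / 60)) %o% exp(-g^2 / 100)
  v <- image_volume(vox, c(1, 1, 1), origin = c(-15, -15, -15))
  t1 <- rigid_transform(c(0.02, 0, 0.01), c(1.5, -1, 0.5))
  t2 <- rigid_transform(c(0, -0.01, 0), c(-0.5, 2, 1))
  step2 <- resample(resample(v, t1), t2)
  once <- resample(v, compose_transform(t1, t2))
  core <- 8:24  # away from fill-affected borders
  expect_equal(step2$voxels[core, core, core], once$voxels[core, core, core],
               tolerance = 0.02)
})

test_that("surface extraction matches brute-force neighbor counting", {
  m <- binary_mask(array(0, c(5, 5, 5)), c(1, 1, 1))
  m$voxels[3, 3, 3] <- 1
  p <- surface_points(m)
  expect_equal(nrow(p), 1)
  expect_equal(as.numeric(p), c(2, 2, 2))  # physical center of index (2,2,2) 0-based
  # solid 3x3x3 cube: all but the center voxel are surface
  cube <- binary_mask(array(0, c(5, 5, 5)), c(1, 1, 1))
  cube$voxels[2:4, 2:4, 2:4] <- 1
  expect_equal(nrow(surface_points(cube)), 26)
  expect_equal(oracle_surface_count(cube$voxels), 26)
  # 1x1x5 rod: every voxel touches background
  rod <- binary_mask(array(0, c(3, 3, 7)), c(1, 1, 1))
  rod$voxels[2, 2, 2:6] <- 1
  expect_equal(nrow(surface_points(rod)), 5)
  # random shapes agree with the oracle
  set.seed(5)
  for (rep in 1:3) {
    r <- binary_mask(array(as.numeric(runif(6^3) < 0.4), c(6, 6, 6)), c(1, 1, 2))
    if (sum(r$voxels) == 0) next
    expect_equal(nrow(surface_points(r)), oracle_surface_count(r$voxels))
  }
  expect_error(surface_points(binary_mask(array(0, c(3, 3, 3)), c(1, 1, 1))),
               "empty structure")
})

test_that("surface points are mask voxel centers and all load-bearing", {
  set.seed(8)
  m <- binary_mask(array(0, c(8, 8, 8)), c(1, 2, 1), origin = c(3, -2, 0))
  m$voxels[3:6, 3:6, 3:6] <- 1
  pts <- surface_points(m)
  ax <- grid_axes(m)
  for (r in seq_len(nrow(pts))) {
    idx <- c(which(abs(ax[[1]] - pts[r, 1]) < 1e-9),
             which(abs(ax[[2]] - pts[r, 2]) < 1e-9),
             which(abs(ax[[3]] - pts[r, 3]) < 1e-9))
    expect_equal(m$voxels[idx[1], idx[2], idx[3]], 1)
  }
})
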