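test_that("volume_cm3 follows voxel count times voxel volume", {
  g <- unit_grid(c(10, 10, 10), c(1, 1, 1))
  expect_equal(volume_cm3(mask_on(g)), 0)
  expect_equal(volume_cm3(binary_structure(array(TRUE, c(10, 10, 10)), g)), 1.0)
  g2 <- unit_grid(c(20, 20, 20), c(1.0, 1.0, 2.5))
  expect_equal(volume_cm3(binary_structure(array(TRUE, c(20, 20, 20)), g2)), 20.0)
})

test_that("translate_structure shifts by the nearest-integer voxel shift", {
  g <- unit_grid(c(12, 12, 12), c(1, 1, 1))
  s <- mask_on(g)
  s$mask[6, 6, 6] <- TRUE
  expect_identical(translate_structure(s, c(0, 0, 0))$mask, s$mask)
  shifted <- translate_structure(s, c(0, 0, 1))
  expect_true(shifted$mask[6, 6, 7])
  expect_equal(sum(shifted$mask), 1L)
  # round-half-away-from-zero: 1.4 mm at 1 mm spacing moves 1 voxel
  cube <- cube_structure(g, c(4, 4, 4), c(8, 8, 8))
  sh <- translate_structure(cube, c(1.4, 0, 0))
  expect_identical(sh$mask[5:9, 4:8, 4:8], cube$mask[4:8, 4:8, 4:8])
  # and 1.5 mm moves 2 voxels (away from zero on the tie)
  sh2 <- translate_structure(cube, c(-1.5, 0, 0))
  expect_identical(sh2$mask[2:6, 4:8, 4:8], cube$mask[4:8, 4:8, 4:8])
  expect_error(translate_structure(cube, c(200, 0, 0)), "exceeds")
})

test_that("volume is invariant under interior translation, clipped at edges", {
  g <- unit_grid(c(24, 24, 24), c(1.5, 1.5, 1.5))
  s <- random_blobs(g, n_blobs = 2, r_range = c(2, 4), seed = 4)
  v0 <- volume_cm3(s)
  expect_equal(volume_cm3(translate_structure(s, c(3, -3, 1.5))), v0)
  edge <- cube_structure(g, c(1, 1, 1), c(4, 4, 4))
  expect_warning(clipped <- translate_structure(edge, c(-1.5, 0, 0)), "dropped")
  expect_lt(volume_cm3(clipped), volume_cm3(edge))
})

test_that("resample_to_reference: identity is bit-exact, voxel shifts are exact", {
  g <- unit_grid(c(16, 16, 16), c(1, 1, 1))
  set.seed(9)
  vol <- image_volume(array(rnorm(16^3), c(16, 16, 16)), c(1, 1, 1))
  expect_identical(resample_to_reference(vol, g, rigid_transform())$data, vol$data)
  s <- mask_on(g)
  s$mask[8, 8, 8] <- TRUE
  expect_identical(resample_to_reference(s, g, rigid_transform())$mask, s$mask)
  # translation of exactly one voxel pitch moves the mask one index
  sh <- resample_to_reference(s, g, rigid_transform(translation = c(1, 0, 0)))
  expect_true(sh$mask[9, 8, 8] || sh$mask[7, 8, 8])
  expect_equal(sum(sh$mask), 1L)
})

test_that("resample round trip recovers the mask (DICE >= 0.9)", {
  g <- unit_grid(c(32, 32, 32), c(1, 1, 1))
  s <- random_blobs(g, n_blobs = 3, r_range = c(2, 5), seed = 11)
  tr <- rigid_transform(translation = c(3.2, -1.7, 4.4))
  fwd <- resample_to_reference(s, g, tr)
  back <- resample_to_reference(fwd, g, invert_transform(tr))
  expect_gte(dice(s, back), 0.9)
  # with a rotation the shell erosion stays within a one-voxel band
  tr2 <- rigid_transform(translation = c(2.2, -1.1, 0.6),
                         rotation = c(4, -2, 3), center = c(16, 16, 16))
  fwd2 <- resample_to_reference(s, g, tr2)
  back2 <- resample_to_reference(fwd2, g, invert_transform(tr2))
  expect_gte(dice(s, back2), 0.8)
})

test_that("transform algebra: inverse composes to the identity", {
  tr <- rigid_transform(translation = c(3, -2, 5), rotation = c(7, -3, 2),
                        center = c(10, 20, 30))
  inv <- invert_transform(tr)
  pts <- matrix(rnorm(30, sd = 40), 10, 3)
  expect_equal(apply_transform(inv, apply_transform(tr, pts)), pts,
               tolerance = 1e-10)
  expect_equal(apply_transform(tr, tr$center),
               tr$center + tr$translation)
})

test_that("constructor invariants are enforced", {
  expect_error(image_volume(array(0, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(0, c(4, 4, 4)), c(1, -1, 1)), "positive")
  expect_error(rigid_transform(rotation = c(0, 0, 200)), "180")
  expect_error(anatomical_margin(left = -1), ">= 0")
  expect_error(deformation_vector_new("s", c(1, NA, 0)), "finite")
  g <- unit_grid(c(8, 8, 8))
  expect_error(dice(mask_on(g), mask_on(unit_grid(c(9, 9, 9)))),
               "different grids")
})

test_that("study_set validates secondaries, CTV and ROI disjointness", {
  g <- unit_grid(c(16, 16, 16))
  ctv <- cube_structure(g, c(7, 7, 7), c(9, 9, 9))
  roi_a <- cube_structure(g, c(1, 1, 1), c(3, 3, 3))
  roi_b <- cube_structure(g, c(12, 12, 12), c(14, 14, 14))
  roi_c <- cube_structure(g, c(1, 12, 1), c(3, 14, 3))
  rois <- list(spine = roi_a, marker = roi_b, refstruct = roi_c)
  expect_s3_class(study_set(g, list(ibh = g), ctv, rois), "study_set")
  expect_error(study_set(g, list(), ctv, rois), "at least one")
  expect_error(study_set(g, list(ibh = g), mask_on(g), rois), "non-empty")
  rois_bad <- rois
  rois_bad$marker <- roi_a
  expect_error(study_set(g, list(ibh = g), ctv, rois_bad), "overlap")
})
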