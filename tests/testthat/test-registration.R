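# Registration tests run on compact synthetic scenes plus one full phantom
# (cached, shared with the validation suite).

test_that("detect_marker finds the brightest component centroid", {
  g <- unit_grid(c(21, 21, 21), c(1, 1, 1))
  img <- g
  img$data[11, 21, 21] <- 0 # keep dims
  img$data[11, 21, 16] <- 0
  img$data[11, 21, 31 - 10] <- 0
  img$data[] <- 0
  img$data[11, 21, 21] <- 0
  roi <- binary_structure(array(TRUE, c(21, 21, 21)), g, "roi")
  # single bright voxel at physical (10, 20, 15)
  img$data[11, 21, 16] <- 3000
  expect_equal(detect_marker(img, roi), c(10, 20, 15))
  # a 2x2x2 bright component outweighs a brighter single voxel
  img$data[] <- 0
  img$data[3:4, 3:4, 3:4] <- 2000
  img$data[15, 15, 15] <- 3000
  cen <- detect_marker(img, roi)
  expect_equal(cen, c(2.5, 2.5, 2.5))
  img$data[] <- 0
  expect_error(detect_marker(img, roi), "marker not found")
})

test_that("phantom marker is detected within half a voxel of ground truth", {
  run <- phantom_run(1)
  st <- run$ph$study
  truth_pos <- run$ph$spec$heart_center + run$ph$spec$marker_rel
  est <- detect_marker(st$primary, st$rois$marker)
  expect_lt(max(abs(est - truth_pos)), 0.5 * max(st$primary$spacing))
})

test_that("self-registration is the identity at every step", {
  run <- phantom_run(1)
  st <- run$ph$study
  sp <- suppressWarnings(
    register_spine_6d(st$primary, st$primary, st$rois$spine, "self"))
  expect_lt(max(abs(sp$transform$translation)), 0.1)
  expect_lt(max(abs(sp$transform$rotation)), 0.1)
  mk <- register_translation_marker(st$primary, st$primary, st$rois$marker, sp)
  expect_lt(max(abs(mk$transform$translation - sp$transform$translation)), 0.1)
  rf <- register_translation_local(st$primary, st$primary, st$rois$refstruct, mk)
  expect_lt(max(abs(rf$transform$translation - mk$transform$translation)), 0.25)
})

test_that("spine registration recovers programmed body shift and rotation", {
  # known body shift (0, 0, -8), no rotation
  ph <- generate_series(phantom_spec(seed = 41, n_fb = 1L,
                                     body_shifts = c(0, 0, -8)))
  st <- ph$study
  sp <- suppressWarnings(
    register_spine_6d(st$primary, st$secondaries$ibh, st$rois$spine, "ibh"))
  expect_lt(max(abs(sp$transform$translation - c(0, 0, -8))),
            max(st$primary$spacing))
  expect_lt(max(abs(sp$transform$rotation)), 0.5)
  # 2 degree axial rotation
  ph2 <- generate_series(phantom_spec(seed = 42, n_fb = 1L,
                                      body_rotation_deg = 2))
  sp2 <- suppressWarnings(
    register_spine_6d(ph2$study$primary, ph2$study$secondaries$ibh,
                      ph2$study$rois$spine, "ibh"))
  expect_lt(abs(sp2$transform$rotation[1] - 2), 0.5)
})

test_that("registration translation is equivariant under a grid-aligned shift", {
  run <- phantom_run(1)
  st <- run$ph$study
  moving <- st$secondaries$fb1
  v <- c(3, -1.5, 4.5) # multiples of the 1.5 mm pitch
  shifted <- image_volume(moving$data, moving$spacing, moving$origin + v)
  r0 <- suppressWarnings(
    register_spine_6d(st$primary, moving, st$rois$spine, "fb1"))
  r1 <- suppressWarnings(
    register_spine_6d(st$primary, shifted, st$rois$spine, "fb1"))
  expect_lt(max(abs(r1$transform$translation -
                      (r0$transform$translation + v))), 0.2)
})

test_that("marker step copies rotations from the prior exactly", {
  run <- phantom_run(1)
  st <- run$ph$study
  prior_tr <- rigid_transform(translation = c(1, 0, -1),
                              rotation = c(1.5, -0.5, 0.25),
                              center = c(70, 70, 70), moving = "fb1")
  prior <- gdmrt:::registration_result(prior_tr, 0, "spine", 1L,
                                       series_id = "fb1")
  mk <- register_translation_marker(st$primary, st$secondaries$fb1,
                                    st$rois$marker, prior)
  expect_identical(mk$transform$rotation, prior_tr$rotation)
  rf <- register_translation_local(st$primary, st$secondaries$fb1,
                                   st$rois$refstruct, mk)
  expect_identical(rf$transform$rotation, prior_tr$rotation)
})

test_that("flat reference ROI raises the discriminability error", {
  g <- unit_grid(c(24, 24, 24), c(1.5, 1.5, 1.5))
  flat <- image_volume(array(100, c(24, 24, 24)), g$spacing)
  roi <- cube_structure(g, c(9, 9, 9), c(15, 15, 15))
  prior <- gdmrt:::registration_result(rigid_transform(), 0, "marker", 1L)
  expect_error(register_translation_local(flat, flat, roi, prior),
               "not discriminable")
})

test_that("deformation vectors subtract componentwise and are antisymmetric", {
  mk <- gdmrt:::registration_result(
    rigid_transform(translation = c(1, 2, 3), moving = "fb1"), 0, "marker", 1L,
    series_id = "fb1")
  rf <- gdmrt:::registration_result(
    rigid_transform(translation = c(3, 1, 3), moving = "fb1"), 0, "ref", 1L,
    series_id = "fb1")
  expect_equal(deformation_vector(mk, rf)$d, c(2, -1, 0))
  expect_equal(deformation_vector(rf, mk)$d, -deformation_vector(mk, rf)$d)
  other <- gdmrt:::registration_result(
    rigid_transform(moving = "fb2"), 0, "ref", 1L, series_id = "fb2")
  expect_error(deformation_vector(mk, other), "mismatched series")
})

test_that("full chain recovers the programmed marker-target deformation", {
  run <- phantom_run(1)
  for (nm in names(run$ph$truth)) {
    est <- run$reg$vectors[[nm]]$d
    tru <- run$ph$truth[[nm]]$deformation$d
    expect_lt(max(abs(est - tru)), max(run$ph$study$primary$spacing))
  }
})
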