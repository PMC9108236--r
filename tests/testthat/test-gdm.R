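test_that("gdm_margin takes per-direction positive maxima, clamped at zero", {
  m <- gdm_margin(list(c(2.0, -1.0, 0.5), c(1.0, 1.5, -0.5)))
  expect_equal(m$left, 2.0)
  expect_equal(m$right, 0.0)
  expect_equal(m$posterior, 1.5)
  expect_equal(m$anterior, 1.0)
  expect_equal(m$superior, 0.5)
  expect_equal(m$inferior, 0.5)
  z <- gdm_margin(list(c(0, 0, 0)))
  expect_true(all(unlist(z) == 0))
  expect_error(gdm_margin(list()), "at least one")
})

test_that("gdm_margin equals the brute-force half-axis maximum on random vectors", {
  set.seed(77)
  vecs <- lapply(1:100, function(i) rnorm(3, sd = 3))
  m <- gdm_margin(vecs)
  vm <- do.call(rbind, vecs)
  axes <- list(left = vm[, 1], right = -vm[, 1],
               posterior = vm[, 2], anterior = -vm[, 2],
               superior = vm[, 3], inferior = -vm[, 3])
  for (nm in names(axes))
    expect_equal(m[[nm]], max(0, max(axes[[nm]])))
})

test_that("box expansion matches closed forms and the Minkowski oracle", {
  g <- unit_grid(c(20, 20, 20))
  cube <- cube_structure(g, c(5, 5, 5), c(14, 14, 14))
  expect_identical(expand_anisotropic(cube, anatomical_margin())$mask, cube$mask)
  grown <- expand_anisotropic(cube, anatomical_margin(left = 2))
  expect_equal(volume_cm3(grown), 1.20)
  # random structures and margins against the brute-force Minkowski sum
  for (seed in 1:8) {
    gg <- unit_grid(c(32, 32, 32), c(1.5, 1.5, 1.5))
    s <- random_blobs(gg, n_blobs = 2, r_range = c(2, 4), seed = seed)
    if (!any(s$mask)) next
    set.seed(seed + 300)
    mg <- do.call(anatomical_margin, as.list(setNames(runif(6, 0, 4),
      c("anterior", "posterior", "right", "left", "superior", "inferior"))))
    expect_identical(expand_anisotropic(s, mg)$mask, oracle_box_expand(s, mg))
  }
  expect_error(expand_anisotropic(cube, anatomical_margin(left = 50)), "pad")
})

test_that("isotropic expansion equals the brute-force distance test", {
  g <- unit_grid(c(11, 11, 11))
  s <- mask_on(g); s$mask[6, 6, 6] <- TRUE
  ball <- expand_isotropic(s, 2)
  expect_equal(sum(ball$mask), 33L) # digital ball of radius 2
  expect_identical(expand_isotropic(s, 0)$mask, s$mask)
  for (seed in 1:6) {
    gg <- unit_grid(c(26, 26, 26), c(1.5, 1.5, 1.5))
    ss <- random_blobs(gg, n_blobs = 2, r_range = c(2, 4), seed = seed + 40)
    if (!any(ss$mask)) next
    r <- runif(1, 0.5, 3.5)
    expect_identical(expand_isotropic(ss, r)$mask, oracle_iso_expand(ss, r))
  }
})

test_that("itv_gdm_sum unions translated CTV copies", {
  g <- unit_grid(c(20, 20, 20))
  ctv <- cube_structure(g, c(8, 8, 8), c(12, 12, 12))
  expect_identical(itv_gdm_sum(ctv, list())$mask, ctv$mask)
  u <- itv_gdm_sum(ctv, list(c(0, 0, 1)))
  manual <- ctv$mask | translate_structure(ctv, c(0, 0, 1))$mask
  expect_identical(u$mask, manual)
  # voxel-count (inclusion-exclusion style) oracle on random vectors
  set.seed(12)
  vecs <- lapply(1:3, function(i) runif(3, -4, 4))
  u3 <- itv_gdm_sum(ctv, vecs)
  manual3 <- ctv$mask
  for (v in vecs) manual3 <- manual3 | translate_structure(ctv, v)$mask
  expect_identical(u3$mask, manual3)
  expect_equal(sum(u3$mask), sum(manual3))
})

test_that("target set holds the containment chain and monotone volumes", {
  g <- unit_grid(c(40, 40, 40), c(1.5, 1.5, 1.5))
  ctv <- random_blobs(g, n_blobs = 2, r_range = c(3, 6), seed = 9)
  set.seed(91)
  vecs <- lapply(1:4, function(i) runif(3, -4, 4))
  ts <- build_target_set(ctv, vecs, iso_margin_mm = 2)
  expect_true(contains(ts$itv_gdm_sum, ts$ctv))
  expect_true(contains(ts$itv_gdm, ts$itv_gdm_sum))
  expect_true(contains(ts$ptv_gdm, ts$itv_gdm))
  expect_true(contains(ts$ptv_gdm_sum, ts$itv_gdm_sum))
  expect_gt(volume_cm3(ts$ptv_gdm), volume_cm3(ts$itv_gdm))
  expect_gt(volume_cm3(ts$ptv_gdm_sum), volume_cm3(ts$itv_gdm_sum))
  expect_lte(volume_cm3(ts$itv_gdm_sum), volume_cm3(ts$itv_gdm))
  # zero vectors, zero margin: everything equals the CTV
  t0 <- build_target_set(ctv, list(), iso_margin_mm = 0)
  for (nm in c("itv_gdm", "itv_gdm_sum", "ptv_gdm", "ptv_gdm_sum"))
    expect_identical(t0[[nm]]$mask, ctv$mask)
})

test_that("enlarging a margin component never shrinks the expansion", {
  g <- unit_grid(c(30, 30, 30))
  s <- random_blobs(g, n_blobs = 2, r_range = c(2, 4), seed = 31)
  base <- anatomical_margin(left = 1, superior = 2)
  bigger <- anatomical_margin(left = 3, superior = 2)
  e1 <- expand_anisotropic(s, base)
  e2 <- expand_anisotropic(s, bigger)
  expect_true(contains(e2, e1))
  expect_gte(volume_cm3(e2), volume_cm3(e1))
})

test_that("ellipsoid kernel is contained in the box kernel", {
  g <- unit_grid(c(26, 26, 26))
  s <- cube_structure(g, c(11, 11, 11), c(15, 15, 15))
  m <- anatomical_margin(left = 3, right = 2, anterior = 2, posterior = 3,
                         superior = 2, inferior = 3)
  box <- expand_anisotropic(s, m, kernel = "box")
  ell <- expand_anisotropic(s, m, kernel = "ellipsoid")
  expect_true(contains(box, ell))
  expect_true(contains(ell, s))
})
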