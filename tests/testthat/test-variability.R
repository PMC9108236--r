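test_that("pair enumeration follows the 6-intra / 9-inter scheme", {
  intra <- enumerate_intra_pairs(1:3)
  expect_equal(nrow(intra), 3L)
  expect_equal(unname(as.matrix(intra)), cbind(c(1, 1, 2), c(2, 3, 3)))
  expect_error(enumerate_intra_pairs(1:2), "exactly 3")
  inter <- enumerate_inter_pairs(1:3, 1:3)
  expect_equal(nrow(inter), 9L)
  expect_error(enumerate_inter_pairs(1:3, 1:2), "exactly 3")
  # both observers together give 6 intra records per patient,
  # 5 patients give 45 inter records
  expect_equal(2 * nrow(intra), 6L)
  expect_equal(5 * nrow(inter), 45L)
})

test_that("fixture tables have the documented shapes", {
  intra <- clinical_reference_table("intra")
  inter <- clinical_reference_table("inter")
  ptv <- clinical_reference_table("ptv_dice")
  expect_equal(nrow(intra), 30L) # 6 comparisons x 5 patients
  expect_equal(nrow(inter), 45L) # 9 comparisons x 5 patients
  expect_equal(length(unique(ptv$row)), 12L)
  expect_true(all(ptv$dice >= 0 & ptv$dice <= 1))
})

test_that("row summaries reproduce the printed PTV-comparison statistics", {
  ptv <- clinical_reference_table("ptv_dice")
  st <- summarize_records(ptv, value = "dice", by = "row")
  row1 <- st[st$group == "1PTV_GDM vs PTV", ]
  expect_equal(row1$mean_display, 0.73)
  expect_equal(round(row1$sd, 3), 0.083)
  expect_equal(st[st$group == "1PTV_GDM vs 2PTV_GDM", "mean_display"], 0.89)
  mim_velo <- st[st$group == "PTV_MIM vs PTV_VELO", ]
  expect_equal(mim_velo$mean_display, 0.85)
  expect_equal(round(mim_velo$sd, 3), 0.063)
  # constant list has zero SD
  const <- summarize_records(data.frame(dice = rep(0.8, 5)), value = "dice")
  expect_equal(const$sd, 0)
})

test_that("pooled means reproduce the published group contrast", {
  ptv <- clinical_reference_table("ptv_dice")
  vs_ptv <- pooled_mean(ptv, select = function(d) d$vol_b == "PTV" &
                          d$vol_a == "1PTV_GDM")
  expect_equal(round(vs_ptv$mean, 2), 0.73)
  pool_all_ptv <- pooled_mean(ptv, select = function(d) d$vol_b == "PTV")
  expect_equal(pool_all_ptv$n, 12L)
  expect_equal(round(pool_all_ptv$mean, 2), 0.73)
  non_ptv <- pooled_mean(ptv, select = function(d) d$vol_b != "PTV")
  expect_equal(non_ptv$n, 60L)
  expect_equal(round(non_ptv$mean, 2), 0.84)
  # a single row pools to that row's own mean
  one <- pooled_mean(ptv, select = function(d) d$row == "PTV_MIM vs PTV_VELO")
  st <- summarize_records(ptv, value = "dice", by = "row")
  expect_equal(one$mean, st[st$group == "PTV_MIM vs PTV_VELO", "mean"])
  expect_error(pooled_mean(ptv, select = function(d) d$patient > 100), "empty")
})

test_that("observer-variability grand means match the printed table footers", {
  intra <- clinical_reference_table("intra")
  inter <- clinical_reference_table("inter")
  expect_equal(round(mean(intra$dice), 2), 0.89)
  expect_equal(round(mean(intra$h_ave_mm), 1), 1.1)
  expect_equal(round(mean(inter$dice), 2), 0.88)
  expect_equal(round(mean(inter$h_ave_mm), 1), 1.2)
})

test_that("group tests behave as designed", {
  set.seed(101)
  a <- rnorm(30, 0, 1); b <- rnorm(30, 1, 1)
  welch <- group_test(a, b, mode = "welch")
  expect_true(welch$significant)
  same <- group_test(c(1, 2, 3, 4), c(1, 2, 3, 4), mode = "paired")
  expect_false(same$significant)
  expect_error(group_test(1:4, 1:5, mode = "paired"), "equal-length")
  expect_error(group_test(1, 1:5), "at least 2")
})

test_that("margin_for_coverage is the inclusive empirical quantile", {
  expect_equal(margin_for_coverage(c(0, 0, 0), 0.5), 0)
  expect_equal(margin_for_coverage(c(1, 2, 3), 2 / 3), 2)
  pooled <- c(clinical_reference_table("intra")$h_ave_mm,
              clinical_reference_table("inter")$h_ave_mm)
  expect_equal(length(pooled), 75L)
  expect_equal(margin_for_coverage(pooled, 1.0), 3.1)
  # monotone in the coverage fraction
  fr <- seq(0.1, 1, by = 0.1)
  ms <- vapply(fr, function(f) margin_for_coverage(pooled, f), numeric(1))
  expect_true(all(diff(ms) >= 0))
})

test_that("histograms use the fixed bins and conserve counts", {
  intra <- clinical_reference_table("intra")
  inter <- clinical_reference_table("inter")
  hd <- histogram_report(intra$dice, metric = "dice", kind = "differential")
  expect_equal(sum(hd$count), 30L)
  expect_equal(unique(round(hd$bin_hi - hd$bin_lo, 10)), 0.05)
  hd2 <- histogram_report(inter$dice, metric = "dice", kind = "differential")
  expect_equal(sum(hd2$count), 45L)
  hc <- histogram_report(c(intra$h_ave_mm, inter$h_ave_mm),
                         metric = "h_ave", kind = "cumulative")
  expect_true(all(diff(hc$count) >= 0))
  expect_equal(hc$count[nrow(hc)], 75L)
  f <- withr::local_tempfile(fileext = ".png")
  histogram_report(intra$dice, metric = "dice", plot_file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
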