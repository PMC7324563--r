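# Tissue segmentation, channel thresholding, area fractions, viability,
# nuclei counting and the longitudinal report.

test_that("tissue segmentation recovers a synthetic disk area", {
  img <- disk_image(256, radius = 100)
  seg <- segment_tissue(img, pixel_size = 10)
  expect_equal(seg$area_mm2, pi * 1^2, tolerance = 0.02)  # r = 100 px = 1 mm
  # idempotent: segmenting the mask reproduces the same area
  seg2 <- segment_tissue(seg$mask * 1, pixel_size = 10)
  expect_equal(seg2$area_mm2, seg$area_mm2)
  # area scales exactly with pixel size squared
  seg3 <- segment_tissue(img, pixel_size = 20)
  expect_equal(seg3$area_mm2, 4 * seg$area_mm2)
  expect_error(segment_tissue(matrix(0.3, 64, 64), 10), "uniform")
})

test_that("channel thresholding separates bimodal intensities", {
  tis <- matrix(TRUE, 64, 64)
  withr::with_seed(6, {
    img <- matrix(stats::rnorm(64^2, 0.2, 0.03), 64, 64)
    bright <- matrix(FALSE, 64, 64); bright[20:40, 20:40] <- TRUE
    img[bright] <- stats::rnorm(sum(bright), 0.8, 0.03)
  })
  m <- channel_mask(img, tis, method = "otsu")
  expect_gt(mean(m[bright]), 0.99)
  expect_lt(mean(m[!bright]), 0.01)
  expect_equal(sum(channel_mask(matrix(0, 64, 64), tis)), 0)
  img_pos <- matrix(0.5, 64, 64)
  expect_true(all(channel_mask(img_pos, tis, method = "fixed", t = 0)))
  expect_error(channel_mask(img_pos, tis, method = "fixed", t = 2),
               "intensity range")
})

test_that("area fractions count pixels and yellow is the intersection", {
  tis <- matrix(TRUE, 10, 10)
  red <- matrix(FALSE, 10, 10); red[1:2, 1:10] <- TRUE    # 20 px
  green <- matrix(FALSE, 10, 10); green[2:3, 1:5] <- TRUE
  green[2, 5] <- FALSE; green[4, 6] <- TRUE               # 10 px, 4 in red
  fr <- area_fractions(red, green, tis)
  expect_equal(unname(fr), c(20, 10, 4))
  expect_lte(fr[["yellow_pct"]], min(fr[["red_pct"]], fr[["green_pct"]]))
  fr0 <- area_fractions(red, matrix(FALSE, 10, 10), tis)
  expect_equal(unname(fr0[c("green_pct", "yellow_pct")]), c(0, 0))
  expect_error(area_fractions(red, green, matrix(FALSE, 10, 10)),
               "empty tissue")
})

test_that("viability is the live share of stained area", {
  live <- matrix(FALSE, 20, 20); live[1:15, 1:20] <- TRUE   # 300
  dead <- matrix(FALSE, 20, 20); dead[16:20, 1:20] <- TRUE  # 100
  expect_equal(viability(live, dead), 75)
  expect_equal(viability(live, matrix(FALSE, 20, 20)), 100)
  # fixed (killed) control: all signal in the dead channel
  expect_equal(viability(matrix(FALSE, 20, 20), dead), 0)
  expect_error(viability(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("nuclei counting finds well-separated nuclei and merges close pairs", {
  fx <- nuclei_image(n = 12)
  res <- count_nuclei(fx$img, matrix(TRUE, 128, 128))
  expect_equal(res$count, 12)
  # blank image
  expect_equal(count_nuclei(matrix(0, 64, 64), matrix(TRUE, 64, 64))$count, 0)
  # two nuclei closer than the suppression distance merge into one
  close_img <- gaussian_spot(64, 30, 30) + gaussian_spot(64, 33, 30)
  expect_equal(count_nuclei(close_img, matrix(TRUE, 64, 64))$count, 1)
  # counts invariant to uniform intensity gain
  expect_equal(count_nuclei(0.3 * fx$img, matrix(TRUE, 128, 128))$count, 12)
})

test_that("MFI per cell is linear and reproduces the uptake fold difference", {
  tis <- matrix(TRUE, 32, 32)
  img <- matrix(0.4, 32, 32)
  expect_equal(mfi_per_cell(img, tis, 10), 0.04)
  expect_equal(mfi_per_cell(2 * img, tis, 10), 0.08)
  expect_equal(mfi_per_cell(matrix(0, 32, 32), tis, 5), 0)
  expect_error(mfi_per_cell(img, tis, 0), "n_cells")
  # printed group means 0.53 vs 0.075 -> a 7-fold uptake difference
  expect_equal(round(fold_change(0.53, 0.075)), 7)
})

test_that("marker-positive nuclei are counted by neighbourhood intensity", {
  fx <- nuclei_image(n = 25)
  marker <- matrix(0, 128, 128)
  pos_idx <- 1:10
  for (i in pos_idx)
    marker <- marker + gaussian_spot(128, fx$centers[i, 1], fx$centers[i, 2])
  det <- count_nuclei(fx$img, matrix(TRUE, 128, 128))
  expect_equal(det$count, 25)
  mp <- marker_positive_count(marker, det$centers, threshold = 0.2)
  expect_equal(mp$count, 10)
  expect_equal(mp$fraction, 10 / 25)
  none <- marker_positive_count(marker, det$centers, threshold = 2)
  expect_equal(none$count, 0)
})

test_that("longitudinal report tracks cumulative green and transient yellow", {
  tl <- synth_timelapse(size = 160, conversion_rate = 3, days = 0:6, seed = 7)
  rep <- longitudinal_report(tl$series, method = "fixed",
                             t = tl$truth$mask_threshold)
  expect_equal(nrow(rep), 7)
  truth <- tl$truth$fractions
  after <- truth$green_pct > 0
  expect_equal(rep$green_pct[after], truth$green_pct[after], tolerance = 0.1)
  expect_equal(rep$red_pct, truth$red_pct, tolerance = 0.1)
  # green is cumulative in a treated series
  expect_true(all(diff(rep$green_pct) >= -1e-9))
  # yellow is transient, bounded by red and green
  expect_true(all(rep$yellow_pct <= pmin(rep$red_pct, rep$green_pct) + 1e-9))

  ctl <- synth_timelapse(size = 160, conversion_rate = 0, days = 0:6, seed = 8)
  rep_c <- longitudinal_report(ctl$series, method = "fixed",
                               t = ctl$truth$mask_threshold)
  # control: islet labelling by day 1, flat afterwards
  g <- rep_c$green_pct[rep_c$day >= 1]
  expect_lt(max(g) - min(g), 1e-9 + 0.1 * max(g))
  # single-timepoint series yields a single-row report
  one <- list(days = 3, pixel_size = 10, images = tl$series$images[4])
  expect_equal(nrow(longitudinal_report(one, method = "fixed", t = 0.4)), 1)
})
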