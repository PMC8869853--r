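full_mask <- function(h, w) matrix(1, h, w)

test_that("fb_image divides masked pixels and guards zero denominators", {
  fi <- matrix(6, 4, 4)
  bi <- matrix(2, 4, 4)
  fb <- fb_image(fi, bi, full_mask(4, 4))
  expect_true(all(fb[!is.na(fb)] == 3))
  expect_equal(attr(fb, "n_retained"), 16L)
  # a masked pixel with B = 0 is excluded and tallied
  bi2 <- bi
  bi2[1, 1] <- 0
  fb2 <- fb_image(fi, bi2, full_mask(4, 4))
  expect_true(is.na(fb2[1, 1]))
  expect_equal(attr(fb2, "n_excluded"), 1L)
  expect_equal(attr(fb2, "n_retained"), 15L)
  expect_error(fb_image(fi, bi, matrix(0, 4, 4)), "empty")
})

test_that("noiseless phantom F/B equals the true ratio map on fiber pixels", {
  sc <- render_scene(scene_config(shape = c(96, 96), ratio = 5,
                                  background = 6, noise = "none", seed = 3))
  fs <- subtract_background(sc$F)$image
  bs <- subtract_background(sc$B)$image
  mask <- adaptive_mask(fs, bs)
  fb <- fb_image(fs, bs, mask)
  lab <- sc$truth$label > 0 & !is.na(fb)
  expect_gt(sum(lab), 500)
  expect_equal(fb[lab], sc$truth$ratio[lab])
})

test_that("ROI mean is the arithmetic mean of retained pixels", {
  fi <- matrix(c(3, 2, 3, 9), 2)
  bi <- matrix(1, 2, 2)
  mask <- matrix(c(1, 1, 1, 0), 2)
  res <- roi_mean_fb(fb_image(fi, bi, mask))
  expect_equal(res$mean_fb, 8 / 3)
  expect_equal(res$n_pixels, 3L)
  single <- fb_image(matrix(4.2, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1))
  expect_equal(roi_mean_fb(single)$mean_fb, 4.2)
})

test_that("masked pixels with zero forward signal count as ratio zero", {
  fi <- matrix(c(0, 4), 1, 2)
  bi <- matrix(c(2, 2), 1, 2)
  res <- roi_mean_fb(fb_image(fi, bi, matrix(1, 1, 2)))
  expect_equal(res$mean_fb, 1)  # (0 + 2) / 2
  expect_equal(res$n_pixels, 2L)
})

test_that("patient aggregate weights ROIs equally regardless of pixel count", {
  rois <- tibble::tibble(
    patient_id = "P01", region = "bulk", timepoint = "pre", method = "manual",
    mean_fb = c(3, 4, 8), n_pixels = c(10L, 1000L, 10L)
  )
  res <- patient_mean(rois)
  expect_equal(res$value, 5)
  expect_equal(res$n_rois, 3L)
  # pixel-pooled average would differ: confirms the unweighted definition
  pooled <- sum(rois$mean_fb * rois$n_pixels) / sum(rois$n_pixels)
  expect_false(isTRUE(all.equal(pooled, res$value)))
  expect_equal(patient_mean(rois[1, ])$value, 3)
  expect_error(patient_mean(rois[, c("patient_id", "mean_fb")]), "lacks")
})

test_that("calibration factors divide reference by current F/B", {
  expect_equal(calibration_factor(8, 8), 1)
  expect_equal(calibration_factor(8, 10), 0.8)
  expect_error(calibration_factor(0, 5), "> 0")
  tbl <- calibration_table(c(8, 10, 6.4))
  expect_equal(tbl$factor_t, c(1, 0.8, 1.25))
  expect_equal(calibration_at(tbl, 1.5), 0.9)
  expect_equal(calibration_at(tbl, 10), 1.25)
})

test_that("calibration is applied once and only once", {
  expect_equal(as.numeric(apply_calibration(6, 1)), 6)
  expect_equal(as.numeric(apply_calibration(6, 0.987)), 5.922)
  v <- apply_calibration(6, 0.987)
  expect_error(apply_calibration(v, 0.987), "already calibrated")
  row <- tibble::tibble(mean_fb = 6, calibrated = FALSE)
  row2 <- apply_calibration(row, 0.9)
  expect_equal(row2$mean_fb, 5.4)
  expect_true(row2$calibrated)
  expect_error(apply_calibration(row2, 0.9), "already calibrated")
})

test_that("gain drift round-trips exactly through the calibration factor", {
  sc <- render_scene(scene_config(shape = c(96, 96), seed = 7, ratio = 5,
                                  noise = "none"))
  measure <- function(pair) {
    fs <- subtract_background(pair$F)$image
    bs <- subtract_background(pair$B)$image
    roi_mean_fb(fb_image(fs, bs, adaptive_mask(fs, bs)))$mean_fb
  }
  ser <- make_calibration_series(sc, gains = list(c(1, 1), c(1, 1.25)))
  ref <- measure(ser[[1]])
  drift <- measure(ser[[2]])
  fac <- calibration_factor(ref, drift)
  expect_equal(fac, 1.25, tolerance = 1e-9)
  expect_equal(drift * fac, ref, tolerance = 1e-12)
})

test_that("masked mean recovers the imposed ratio under poisson noise", {
  for (r in c(2, 8)) {
    sc <- render_scene(scene_config(
      shape = c(128, 128), ratio = r, amplitude_B = 100, background = 5,
      noise = "poisson", seed = 40 + r
    ))
    fs <- subtract_background(sc$F)$image
    bs <- subtract_background(sc$B)$image
    res <- roi_mean_fb(fb_image(fs, bs, adaptive_mask(fs, bs)))
    expect_gt(res$n_pixels, 500)
    expect_lt(abs(res$mean_fb - r) / r, 0.05)
  }
})
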