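test_that("manual mask is the product of strict per-channel thresholds", {
  fi <- matrix(c(5, 4, 1, 4), 2, byrow = TRUE)
  bi <- matrix(c(3, 1, 4, 5), 2, byrow = TRUE)
  m <- manual_mask(fi, bi, 2, 2)
  expect_equal(unclass(m)[, ], matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_warning(m0 <- manual_mask(fi, bi, 10, 10), "empty")
  expect_true(mask_is_empty(m0))
  expect_true(attr(m0, "empty"))
  set.seed(3)
  for (i in 1:100) {
    a <- random_image()
    b <- random_image()
    got <- suppressWarnings(manual_mask(a, b, 4, 5))
    expect_equal(unclass(got), oracle_manual_mask(a, b, 4, 5),
                 ignore_attr = TRUE)
  }
})

test_that("raising a manual threshold never adds pixels", {
  set.seed(5)
  a <- random_image(16, 16)
  b <- random_image(16, 16)
  m1 <- suppressWarnings(manual_mask(a, b, 3, 3))
  m2 <- suppressWarnings(manual_mask(a, b, 5, 3))
  m3 <- suppressWarnings(manual_mask(a, b, 3, 6))
  expect_true(all(m2 <= m1))
  expect_true(all(m3 <= m1))
  # scale covariance: scaling images and thresholds together is a no-op
  m4 <- suppressWarnings(manual_mask(3 * a, 3 * b, 9, 9))
  expect_equal(unclass(m4), unclass(m1), ignore_attr = TRUE)
})

test_that("global binarization cuts at a fraction of the image mean", {
  expect_true(all(binarize_global(matrix(4, 5, 5)) == 1))
  img <- matrix(c(10, 0, 0, 0), 2, byrow = TRUE)
  expect_equal(unclass(binarize_global(img)), matrix(c(1, 0, 0, 0), 2),
               ignore_attr = TRUE)
  set.seed(8)
  for (i in 1:50) {
    a <- random_image()
    expect_equal(unclass(binarize_global(a)), oracle_global_mask(a, 0.6),
                 ignore_attr = TRUE)
    # threshold is proportional to the mean: scaling changes nothing
    expect_equal(unclass(binarize_global(a * 7)), unclass(binarize_global(a)))
  }
  expect_warning(z <- binarize_global(matrix(0, 4, 4)), "all-zero")
  expect_true(mask_is_empty(z))
})

test_that("window selection requires adequate fill at every center", {
  ones <- matrix(1, 64, 64)
  params <- adaptive_params(window_schedule = c(63, 31, 15, 7, 3))
  w <- select_window(new_mask_for_test(ones), params)
  expect_equal(as.integer(w), 3)
  # a single set pixel cannot satisfy the criterion at any size: fallback
  single <- matrix(0, 64, 64)
  single[1, 1] <- 1
  expect_warning(
    wf <- select_window(new_mask_for_test(single), params),
    "falling back"
  )
  expect_equal(as.integer(wf), 63)
  expect_true(attr(wf, "fallback"))
  expect_error(select_window(new_mask_for_test(matrix(0, 8, 8))), "empty")
})

test_that("selected window agrees with explicit center enumeration", {
  set.seed(13)
  schedule <- c(15, 7, 3)
  params <- adaptive_params(window_schedule = schedule)
  for (i in 1:10) {
    seed_mask <- (random_image(16, 16) > 7) * 1
    if (sum(seed_mask) == 0) next
    got <- suppressWarnings(select_window(new_mask_for_test(seed_mask), params))
    qualifying <- Filter(
      function(w) oracle_window_qualifies(seed_mask, w, 0.05),
      sort(schedule)
    )
    want <- if (length(qualifying)) min(unlist(qualifying)) else max(schedule)
    expect_equal(as.integer(got), as.integer(want))
  }
})

test_that("windowed local threshold matches the per-pixel loop oracle", {
  expect_true(all(local_adaptive_mask(matrix(3, 8, 8), 3) == 1))
  set.seed(21)
  for (i in 1:50) {
    img <- random_image(16, 16)
    expect_equal(unclass(local_adaptive_mask(img, 5)),
                 oracle_local_mask(img, 5, 0.6), ignore_attr = TRUE)
  }
  # a window so large that every cropped window is the whole image reduces
  # to the global rule
  img <- random_image(12, 12)
  big <- 2 * 12 - 1
  expect_equal(unclass(local_adaptive_mask(img, big)),
               unclass(binarize_global(img)), ignore_attr = TRUE)
})

test_that("adaptive mask is scale invariant and intersects its channels", {
  sc <- render_scene(scene_config(shape = c(96, 96), seed = 14,
                                  noise = "poisson"))
  m1 <- adaptive_mask(sc$F, sc$B)
  m2 <- adaptive_mask(sc$F * 3, sc$B * 3)
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
  expect_equal(attr(m1, "windows"), attr(m2, "windows"))
  # the product never exceeds either channel mask
  pf <- adaptive_params()
  seedF <- binarize_global(sc$F, pf$alpha)
  chF <- local_adaptive_mask(sc$F, select_window(seedF, pf), pf$alpha)
  expect_true(all(unclass(m1) <= unclass(chF)))
  # constant positive channels give an all-ones mask
  const <- matrix(5, 32, 32)
  expect_true(all(adaptive_mask(const, const) == 1))
})

test_that("adaptive mask tracks the true fiber support on noiseless phantoms", {
  sc <- render_scene(scene_config(
    shape = c(96, 96), n_fibers = 30, fiber_length = 70, width_sigma = 2.5,
    seed = 2, noise = "none"
  ))
  fs <- subtract_background(sc$F)$image
  bs <- subtract_background(sc$B)$image
  m <- adaptive_mask(fs, bs)
  core <- Reduce(`|`, lapply(sc$truth$fibers, function(f) {
    ci <- shgfb:::fiber_contribution(f, dim(sc$B))
    ci >= f$amplitude_B * exp(-0.5)
  }))
  expect_gte(sum(m[core] == 1) / sum(core), 0.9)
  dilated <- shgfb:::dilate_mask((sc$truth$label > 0) * 1, 2)
  expect_equal(sum(m[dilated == 0] == 1), 0)
})
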