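# Phantom-based invariant battery: oracle equivalences, exact noiseless
# recovery, scale invariance, calibration round-trip, orientation recovery.

# binary dilation by r pixels (square structuring element)
dilate_mask <- function(mask, r) {
  (local_mean(matrix(as.numeric(mask), nrow(mask)), 2 * r + 1) > 0) * 1
}

#' Run the built-in invariant self-check
#'
#' Runs a compact battery of correctness checks against synthetic phantoms
#' with known ground truth: per-pixel loop oracles for projection and both
#' mask types, exact noiseless F/B recovery, scale invariance of the
#' adaptive pipeline, adaptive-mask coverage of true fiber pixels,
#' calibration-factor round-trip, structure-tensor orientation recovery,
#' and the branch-cut dispersion identity.
#'
#' @param alpha Adaptive threshold fraction used by the coverage check
#'   (default 0.6; lowering the sensitivity of the check to a corrupted
#'   parameter is itself checked by tests).
#' @param seed Seed for the random phantoms.
#' @return Tibble with `check`, `value`, `threshold`, `pass`; attribute
#'   `ok` is `TRUE` iff every check passed.
#' @export
run_selfcheck <- function(alpha = 0.6, seed = 1L) {
  checks <- list()
  add <- function(check, value, threshold, pass) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, value = value, threshold = threshold, pass = pass
    )
  }
  with_seed(derive_seed(seed, 7L), {
    # 1. MIP equals the per-pixel loop oracle
    dev <- 0
    for (i in 1:20) {
      st <- array(runif(8 * 8 * 3, 0, 100), c(8, 8, 3))
      oracle <- matrix(0, 8, 8)
      for (r in 1:8) for (c in 1:8) oracle[r, c] <- max(st[r, c, ])
      dev <- max(dev, max(abs(max_intensity_project(st) - oracle)))
    }
    add("mip_matches_pixel_loop", dev, 0, dev == 0)

    # 2. manual mask equals the loop oracle
    dev <- 0
    for (i in 1:20) {
      fi <- matrix(runif(64, 0, 10), 8)
      bi <- matrix(runif(64, 0, 10), 8)
      m <- suppressWarnings(manual_mask(fi, bi, 4, 5))
      oracle <- matrix(0, 8, 8)
      for (r in 1:8) for (c in 1:8) {
        oracle[r, c] <- as.numeric(fi[r, c] > 4 && bi[r, c] > 5)
      }
      dev <- max(dev, max(abs(unclass(m) - oracle)))
    }
    add("manual_mask_matches_pixel_loop", dev, 0, dev == 0)

    # 3. windowed local threshold equals the loop oracle
    dev <- 0
    for (i in 1:10) {
      img <- matrix(runif(256, 0, 10), 16)
      m <- local_adaptive_mask(img, 5, 0.6)
      oracle <- matrix(0, 16, 16)
      for (r in 1:16) for (c in 1:16) {
        rr <- max(1, r - 2):min(16, r + 2)
        cc <- max(1, c - 2):min(16, c + 2)
        oracle[r, c] <- as.numeric(img[r, c] > 0.6 * mean(img[rr, cc]))
      }
      dev <- max(dev, max(abs(unclass(m) - oracle)))
    }
    add("local_threshold_matches_pixel_loop", dev, 0, dev == 0)

    # 4. noiseless phantom: pixelwise F/B equals the true ratio map exactly
    sc <- render_scene(scene_config(shape = c(96, 96), seed = seed,
                                    noise = "none", ratio = 5))
    lab <- sc$truth$label > 0
    ratio_err <- max(abs((sc$F[lab] - sc$config$background) /
                           (sc$B[lab] - sc$config$background) -
                           sc$truth$ratio[lab]))
    add("noiseless_ratio_exact", ratio_err, 1e-9, ratio_err < 1e-9)

    # 5. adaptive pipeline scale invariance
    sub <- function(img) subtract_background(img, p = 10)$image
    fb_of <- function(fi, bi, a) {
      fs <- sub(fi); bs <- sub(bi)
      msk <- adaptive_mask(fs, bs, adaptive_params(alpha = a))
      roi_mean_fb(fb_image(fs, bs, msk))$mean_fb
    }
    sc2 <- render_scene(scene_config(shape = c(96, 96), seed = seed + 1L,
                                     noise = "poisson"))
    v1 <- fb_of(sc2$F, sc2$B, 0.6)
    v3 <- fb_of(sc2$F * 3, sc2$B * 3, 0.6)
    rel <- abs(v3 - v1) / v1
    add("adaptive_scale_invariance", rel, 1e-9, rel < 1e-9)

    # 6. adaptive mask covers the true fiber support (noiseless, dense scene
    # so the window search picks a genuinely local window)
    scd <- render_scene(scene_config(
      shape = c(96, 96), n_fibers = 30, fiber_length = 70,
      width_sigma = 2.5, seed = seed + 1L, noise = "none"
    ))
    fs <- sub(scd$F); bs <- sub(scd$B)
    msk <- suppressWarnings(adaptive_mask(fs, bs, adaptive_params(alpha = alpha)))
    core <- purrr::map(scd$truth$fibers, function(f) {
      ci <- fiber_contribution(f, dim(scd$B))
      ci >= f$amplitude_B * exp(-0.5)  # within 1 sigma of the axis
    }) |> purrr::reduce(`|`)
    coverage <- sum(msk[core] == 1) / sum(core)
    add("adaptive_mask_core_coverage", coverage, 0.9, coverage >= 0.9)
    outside <- sum(msk[dilate_mask((scd$truth$label > 0) * 1, 2) == 0] == 1)
    add("adaptive_mask_confined_to_fibers", outside, 0, outside == 0)

    # 7. calibration round-trip under gain drift (noiseless)
    series <- make_calibration_series(sc, gains = list(c(1, 1), c(1, 1.25)))
    fbs <- purrr::map_dbl(series, function(p) {
      fs <- sub(p$F); bs <- sub(p$B)
      roi_mean_fb(fb_image(fs, bs, adaptive_mask(fs, bs)))$mean_fb
    })
    fac <- calibration_factor(fbs[1], fbs[2])
    add("calibration_recovers_gain", abs(fac - 1.25), 1e-6,
        abs(fac - 1.25) < 1e-6)

    # 8. structure tensor recovers a 45-degree fiber
    cfg45 <- scene_config(
      shape = c(64, 64),
      fibers = list(fiber_spec(c(32, 32), 45, length = 40)),
      background = 0, noise = "none", seed = seed
    )
    s45 <- render_scene(cfg45)
    ang <- local_orientation(s45$B, (s45$truth$label > 0) * 1, c(32, 32))$angle
    err <- min(abs(ang - 45), 180 - abs(ang - 45))
    add("orientation_45deg_recovery", err, 2, err <= 2)

    # 9. branch-cut dispersion identity
    v <- as.numeric(orientation_sd(c(175, 175, 5, 5)))
    add("branch_cut_sd", abs(v - 5.7735027), 1e-6, abs(v - 5.7735027) < 1e-6)
  })
  out <- dplyr::bind_rows(checks)
  attr(out, "ok") <- all(out$pass)
  out
}
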