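#' Specify a single synthetic collagen fiber
#'
#' A fiber is rendered as an anti-aliased line segment with a Gaussian
#' cross-section. Its forward/backward (F/B) ratio is imposed directly:
#' the backward channel receives the Gaussian intensity profile and the
#' forward channel receives `ratio` times that profile, so the fiber's true
#' per-pixel F/B is known exactly.
#'
#' @param center Numeric length-2, fiber midpoint as (x, y) in pixels
#'   (x = column, y = row).
#' @param angle Orientation in degrees in `[0, 180)`, measured
#'   counter-clockwise from the horizontal "3 o'clock" direction.
#' @param length Fiber length in pixels.
#' @param width_sigma Gaussian cross-section standard deviation in pixels.
#' @param amplitude_B Peak backward-channel intensity (arbitrary units).
#' @param ratio True F/B ratio of this fiber (> 0).
#' @return A `fiber_spec` list.
#' @export
#' @examples
#' fiber_spec(center = c(64, 64), angle = 45, length = 80)
fiber_spec <- function(center, angle, length = 60, width_sigma = 1.5,
                       amplitude_B = 100, ratio = 5) {
  stopifnot(is.numeric(center), length(center) == 2L)
  if (ratio <= 0) abort("`ratio` must be > 0.")
  if (width_sigma <= 0) abort("`width_sigma` must be > 0.")
  if (length <= 0) abort("`length` must be > 0.")
  structure(
    list(
      center = as.numeric(center),
      angle = as.numeric(angle) %% 180,
      length = as.numeric(length),
      width_sigma = as.numeric(width_sigma),
      amplitude_B = as.numeric(amplitude_B),
      ratio = as.numeric(ratio)
    ),
    class = "fiber_spec"
  )
}

#' Configure a synthetic SHG scene
#'
#' Describes one paired forward/backward field: either an explicit list of
#' [fiber_spec()] objects or parameters from which fibers are sampled
#' (uniform centers, normal angles). A constant background offset is added to
#' both channels (two independent detectors, each with a dark offset), and
#' noise is applied per channel after image formation.
#'
#' @param shape Image shape `c(H, W)` in pixels; both must be >= 16.
#' @param fibers Optional list of [fiber_spec()]. If `NULL`, `n_fibers` are
#'   sampled.
#' @param n_fibers,angle_mean,angle_sd Sampling parameters used when `fibers`
#'   is `NULL`: number of fibers, mean orientation (degrees) and orientation
#'   spread (degrees; angles are drawn normal and wrapped into `[0, 180)`).
#' @param fiber_length,width_sigma,amplitude_B,ratio Geometry and intensity
#'   defaults for sampled fibers.
#' @param background Constant offset added to both channels (>= 0).
#' @param noise One of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_sd Standard deviation for Gaussian noise.
#' @param seed Integer seed; the same config is guaranteed to render
#'   byte-identical scenes.
#' @return A `scene_config` list.
#' @export
scene_config <- function(shape = c(128, 128), fibers = NULL,
                         n_fibers = 12, angle_mean = 90, angle_sd = 45,
                         fiber_length = 60, width_sigma = 1.5,
                         amplitude_B = 100, ratio = 5,
                         background = 5, noise = c("poisson", "gaussian", "none"),
                         noise_sd = 5, seed = 1L) {
  noise <- match.arg(noise)
  if (length(shape) != 2L || any(shape < 16)) {
    abort("`shape` must be c(H, W) with both dimensions >= 16.")
  }
  if (background < 0) abort("`background` must be >= 0.")
  structure(
    list(
      shape = as.integer(shape), fibers = fibers, n_fibers = n_fibers,
      angle_mean = angle_mean, angle_sd = angle_sd,
      fiber_length = fiber_length, width_sigma = width_sigma,
      amplitude_B = amplitude_B, ratio = ratio,
      background = background, noise = noise, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "scene_config"
  )
}

# Sample the fiber list for a config that does not fix fibers explicitly.
sample_fibers <- function(config) {
  h <- config$shape[[1]]
  w <- config$shape[[2]]
  margin <- 4
  n <- config$n_fibers
  centers_x <- runif(n, margin, w - margin)
  centers_y <- runif(n, margin, h - margin)
  angles <- (rnorm(n, config$angle_mean, config$angle_sd)) %% 180
  lapply(seq_len(n), function(i) {
    fiber_spec(
      center = c(centers_x[i], centers_y[i]), angle = angles[i],
      length = config$fiber_length, width_sigma = config$width_sigma,
      amplitude_B = config$amplitude_B, ratio = config$ratio
    )
  })
}

# Gaussian-profile contribution of one fiber over the full image, using the
# distance from each pixel center to the fiber's axis segment. Contributions
# beyond 4 sigma are cut to exactly zero so far-field pixels carry only the
# background offset.
fiber_contribution <- function(fiber, shape) {
  h <- shape[[1]]
  w <- shape[[2]]
  theta <- fiber$angle * pi / 180
  # direction in (x = col, y = row) coordinates; rows grow downward, so the
  # visual counter-clockwise angle maps to a negative row component.
  ux <- cos(theta)
  uy <- -sin(theta)
  half <- fiber$length / 2
  cut <- 4 * fiber$width_sigma
  # bounding box of the segment plus the cut radius
  ex <- abs(ux) * half + cut
  ey <- abs(uy) * half + cut
  c0 <- max(1L, floor(fiber$center[1] - ex))
  c1 <- min(w, ceiling(fiber$center[1] + ex))
  r0 <- max(1L, floor(fiber$center[2] - ey))
  r1 <- min(h, ceiling(fiber$center[2] + ey))
  if (c0 > c1 || r0 > r1) {
    abort(sprintf(
      "fiber at (%.1f, %.1f) lies entirely outside a %dx%d image",
      fiber$center[1], fiber$center[2], h, w
    ))
  }
  cols <- c0:c1
  rows <- r0:r1
  px <- matrix(cols, length(rows), length(cols), byrow = TRUE) - fiber$center[1]
  py <- matrix(rows, length(rows), length(cols)) - fiber$center[2]
  t_along <- px * ux + py * uy
  t_clamp <- pmin(pmax(t_along, -half), half)
  dx <- px - t_clamp * ux
  dy <- py - t_clamp * uy
  d2 <- dx^2 + dy^2
  g <- fiber$amplitude_B * exp(-d2 / (2 * fiber$width_sigma^2))
  g[d2 > cut^2] <- 0
  out <- matrix(0, h, w)
  out[rows, cols] <- g
  out
}

apply_noise <- function(image, noise, noise_sd) {
  switch(noise,
    none = image,
    poisson = matrix(rpois(length(image), lambda = image), nrow(image)),
    gaussian = pmax(image + rnorm(length(image), 0, noise_sd), 0)
  )
}

#' Render a synthetic SHG image pair with per-pixel ground truth
#'
#' Renders every fiber as a Gaussian-profile segment, sums overlapping
#' contributions per channel (backward: the profile; forward: `ratio` times
#' the profile), adds the background offset to both channels, and applies the
#' configured noise independently per channel. Ground-truth maps record,
#' per pixel, the dominant fiber label (the fiber contributing the most
#' intensity, within 2 sigma of its axis), the exact noiseless F/B of the
#' summed fiber signal, and the dominant fiber's orientation.
#'
#' @param config A [scene_config()].
#' @return An object of class `shg_scene`: a list with numeric matrices `F`
#'   and `B`, a `truth` list (`label`, `ratio`, `angle` maps plus the
#'   realized `fibers`), and the `config`.
#' @export
#' @examples
#' sc <- render_scene(scene_config(seed = 7, noise = "none"))
#' range(sc$F / pmax(sc$B, 1e-12))
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(derive_seed(config$seed, 0L), {
    fibers <- config$fibers %||% sample_fibers(config)
    h <- config$shape[[1]]
    w <- config$shape[[2]]
    sumB <- matrix(0, h, w)
    sumF <- matrix(0, h, w)
    best <- matrix(0, h, w)   # strongest single-fiber contribution
    label <- matrix(0L, h, w)
    angle <- matrix(NA_real_, h, w)
    for (i in seq_along(fibers)) {
      fib <- fibers[[i]]
      ci <- fiber_contribution(fib, config$shape)
      sumB <- sumB + ci
      sumF <- sumF + fib$ratio * ci
      core <- ci >= fib$amplitude_B * exp(-2)  # within 2 sigma of the axis
      take <- core & ci > best
      label[take] <- i
      angle[take] <- fib$angle
      best[take] <- ci[take]
    }
    ratio <- matrix(NA_real_, h, w)
    lab <- label > 0L
    ratio[lab] <- sumF[lab] / sumB[lab]
    img_B <- sumB + config$background
    img_F <- sumF + config$background
    img_B <- apply_noise(img_B, config$noise, config$noise_sd)
    img_F <- apply_noise(img_F, config$noise, config$noise_sd)
    structure(
      list(
        F = img_F, B = img_B,
        truth = list(label = label, ratio = ratio, angle = angle,
                     fibers = fibers),
        config = config
      ),
      class = "shg_scene"
    )
  })
}

#' Render a synthetic z-stack pair
#'
#' Each slice is the noiseless scene scaled by a per-slice axial weight
#' (emulating the fiber sheet moving through focus), with noise re-drawn per
#' slice. The maximum weight must be 1 so the maximum-intensity projection of
#' a noiseless stack reproduces the in-focus scene.
#'
#' @param config A [scene_config()].
#' @param n_slices Number of slices (>= 1).
#' @param step_um Axial step between slices in micrometres (> 0).
#' @param axial_profile Per-slice amplitude weights in `[0, 1]` with
#'   `max == 1`; defaults to all 1.
#' @return An object of class `shg_zstack_pair`: arrays `F` and `B` of shape
#'   `H x W x n_slices`, the `truth` maps of the in-focus scene, `step_um`,
#'   `span_um` (see [stack_span()]), and `axial_profile`.
#' @export
render_zstack <- function(config, n_slices = 3, step_um = 3,
                          axial_profile = rep(1, n_slices)) {
  stopifnot(inherits(config, "scene_config"))
  if (n_slices < 1) abort("`n_slices` must be >= 1.")
  if (step_um <= 0) abort("`step_um` must be > 0.")
  if (length(axial_profile) != n_slices) {
    abort("`axial_profile` must have one weight per slice.")
  }
  if (any(axial_profile < 0 | axial_profile > 1) ||
      max(axial_profile) != 1) {
    abort("`axial_profile` weights must lie in [0, 1] with max == 1.")
  }
  base_cfg <- config
  base_cfg$noise <- "none"
  base <- render_scene(base_cfg)
  h <- config$shape[[1]]
  w <- config$shape[[2]]
  arr_F <- array(0, c(h, w, n_slices))
  arr_B <- array(0, c(h, w, n_slices))
  for (k in seq_len(n_slices)) {
    sF <- base$F * axial_profile[k]
    sB <- base$B * axial_profile[k]
    with_seed(derive_seed(config$seed, k), {
      arr_F[, , k] <- apply_noise(sF, config$noise, config$noise_sd)
      arr_B[, , k] <- apply_noise(sB, config$noise, config$noise_sd)
    })
  }
  structure(
    list(
      F = arr_F, B = arr_B, truth = base$truth,
      step_um = step_um, span_um = stack_span(n_slices, step_um),
      axial_profile = axial_profile, config = config
    ),
    class = "shg_zstack_pair"
  )
}

#' Simulate an hourly calibration image series
#'
#' Emulates re-imaging the same field across an imaging session with detector
#' gain drift and stage translation: element `t` is the reference pair with
#' channels multiplied by per-hour gains `(gF, gB)` and translated by
#' `(dx, dy)` pixels. The first element should use gains `(1, 1)` and shift
#' `(0, 0)` so it is the unmodified reference.
#'
#' @param pair An `shg_scene` (or list with matrices `F` and `B`).
#' @param gains List of length-2 numeric vectors `(gF, gB)`, all > 0.
#' @param shifts List of length-2 numeric vectors `(dx, dy)` in pixels;
#'   sub-pixel shifts are applied by bilinear interpolation. Defaults to no
#'   shift.
#' @return A list of `shg_scene`-like pairs, each carrying attributes
#'   `gain` and `shift`.
#' @export
make_calibration_series <- function(pair, gains,
                                    shifts = rep(list(c(0, 0)), length(gains))) {
  stopifnot(is.list(gains), is.list(shifts), length(gains) == length(shifts))
  if (any(vapply(gains, function(g) any(g <= 0), logical(1)))) {
    abort("all gains must be > 0.")
  }
  h <- nrow(pair$B)
  w <- ncol(pair$B)
  if (any(vapply(shifts, function(s) any(abs(s) >= c(w, h)), logical(1)))) {
    abort("shifts must be smaller than the image.")
  }
  purrr::map2(gains, shifts, function(g, s) {
    out <- list(
      F = translate_image(pair$F * g[[1]], s[[1]], s[[2]]),
      B = translate_image(pair$B * g[[2]], s[[1]], s[[2]])
    )
    structure(out, class = "shg_scene", gain = g, shift = s)
  })
}

#' Place one fiber near each 3x3 grid anchor
#'
#' Convenience constructor for orientation-recovery phantoms: one fiber per
#' grid cell, centered at the grid intersection points of [grid_points()],
#' with angles drawn normal around `angle_mean` (wrapped into `[0, 180)`).
#' Guarantees that every grid anchor has a nearby fiber to measure.
#'
#' @inheritParams scene_config
#' @param jitter_px Uniform jitter applied to each fiber center, in pixels.
#' @return A [scene_config()] with explicit fibers.
#' @export
grid_fiber_scene <- function(shape = c(128, 128), angle_mean = 90,
                             angle_sd = 10, fiber_length = 24,
                             width_sigma = 1.5, amplitude_B = 100, ratio = 5,
                             background = 5, noise = "none", noise_sd = 5,
                             jitter_px = 2, seed = 1L) {
  pts <- grid_points(shape)
  fibers <- with_seed(derive_seed(seed, 99L), {
    angles <- (rnorm(nrow(pts), angle_mean, angle_sd)) %% 180
    jx <- runif(nrow(pts), -jitter_px, jitter_px)
    jy <- runif(nrow(pts), -jitter_px, jitter_px)
    lapply(seq_len(nrow(pts)), function(i) {
      fiber_spec(
        center = c(pts$x[i] + jx[i], pts$y[i] + jy[i]), angle = angles[i],
        length = fiber_length, width_sigma = width_sigma,
        amplitude_B = amplitude_B, ratio = ratio
      )
    })
  })
  scene_config(
    shape = shape, fibers = fibers, background = background,
    noise = noise, noise_sd = noise_sd, seed = seed
  )
}
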