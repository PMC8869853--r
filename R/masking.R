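# Collagen/background segmentation: manual dual thresholds and the
# automated adaptive (windowed) thresholding algorithm.

new_mask <- function(pixels, provenance, channel = NA_character_, ...) {
  structure(
    pixels,
    provenance = provenance, channel = channel, ...,
    class = c("shg_mask", "matrix", "array")
  )
}

#' Is a mask empty?
#' @param mask A binary mask.
#' @return `TRUE` if no pixel is set.
#' @export
mask_is_empty <- function(mask) sum(mask) == 0

#' Manual dual-threshold collagen mask
#'
#' The manual method: one global threshold per channel, chosen by an
#' observer. Pixels strictly above the threshold are set to 1 in each
#' channel's mask, and the two masks are multiplied so only pixels inside
#' collagen fibers in both channels survive.
#'
#' @param image_F,image_B Background-subtracted channel images, same shape.
#' @param tF,tB Intensity thresholds (>= 0), one per channel.
#' @return A binary `shg_mask`. If no pixel survives, the mask carries
#'   attribute `empty = TRUE` (downstream averaging refuses empty masks).
#' @export
manual_mask <- function(image_F, image_B, tF, tB) {
  assert_image(image_F)
  assert_image(image_B)
  assert_same_shape(image_F, image_B)
  if (tF < 0 || tB < 0) abort("thresholds must be >= 0.")
  m <- (image_F > tF) * (image_B > tB)
  empty <- sum(m) == 0
  if (empty) warn("manual mask is empty (empty ROI).")
  new_mask(m, "manual", thresholds = c(tF = tF, tB = tB), empty = empty)
}

#' Global relative-mean binarization
#'
#' First stage of the adaptive method: a pixel is foreground iff its
#' intensity strictly exceeds `alpha` times the mean intensity of the whole
#' image (default `alpha = 0.6`). The threshold scales with the image, so the
#' mask is invariant to multiplying the image by any positive constant.
#'
#' @param image Intensity matrix.
#' @param alpha Fraction of the image mean used as the cut (0 < alpha < 1).
#' @return A binary `shg_mask` (provenance `"adaptive"`).
#' @export
binarize_global <- function(image, alpha = 0.6) {
  assert_image(image)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (all(image == 0)) {
    warn("all-zero image: global binarization yields an empty mask.")
    return(new_mask(matrix(0, nrow(image), ncol(image)), "adaptive", empty = TRUE))
  }
  m <- (image > alpha * mean(image)) * 1
  new_mask(m, "adaptive", empty = sum(m) == 0)
}

# Mean of each (cropped) w x w window centered on every pixel, by integral
# image. Windows are cropped at the borders, never padded.
local_mean <- function(image, window) {
  if (!is_odd(window) || window < 3) abort("`window` must be odd and >= 3.")
  h <- nrow(image)
  w <- ncol(image)
  r <- (window - 1) %/% 2
  # integral image with a zero border
  S <- matrix(0, h + 1, w + 1)
  S[-1, -1] <- apply(apply(image, 2, cumsum), 1, cumsum) |> t()
  top <- pmax(seq_len(h) - r, 1L)
  bot <- pmin(seq_len(h) + r, h)
  lef <- pmax(seq_len(w) - r, 1L)
  rig <- pmin(seq_len(w) + r, w)
  sums <- S[bot + 1, rig + 1, drop = FALSE] - S[top, rig + 1, drop = FALSE] -
    S[bot + 1, lef, drop = FALSE] + S[top, lef, drop = FALSE]
  counts <- outer(bot - top + 1L, rig - lef + 1L)
  sums / counts
}

#' Default window schedule for the adaptive method
#'
#' Progressively smaller odd window sizes: from the largest odd size that
#' fits the image, halving down to 7 pixels.
#'
#' @param shape Image shape `c(H, W)`.
#' @return Strictly decreasing integer vector of odd sizes, all >= 7.
#' @export
default_window_schedule <- function(shape) {
  w <- min(shape)
  if (w %% 2 == 0) w <- w - 1L
  out <- integer(0)
  while (w >= 7) {
    out <- c(out, as.integer(w))
    w <- floor(w / 2)
    if (w %% 2 == 0) w <- w - 1L
  }
  out
}

#' Parameters of the adaptive thresholding algorithm
#'
#' @param alpha Fraction of the (global or local) mean used as the intensity
#'   cut; default 0.6.
#' @param fill_frac Minimum fraction of foreground seed pixels a window must
#'   contain; default 0.05 (the ">5% nonzero pixels" criterion).
#' @param window_schedule Strictly decreasing vector of odd window sizes
#'   (>= 3), or `NULL` to derive one from the image shape.
#' @return An `adaptive_params` list.
#' @export
adaptive_params <- function(alpha = 0.6, fill_frac = 0.05,
                            window_schedule = NULL) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (fill_frac <= 0 || fill_frac >= 1) abort("`fill_frac` must be in (0, 1).")
  if (!is.null(window_schedule)) {
    ws <- as.integer(window_schedule)
    if (any(diff(ws) >= 0) && length(ws) > 1) {
      abort("`window_schedule` must be strictly decreasing.")
    }
    if (any(ws < 3) || any(!is_odd(ws))) {
      abort("`window_schedule` sizes must be odd and >= 3.")
    }
  }
  structure(
    list(alpha = alpha, fill_frac = fill_frac,
         window_schedule = window_schedule),
    class = "adaptive_params"
  )
}

#' Select the adaptive window size from a seed mask
#'
#' Scans the window schedule for the smallest size such that the window
#' centered on EVERY pixel (cropped at borders) contains strictly more than
#' `fill_frac` foreground seed pixels — guaranteeing stable local means at
#' all positions. If no scheduled size qualifies, the largest scheduled size
#' is returned with a warning.
#'
#' @param seed_mask Binary mask from [binarize_global()].
#' @param params An [adaptive_params()].
#' @return Selected odd window size (integer), with attribute `fallback`
#'   set to `TRUE` when no size met the criterion.
#' @export
select_window <- function(seed_mask, params = adaptive_params()) {
  assert_mask(seed_mask)
  if (sum(seed_mask) == 0) abort("seed mask is empty; cannot select a window.")
  schedule <- params$window_schedule %||% default_window_schedule(dim(seed_mask))
  m <- matrix(as.numeric(seed_mask), nrow(seed_mask))
  for (w in sort(schedule)) {
    fills <- local_mean(m, w)
    if (min(fills) > params$fill_frac) {
      return(structure(as.integer(w), fallback = FALSE))
    }
  }
  warn(sprintf(
    "no scheduled window reached >%.0f%% fill at every position; falling back to %d px.",
    100 * params$fill_frac, max(schedule)
  ))
  structure(as.integer(max(schedule)), fallback = TRUE)
}

#' Windowed local-mean binarization
#'
#' Second stage of the adaptive method: a pixel is foreground iff its
#' intensity strictly exceeds `alpha` times the mean of the `window`-sized
#' neighborhood centered on it (cropped at image borders).
#'
#' @param image Intensity matrix.
#' @param window Odd window size >= 3.
#' @param alpha Fraction of the local mean used as the cut.
#' @return A binary `shg_mask` (provenance `"adaptive"`).
#' @export
local_adaptive_mask <- function(image, window, alpha = 0.6) {
  assert_image(image)
  m <- (image > alpha * local_mean(image, window)) * 1
  new_mask(m, "adaptive", window = as.integer(window), empty = sum(m) == 0)
}

#' Automated adaptive-threshold collagen mask
#'
#' Per channel: global relative-mean binarization seeds the window search,
#' the smallest window with adequate fill everywhere is selected, and the
#' windowed local-mean binarization is applied to the channel. The two
#' channel masks are then multiplied, mirroring the manual method, so the
#' manual and adaptive pipelines differ only in how thresholds are chosen.
#'
#' @param image_F,image_B Background-subtracted channel images, same shape.
#' @param params An [adaptive_params()].
#' @return A binary `shg_mask` with attribute `windows = c(F = , B = )`
#'   recording the selected per-channel window sizes.
#' @export
adaptive_mask <- function(image_F, image_B, params = adaptive_params()) {
  assert_image(image_F)
  assert_image(image_B)
  assert_same_shape(image_F, image_B)
  one <- function(img) {
    seed <- binarize_global(img, params$alpha)
    w <- select_window(seed, params)
    list(mask = local_adaptive_mask(img, w, params$alpha), window = w)
  }
  chF <- one(image_F)
  chB <- one(image_B)
  m <- unclass(chF$mask) * unclass(chB$mask)
  attributes(m) <- attributes(m)["dim"]
  empty <- sum(m) == 0
  if (empty) warn("adaptive mask is empty (empty ROI).")
  new_mask(
    m, "adaptive",
    windows = c(F = as.integer(chF$window), B = as.integer(chB$window)),
    fallback = c(F = attr(chF$window, "fallback"), B = attr(chB$window, "fallback")),
    empty = empty
  )
}
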