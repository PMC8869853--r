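#' Subtract a background offset from an image
#'
#' The offset is either a fixed value or a low intensity percentile of the
#' image (default: the 10th percentile, which on sparse fiber images falls in
#' the pure-background population). The result is clipped at zero: photon
#' counts cannot be negative, and clipping keeps downstream masks
#' well-defined.
#'
#' @param image Numeric intensity matrix.
#' @param estimator `"low_percentile"` or `"fixed"`.
#' @param p Percentile in `(0, 50]` for the percentile estimator.
#' @param offset Fixed offset for the fixed estimator.
#' @return A list with `image` (background-subtracted, clipped at 0) and
#'   `offset` (the value that was subtracted).
#' @export
#' @examples
#' subtract_background(matrix(7, 4, 4))$offset # 7
subtract_background <- function(image, estimator = c("low_percentile", "fixed"),
                                p = 10, offset = 0) {
  assert_image(image)
  estimator <- match.arg(estimator)
  if (estimator == "low_percentile") {
    if (p <= 0 || p > 50) abort("`p` must be in (0, 50].")
    offset <- unname(quantile(image, p / 100))
  }
  if (offset > max(image)) {
    warn("background offset exceeds the image maximum; returning an all-zero image.")
    return(list(image = matrix(0, nrow(image), ncol(image)), offset = offset))
  }
  list(image = pmax(image - offset, 0), offset = offset)
}

# Cross-correlation surface over cyclic shifts via FFT, after mean removal.
fft_crosscorr <- function(reference, moving) {
  r0 <- reference - mean(reference)
  m0 <- moving - mean(moving)
  Re(fft(fft(r0) * Conj(fft(m0)) / length(r0), inverse = TRUE))
}

#' Register one image to a reference by integer-pixel translation
#'
#' Finds the translation `(dx, dy)` of `moving` (dx along columns, dy along
#' rows) that maximizes the mean-removed cross-correlation with `reference`,
#' restricted to `|dx|, |dy| <= max_shift`. The correlation surface is
#' computed by FFT; the registered image is `moving` translated by the
#' recovered shift with zero-filled edges.
#'
#' @param reference,moving Numeric matrices of identical shape.
#' @param max_shift Maximum absolute shift searched, in pixels.
#' @return A list with `image` (the registered moving image) and `shift`
#'   (`c(dx, dy)`); applying `shift` to `moving` aligns it to `reference`.
#' @export
register_translation <- function(reference, moving, max_shift = 20) {
  assert_image(reference)
  assert_image(moving)
  assert_same_shape(reference, moving)
  if (var(as.vector(reference)) == 0 || var(as.vector(moving)) == 0) {
    abort("cannot register a flat (zero-variance) image.")
  }
  h <- nrow(reference)
  w <- ncol(reference)
  cc <- fft_crosscorr(reference, moving)
  # cc[i, j] corresponds to correlating moving displaced by
  # (dy, dx) = (i - 1, j - 1) cyclically; wrap to signed shifts.
  dys <- c(0:(h - 1))
  dys[dys > h / 2] <- dys[dys > h / 2] - h
  dxs <- c(0:(w - 1))
  dxs[dxs > w / 2] <- dxs[dxs > w / 2] - w
  ok_r <- abs(dys) <= max_shift
  ok_c <- abs(dxs) <= max_shift
  sub <- cc[ok_r, ok_c, drop = FALSE]
  idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  dy <- dys[ok_r][idx[[1]]]
  dx <- dxs[ok_c][idx[[2]]]
  list(image = translate_image(moving, dx, dy), shift = c(dx = dx, dy = dy))
}
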