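# Internal helpers shared across modules.

# Derive a stream-specific RNG seed from a master seed. Kept below 2^31 so it
# is always representable as an R integer.
derive_seed <- function(seed, stream = 0L) {
  s <- (as.double(seed) * 48271 + 1 + as.double(stream) * 7919) %% 2147483647
  as.integer(s)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assert_image <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    abort(sprintf("`%s` must have positive dimensions.", arg))
  }
  if (any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  if (any(x < 0)) {
    abort(sprintf("`%s` contains negative intensities.", arg))
  }
  invisible(x)
}

assert_same_shape <- function(a, b, what = c("images")) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf(
      "%s must have identical dimensions (%s vs %s).",
      what[[1]], paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")
    ))
  }
  invisible(TRUE)
}

assert_mask <- function(mask, arg = deparse(substitute(mask))) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    abort(sprintf("`%s` must be a binary (0/1) matrix.", arg))
  }
  invisible(mask)
}

is_odd <- function(x) x %% 2 == 1

# Translate an image by integer or sub-pixel (dx, dy) where dx moves content
# towards larger column indices and dy towards larger row indices. Pixels
# shifted in from outside are zero-filled; sub-pixel shifts use bilinear
# interpolation.
translate_image <- function(image, dx, dy) {
  h <- nrow(image)
  w <- ncol(image)
  out <- matrix(0, h, w)
  if (dx == round(dx) && dy == round(dy)) {
    dx <- as.integer(round(dx))
    dy <- as.integer(round(dy))
    src_rows <- seq_len(h) - dy
    src_cols <- seq_len(w) - dx
    ok_r <- src_rows >= 1L & src_rows <= h
    ok_c <- src_cols >= 1L & src_cols <= w
    out[which(ok_r), which(ok_c)] <- image[src_rows[ok_r], src_cols[ok_c], drop = FALSE]
    return(out)
  }
  # bilinear sampling at (row - dy, col - dx)
  rr <- matrix(seq_len(h), h, w) - dy
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - dx
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  val <- function(r, c) {
    inside <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- numeric(length(r))
    v[inside] <- image[cbind(r[inside], c[inside])]
    v
  }
  v <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
  matrix(v, h, w)
}
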