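# Naive per-pixel reference implementations, kept deliberately independent
# of the package's vectorized code paths.

oracle_mip <- function(stack) {
  d <- dim(stack)
  out <- matrix(0, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      out[r, c] <- max(stack[r, c, ])
    }
  }
  out
}

oracle_manual_mask <- function(fi, bi, tF, tB) {
  out <- matrix(0, nrow(fi), ncol(fi))
  for (r in seq_len(nrow(fi))) {
    for (c in seq_len(ncol(fi))) {
      out[r, c] <- as.numeric(fi[r, c] > tF && bi[r, c] > tB)
    }
  }
  out
}

oracle_global_mask <- function(img, alpha) {
  cut <- alpha * mean(img)
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      out[r, c] <- as.numeric(img[r, c] > cut)
    }
  }
  out
}

oracle_local_mask <- function(img, window, alpha) {
  h <- nrow(img)
  w <- ncol(img)
  rad <- (window - 1) / 2
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      rr <- max(1, r - rad):min(h, r + rad)
      cc <- max(1, c - rad):min(w, c + rad)
      out[r, c] <- as.numeric(img[r, c] > alpha * mean(img[rr, cc]))
    }
  }
  out
}

# window fill criterion checked by explicit enumeration of every center
oracle_window_qualifies <- function(seed_mask, window, fill_frac) {
  h <- nrow(seed_mask)
  w <- ncol(seed_mask)
  rad <- (window - 1) / 2
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      rr <- max(1, r - rad):min(h, r + rad)
      cc <- max(1, c - rad):min(w, c + rad)
      if (mean(seed_mask[rr, cc]) <= fill_frac) return(FALSE)
    }
  }
  TRUE
}

# exhaustive integer-shift correlation search on zero-filled overlaps
oracle_register <- function(reference, moving, max_shift) {
  best <- -Inf
  best_shift <- c(0, 0)
  r0 <- reference - mean(reference)
  m0 <- moving - mean(moving)
  h <- nrow(reference)
  w <- ncol(reference)
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      shifted <- matrix(0, h, w)
      sr <- seq_len(h) - dy
      sc <- seq_len(w) - dx
      okr <- sr >= 1 & sr <= h
      okc <- sc >= 1 & sc <= w
      shifted[which(okr), which(okc)] <- m0[sr[okr], sc[okc]]
      score <- sum(r0 * shifted)
      if (score > best) {
        best <- score
        best_shift <- c(dx, dy)
      }
    }
  }
  best_shift
}

# minimal-spread axial SD by enumerating every 0/180 relabeling
oracle_axial_sd <- function(angles) {
  n <- length(angles)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    shift <- as.numeric(bitwAnd(bitwShiftR(mask, seq_len(n) - 1), 1L))
    best <- min(best, sd(angles %% 180 + 180 * shift))
  }
  best
}

# select_window() accepts any binary matrix; alias for readability
new_mask_for_test <- function(m) m

random_image <- function(h = 8, w = 8, max = 10) {
  matrix(runif(h * w, 0, max), h, w)
}

single_fiber_scene <- function(angle, shape = c(64, 64), ratio = 5,
                               background = 0, noise = "none", length = 40,
                               seed = 1) {
  render_scene(scene_config(
    shape = shape,
    fibers = list(fiber_spec(c(shape[2] / 2, shape[1] / 2), angle,
                             length = length, ratio = ratio)),
    background = background, noise = noise, seed = seed
  ))
}
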