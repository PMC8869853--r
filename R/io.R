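#' Write an image or z-stack to a multi-page TIFF
#'
#' Intensities are stored with the standard 16-bit microscopy convention:
#' sample value = round(intensity), so integer photon counts in
#' `[0, 65535]` round-trip exactly. Images whose maximum exceeds 65535 are
#' rejected rather than silently rescaled.
#'
#' @param x A numeric matrix, a list of matrices (one per slice), or an
#'   `H x W x K` array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  slices <- if (is.matrix(x)) {
    list(x)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    lapply(seq_len(dim(x)[3]), function(k) x[, , k])
  } else if (is.list(x)) {
    x
  } else {
    abort("`x` must be a matrix, a 3-d array, or a list of matrices.")
  }
  mx <- max(vapply(slices, max, numeric(1)))
  if (mx > 65535) abort("intensities above 65535 cannot be stored at 16 bits.")
  tiff::writeTIFF(
    lapply(slices, function(s) round(s) / 65535),
    path, bits.per.sample = 16L, compression = "none"
  )
  invisible(path)
}

read_tiff_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("TIFF file not found: %s", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) abort(sprintf("cannot read TIFF %s: %s", path, conditionMessage(e)))
  )
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first sample of multi-channel pages
    storage.mode(p) <- "double"
    p
  })
}

#' Read a paired forward/backward TIFF z-stack
#'
#' Both files must be multi-page TIFFs with equal page counts and page
#' shapes. Integer pixel types are promoted to double without rescaling.
#'
#' @param path_F,path_B Paths to the forward- and backward-channel TIFFs.
#' @return A list with elements `F` and `B`, each an `shg_zstack`: an
#'   `H x W x K` array with attributes `channel` and (if supplied) `step_um`.
#' @param step_um Optional axial step to record in the stack metadata.
#' @export
read_stack_pair <- function(path_F, path_B, step_um = NULL) {
  pf <- read_tiff_stack(path_F)
  pb <- read_tiff_stack(path_B)
  if (length(pf) != length(pb)) {
    abort(sprintf(
      "page counts differ: %s has %d, %s has %d",
      path_F, length(pf), path_B, length(pb)
    ))
  }
  shapes <- unique(lapply(c(pf, pb), dim))
  if (length(shapes) != 1L) {
    abort(sprintf("page shapes differ between %s and %s", path_F, path_B))
  }
  as_stack <- function(pages, channel) {
    arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    structure(arr, channel = channel, step_um = step_um, class = "shg_zstack")
  }
  list(F = as_stack(pf, "F"), B = as_stack(pb, "B"))
}

#' Maximum-intensity projection of a z-stack
#'
#' Collapses a stack to a single image by taking the per-pixel maximum over
#' slices — a pixel-by-pixel autofocus for tissue that is not perfectly
#' parallel to the image plane.
#'
#' @param stack An `shg_zstack` (`H x W x K` array), a plain 3-d array, a
#'   list of matrices, or a single matrix (returned unchanged).
#' @return A numeric `H x W` matrix.
#' @export
max_intensity_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (is.list(stack) && !is.array(stack)) {
    stack <- array(unlist(stack), c(dim(stack[[1]]), length(stack)))
  }
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 1L) {
    abort("`stack` must contain at least one slice.")
  }
  out <- stack[, , 1]
  for (k in seq_len(dim(stack)[3])[-1]) out <- pmax(out, stack[, , k])
  matrix(out, dim(stack)[1], dim(stack)[2])
}

#' Axial span of a z-stack
#'
#' The distance between the first and last slice: `(n_slices - 1) * step_um`.
#' Three slices at 3 um steps span 6 um.
#'
#' @param n_slices Number of slices (>= 1).
#' @param step_um Step between slices in micrometres (> 0).
#' @return Span in micrometres.
#' @export
#' @examples
#' stack_span(3, 3) # 6
stack_span <- function(n_slices, step_um) {
  if (n_slices < 1) abort("`n_slices` must be >= 1.")
  if (step_um <= 0) abort("`step_um` must be > 0.")
  (n_slices - 1) * step_um
}
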