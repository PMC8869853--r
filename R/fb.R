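# Masked F/B ratio images, ROI means, patient aggregates, and session
# calibration.

#' Masked forward/backward ratio image
#'
#' Divides the background-subtracted channels pixelwise wherever the final
#' collagen mask is 1 and the backward channel is positive. Masked pixels
#' with `B == 0` cannot yield a finite ratio; they are excluded and counted.
#' Masked pixels with `F == 0` are retained with ratio 0: they are inside
#' collagen by mask consensus, and dropping them would bias F/B upward.
#'
#' @param image_F,image_B Background-subtracted channel images.
#' @param mask Binary collagen mask (product of the two channel masks).
#' @return An `shg_fb_image`: a matrix of ratios with `NA` outside the
#'   retained support, carrying attributes `method`, `n_retained`, and
#'   `n_excluded` (masked pixels dropped because `B == 0`).
#' @export
fb_image <- function(image_F, image_B, mask) {
  assert_image(image_F)
  assert_image(image_B)
  assert_same_shape(image_F, image_B)
  assert_same_shape(image_F, mask, "mask and images")
  if (mask_is_empty(mask)) abort("mask is empty (empty ROI); no F/B can be computed.")
  retained <- mask == 1 & image_B > 0
  excluded <- sum(mask == 1 & image_B <= 0)
  ratio <- matrix(NA_real_, nrow(image_F), ncol(image_F))
  ratio[retained] <- image_F[retained] / image_B[retained]
  structure(
    ratio,
    method = attr(mask, "provenance") %||% NA_character_,
    n_retained = sum(retained), n_excluded = excluded,
    class = c("shg_fb_image", "matrix", "array")
  )
}

#' Mean F/B of one region of interest
#'
#' Arithmetic mean of the retained per-pixel ratios of one imaged field.
#'
#' @param fb An [fb_image()] result.
#' @return A one-row tibble: `mean_fb`, `n_pixels`, `n_excluded`, `method`,
#'   `calibrated` (always `FALSE` here; see [apply_calibration()]).
#' @export
roi_mean_fb <- function(fb) {
  vals <- fb[!is.na(fb)]
  if (length(vals) == 0) abort("no retained pixels (empty ROI).")
  tibble::tibble(
    mean_fb = mean(vals),
    n_pixels = length(vals),
    n_excluded = attr(fb, "n_excluded") %||% 0L,
    method = attr(fb, "method") %||% NA_character_,
    calibrated = FALSE
  )
}

#' Patient-level F/B aggregate
#'
#' Unweighted mean of the ROI means within each patient x region x
#' timepoint x method cell: each imaged field contributes equally regardless
#' of how many collagen pixels it retained.
#'
#' @param rois Tibble of ROI results carrying `mean_fb` plus the id columns
#'   `patient_id`, `region`, `timepoint`, and `method`.
#' @return A tibble with one row per cell: `value` (mean of ROI means) and
#'   `n_rois`.
#' @export
patient_mean <- function(rois) {
  needed <- c("patient_id", "region", "timepoint", "method", "mean_fb")
  missing <- setdiff(needed, names(rois))
  if (length(missing) > 0) {
    abort(paste0("`rois` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  rois |>
    dplyr::group_by(patient_id, region, timepoint, method) |>
    dplyr::summarise(
      value = mean(mean_fb), n_rois = dplyr::n(), .groups = "drop"
    )
}

#' Session calibration factor
#'
#' Ratio of the reference (hour 1) F/B of the calibration target to its F/B
#' at a later hour. Multiplying a measurement taken at that hour by the
#' factor removes slow detector/alignment drift.
#'
#' @param fb_reference,fb_current Mean F/B of the calibration field at the
#'   reference hour and at the current hour (numbers or [roi_mean_fb()]
#'   rows).
#' @return The calibration factor (> 0).
#' @export
#' @examples
#' calibration_factor(8, 10) # 0.8
calibration_factor <- function(fb_reference, fb_current) {
  get_val <- function(x) if (is.data.frame(x)) x$mean_fb[[1]] else x[[1]]
  ref <- get_val(fb_reference)
  cur <- get_val(fb_current)
  if (!is.finite(ref) || !is.finite(cur) || ref <= 0 || cur <= 0) {
    abort("calibration inputs must be finite and > 0.")
  }
  ref / cur
}

#' Calibration factors for an hourly series
#'
#' @param fb_series Numeric vector of the calibration field's mean F/B per
#'   hour; the first element is the reference.
#' @return Tibble with `hour` (1-based) and `factor_t`.
#' @export
calibration_table <- function(fb_series) {
  if (length(fb_series) < 1 || any(fb_series <= 0)) {
    abort("`fb_series` must be positive.")
  }
  tibble::tibble(
    hour = seq_along(fb_series),
    factor_t = fb_series[[1]] / fb_series
  )
}

#' Interpolate a calibration factor at an arbitrary session time
#'
#' Linear interpolation between hourly factors; times outside the measured
#' range take the nearest measured factor.
#'
#' @param cal Tibble from [calibration_table()].
#' @param time Session time in hours (same clock as `hour`).
#' @return Interpolated factor.
#' @export
calibration_at <- function(cal, time) {
  approx(cal$hour, cal$factor_t, xout = time, rule = 2)$y
}

#' Normalize F/B values by a session calibration factor
#'
#' Multiplies the F/B value(s) by the factor and flags them as calibrated;
#' applying a factor to already-calibrated values is an error.
#'
#' @param x A number, an [roi_mean_fb()] row, or a [patient_mean()] tibble
#'   (columns `mean_fb` or `value`).
#' @param factor Calibration factor (> 0).
#' @return Same shape as `x` with values multiplied by `factor` and a
#'   `calibrated` flag set.
#' @export
apply_calibration <- function(x, factor) {
  if (!is.finite(factor) || factor <= 0) abort("`factor` must be > 0.")
  if (is.data.frame(x)) {
    if (!is.null(x$calibrated) && any(x$calibrated)) {
      abort("values are already calibrated; refusing to apply a factor twice.")
    }
    col <- if ("mean_fb" %in% names(x)) "mean_fb" else "value"
    x[[col]] <- x[[col]] * factor
    x$calibrated <- TRUE
    return(x)
  }
  if (isTRUE(attr(x, "calibrated"))) {
    abort("value is already calibrated; refusing to apply a factor twice.")
  }
  structure(x * factor, calibrated = TRUE)
}
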