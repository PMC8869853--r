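# ggplot2 visualisations for scenes, F/B maps, orientation overlays, and
# group comparisons.

image_to_df <- function(image, what = "intensity") {
  df <- expand.grid(y = seq_len(nrow(image)), x = seq_len(ncol(image)))
  df[[what]] <- as.vector(image)
  tibble::as_tibble(df)
}

#' Plot the two channels of a synthetic scene
#'
#' @param object An `shg_scene`.
#' @param ... Unused.
#' @return A ggplot faceted by channel.
#' @exportS3Method ggplot2::autoplot
autoplot.shg_scene <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(image_to_df(object$F), channel = "forward (F)"),
    dplyr::mutate(image_to_df(object$B), channel = "backward (B)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x, y, fill = intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a masked F/B ratio map
#'
#' @param fb An [fb_image()] result.
#' @return A ggplot raster of the per-pixel ratio (excluded pixels blank).
#' @export
plot_fb_map <- function(fb) {
  df <- image_to_df(unclass(fb), "value")
  ggplot2::ggplot(df, ggplot2::aes(x, y, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey15", name = "F/B") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Overlay measured fiber orientations on an image
#'
#' Draws the grid anchor points and a line glyph per valid measurement,
#' oriented at the measured angle, for quality control of the automated
#' orientation measurement.
#'
#' @param image Intensity image the orientations were measured on.
#' @param sample Tibble from [orientation_sample()].
#' @param glyph_length Length of the angle glyphs in pixels.
#' @return A ggplot.
#' @export
plot_orientation_overlay <- function(image, sample, glyph_length = 15) {
  df <- image_to_df(image)
  segs <- sample |>
    dplyr::filter(valid) |>
    dplyr::mutate(
      dx = glyph_length / 2 * cos(angle * pi / 180),
      dy = -glyph_length / 2 * sin(angle * pi / 180)
    )
  ggplot2::ggplot(df, ggplot2::aes(x, y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = intensity)) +
    ggplot2::geom_point(data = sample, ggplot2::aes(x, y),
                        colour = "red", shape = 3) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = anchor_x - dx, xend = anchor_x + dx,
                   y = anchor_y - dy, yend = anchor_y + dy),
      colour = "orange", linewidth = 1
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot patient-level group values as points with mean and SEM
#'
#' Mirrors the conventional presentation of cohort results: one point per
#' patient, group mean with an SEM error bar, faceted by region and masking
#' method.
#'
#' @param patient_results Tibble from [run_study()]'s `patient_results`.
#' @return A ggplot.
#' @export
plot_group_means <- function(patient_results) {
  summ <- patient_results |>
    dplyr::group_by(region, timepoint, method) |>
    dplyr::summarise(
      mean = mean(value), sem = sd(value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(patient_results,
                  ggplot2::aes(timepoint, value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(timepoint, mean, ymin = mean - sem, ymax = mean + sem),
      colour = "red"
    ) +
    ggplot2::facet_grid(method ~ region) +
    ggplot2::labs(y = "patient mean F/B", x = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
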