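# End-to-end study driver: from a directory of per-patient TIFF pairs (or a
# simulation spec) to projected images, masks, F/B and organization tables,
# and the comparison report.

#' Simulation spec for an image-level study
#'
#' Describes how to synthesize a full imaging study from a patient cohort:
#' for each patient x region x timepoint cell, `n_rois` fiber phantoms are
#' rendered whose true F/B equals the patient's simulated cell value and —
#' in the tumor bulk — whose fiber-angle spread equals the patient's
#' simulated orientation-dispersion value.
#'
#' @param cohort A [cohort_config()].
#' @param image_shape Phantom shape `c(H, W)`.
#' @param n_rois Imaged fields per region per timepoint (3 in the reference
#'   design).
#' @param amplitude_B,background,noise,noise_sd,fiber_length,width_sigma
#'   Passed to the phantom generator.
#' @return A `simulate_spec` list.
#' @export
simulate_spec <- function(cohort = cohort_config(n_patients = 6),
                          image_shape = c(96, 96), n_rois = 3,
                          amplitude_B = 100, background = 5,
                          noise = "poisson", noise_sd = 5,
                          fiber_length = 24, width_sigma = 1.5) {
  structure(
    list(
      cohort = cohort, image_shape = as.integer(image_shape),
      n_rois = as.integer(n_rois), amplitude_B = amplitude_B,
      background = background, noise = noise, noise_sd = noise_sd,
      fiber_length = fiber_length, width_sigma = width_sigma
    ),
    class = "simulate_spec"
  )
}

#' Configure a study run
#'
#' Exactly one of `input_root` (a directory laid out as
#' `<root>/<patient>/<timepoint>/<region>/roi<k>_{F,B}.tif` with a
#' `patients.csv` holding `patient_id`, `subtype`, `rcb_class`) or
#' `simulate` (a [simulate_spec()]) must be given.
#'
#' @param input_root Root directory of an imaged study, or `NULL`.
#' @param simulate A [simulate_spec()], or `NULL`.
#' @param method Masking method(s) to run: `"both"`, `"manual"`, or
#'   `"adaptive"`.
#' @param adaptive An [adaptive_params()].
#' @param manual_percentile Percentile (of each background-subtracted
#'   channel) used as that channel's manual threshold; stands in for the
#'   blinded observer's choice.
#' @param background_p Background percentile for [subtract_background()].
#' @param calibration Optional tibble with `timepoint` and `factor_t`
#'   columns; patient-level F/B values are multiplied by the matching
#'   session factor.
#' @param search_radius,window Orientation-measurement parameters.
#' @param alpha_norm Normality gate for the statistical layer.
#' @param seed Master seed for all randomness in the run.
#' @return A `study_config` list.
#' @export
study_config <- function(input_root = NULL, simulate = NULL,
                         method = c("both", "manual", "adaptive"),
                         adaptive = adaptive_params(),
                         manual_percentile = 90, background_p = 10,
                         calibration = NULL,
                         search_radius = 64, window = 21,
                         alpha_norm = 0.05, seed = 1L) {
  method <- match.arg(method)
  if (is.null(input_root) == is.null(simulate)) {
    abort("give exactly one of `input_root` or `simulate`.")
  }
  if (!is.null(input_root) && !dir.exists(input_root)) {
    abort(sprintf("input root does not exist: %s", input_root))
  }
  structure(
    list(
      input_root = input_root, simulate = simulate, method = method,
      adaptive = adaptive, manual_percentile = manual_percentile,
      background_p = background_p, calibration = calibration,
      search_radius = search_radius, window = window,
      alpha_norm = alpha_norm, seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

study_methods <- function(config) {
  switch(config$method, both = c("manual", "adaptive"), config$method)
}

# Background-subtract both channels, build the requested masks, and return
# per-method ROI rows plus the masks (reused for orientation measurement).
process_pair <- function(img_F, img_B, config) {
  bF <- subtract_background(img_F, p = config$background_p)
  bB <- subtract_background(img_B, p = config$background_p)
  out <- list(rows = list(), masks = list(), F_sub = bF$image)
  for (m in study_methods(config)) {
    mask <- tryCatch(
      {
        if (m == "manual") {
          tF <- unname(quantile(bF$image, config$manual_percentile / 100))
          tB <- unname(quantile(bB$image, config$manual_percentile / 100))
          suppressWarnings(manual_mask(bF$image, bB$image, tF, tB))
        } else {
          suppressWarnings(adaptive_mask(bF$image, bB$image, config$adaptive))
        }
      },
      error = function(e) NULL
    )
    row <- if (is.null(mask) || mask_is_empty(mask)) {
      tibble::tibble(method = m, mean_fb = NA_real_, n_pixels = 0L,
                     n_excluded = 0L, calibrated = FALSE, flag = "empty_roi")
    } else {
      fb <- fb_image(bF$image, bB$image, mask)
      dplyr::mutate(roi_mean_fb(fb), flag = "")
    }
    out$rows[[m]] <- row
    out$masks[[m]] <- mask
  }
  out$roi_rows <- dplyr::bind_rows(out$rows)
  out
}

simulate_study_images <- function(config) {
  spec <- config$simulate
  cohort_tbl <- make_cohort(spec$cohort)
  fb_tbl <- dplyr::filter(cohort_tbl, measure == "fb")
  org_tbl <- dplyr::filter(cohort_tbl, measure == "orientation_sd")
  patients <- dplyr::distinct(cohort_tbl, patient_id, subtype, rcb_class)
  cells <- dplyr::distinct(fb_tbl, patient_id, region, timepoint, value)
  scenes <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    ratio <- max(cell$value, 0.2)
    ang_sd <- 45
    if (cell$region == "bulk" && nrow(org_tbl) > 0) {
      o <- dplyr::filter(org_tbl, patient_id == cell$patient_id,
                         timepoint == cell$timepoint)
      if (nrow(o) == 1) ang_sd <- min(max(o$value, 2), 60)
    }
    for (k in seq_len(spec$n_rois)) {
      sseed <- derive_seed(config$seed, i * 101L + k)
      ang_mean <- with_seed(derive_seed(sseed, 3L), runif(1, 0, 180))
      sc_cfg <- grid_fiber_scene(
        shape = spec$image_shape, angle_mean = ang_mean, angle_sd = ang_sd,
        fiber_length = spec$fiber_length, width_sigma = spec$width_sigma,
        amplitude_B = spec$amplitude_B, ratio = ratio,
        background = spec$background, noise = spec$noise,
        noise_sd = spec$noise_sd, seed = sseed
      )
      key <- paste(cell$patient_id, cell$timepoint, cell$region, k, sep = "/")
      scenes[[key]] <- c(
        list(scene = render_scene(sc_cfg)),
        as.list(cell[c("patient_id", "region", "timepoint")]), list(roi = k)
      )
    }
  }
  list(patients = patients, scenes = scenes, cohort = cohort_tbl)
}

read_study_images <- function(config) {
  root <- config$input_root
  meta_path <- file.path(root, "patients.csv")
  if (!file.exists(meta_path)) abort(sprintf("missing %s", meta_path))
  patients <- readr::read_csv(meta_path, show_col_types = FALSE)
  scenes <- list()
  for (pid in patients$patient_id) {
    for (tp in c("pre", "post")) {
      for (reg in c("bulk", "interface")) {
        d <- file.path(root, pid, tp, reg)
        if (!dir.exists(d)) next
        k <- 1
        repeat {
          fF <- file.path(d, sprintf("roi%d_F.tif", k))
          fB <- file.path(d, sprintf("roi%d_B.tif", k))
          if (!file.exists(fF) || !file.exists(fB)) break
          stacks <- read_stack_pair(fF, fB)
          key <- paste(pid, tp, reg, k, sep = "/")
          scenes[[key]] <- list(
            scene = list(F = max_intensity_project(stacks$F),
                         B = max_intensity_project(stacks$B)),
            patient_id = pid, region = reg, timepoint = tp, roi = k
          )
          k <- k + 1
        }
      }
    }
  }
  if (length(scenes) == 0) abort("no image pairs found under the input root.")
  list(patients = patients, scenes = scenes, cohort = NULL)
}

study_comparisons <- function(patient_results, organization, patients,
                              alpha_norm) {
  rows <- list()
  add <- function(measure, method, comparison, region, cmp) {
    rows[[length(rows) + 1]] <<- dplyr::mutate(
      tidy(cmp),
      measure = measure, method = method, comparison = comparison,
      region = region, .before = 1
    )
  }
  paired_vals <- function(df, reg) {
    df |>
      dplyr::filter(region == reg) |>
      dplyr::select(patient_id, timepoint, value) |>
      tidyr::pivot_wider(names_from = timepoint, values_from = value) |>
      dplyr::filter(is.finite(pre), is.finite(post))
  }
  for (m in unique(patient_results$method)) {
    dfm <- dplyr::filter(patient_results, method == m)
    for (reg in unique(dfm$region)) {
      w <- paired_vals(dfm, reg)
      if (nrow(w) >= 3) {
        add("fb", m, "pre_vs_post", reg,
            compare_paired(w$pre, w$post, alpha_norm))
      }
    }
    # regional contrast at each timepoint
    for (tp in c("pre", "post")) {
      w <- dfm |>
        dplyr::filter(timepoint == tp) |>
        dplyr::select(patient_id, region, value) |>
        tidyr::pivot_wider(names_from = region, values_from = value)
      if (all(c("bulk", "interface") %in% names(w))) {
        w <- dplyr::filter(w, is.finite(bulk), is.finite(interface))
        if (nrow(w) >= 3) {
          add("fb", m, paste0("interface_vs_bulk_", tp), "both",
              compare_paired(w$interface, w$bulk, alpha_norm))
        }
      }
    }
  }
  if (!is.null(organization) && nrow(organization) >= 6) {
    w <- organization |>
      dplyr::select(patient_id, timepoint, sd_degrees) |>
      tidyr::pivot_wider(names_from = timepoint, values_from = sd_degrees) |>
      dplyr::filter(is.finite(pre), is.finite(post))
    if (nrow(w) >= 3) {
      add("orientation_sd", "structure-tensor", "pre_vs_post", "bulk",
          compare_paired(w$pre, w$post, alpha_norm))
    }
  }
  dplyr::bind_rows(rows)
}

#' Run a complete F/B and fiber-organization study
#'
#' Executes the full pipeline — project, background-subtract, mask (manual
#' and/or adaptive), compute masked F/B per field, aggregate per patient,
#' apply session calibration, measure fiber organization on two tumor-bulk
#' fields per patient, and run the pre/post, regional, and subgroup
#' comparisons. Deterministic given the config (including its seed).
#'
#' @param config A [study_config()].
#' @return An `shg_study` list: `roi_results`, `patient_results`,
#'   `organization`, `comparisons`, `subgroups`, `patients`, `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  inputs <- if (!is.null(config$simulate)) {
    simulate_study_images(config)
  } else {
    read_study_images(config)
  }
  processed <- purrr::imap(inputs$scenes, function(s, key) {
    pr <- process_pair(s$scene$F, s$scene$B, config)
    pr$meta <- s[c("patient_id", "region", "timepoint", "roi")]
    pr
  })
  roi_results <- purrr::map_dfr(processed, function(pr) {
    dplyr::bind_cols(tibble::as_tibble(pr$meta), pr$roi_rows)
  })
  patient_results <- roi_results |>
    dplyr::filter(is.finite(mean_fb)) |>
    patient_mean()
  if (!is.null(config$calibration)) {
    patient_results <- patient_results |>
      dplyr::left_join(config$calibration, by = "timepoint") |>
      dplyr::mutate(value = value * dplyr::coalesce(factor_t, 1),
                    calibrated = !is.na(factor_t)) |>
      dplyr::select(-factor_t)
  } else {
    patient_results$calibrated <- FALSE
  }
  # fiber organization: two bulk fields per patient per timepoint
  org_method <- if (config$method == "manual") "manual" else "adaptive"
  org_keys <- purrr::keep(processed, function(pr) {
    pr$meta$region == "bulk" && pr$meta$roi <= 2 &&
      !is.null(pr$masks[[org_method]]) &&
      !mask_is_empty(pr$masks[[org_method]])
  })
  organization <- NULL
  if (length(org_keys) > 0) {
    groups <- split(
      org_keys,
      purrr::map_chr(org_keys, ~ paste(.x$meta$patient_id, .x$meta$timepoint,
                                       sep = "|"))
    )
    organization <- purrr::imap_dfr(groups, function(g, key) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      res <- tryCatch(
        patient_organization(
          images = purrr::map(g, ~ .x$F_sub),
          masks = purrr::map(g, ~ .x$masks[[org_method]]),
          search_radius = config$search_radius, window = config$window
        ),
        error = function(e) NULL
      )
      if (is.null(res)) {
        return(tibble::tibble(patient_id = parts[1], timepoint = parts[2],
                              sd_degrees = NA_real_, n_angles = NA_integer_,
                              flag = "too_few_valid_points"))
      }
      tibble::tibble(patient_id = parts[1], timepoint = parts[2],
                     sd_degrees = res$sd_degrees, n_angles = res$n_angles,
                     flag = "")
    })
  }
  patients <- inputs$patients
  patient_results <- dplyr::left_join(patient_results, patients,
                                      by = "patient_id")
  comparisons <- study_comparisons(patient_results, organization, patients,
                                   config$alpha_norm)
  subgroups <- purrr::map_dfr(unique(patient_results$method), function(m) {
    recs <- patient_results |>
      dplyr::filter(method == m) |>
      dplyr::select(patient_id, rcb_class, region, timepoint, value)
    dplyr::bind_rows(
      dplyr::mutate(subgroup_analysis(recs, "bulk", config$alpha_norm),
                    region = "bulk", method = m, .before = 1),
      dplyr::mutate(subgroup_analysis(recs, "interface", config$alpha_norm),
                    region = "interface", method = m, .before = 1)
    )
  })
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    methods = study_methods(config),
    n_patients = nrow(patients),
    n_fields = length(inputs$scenes),
    package = "shgfb",
    version = as.character(utils::packageVersion("shgfb"))
  )
  structure(
    list(
      roi_results = roi_results, patient_results = patient_results,
      organization = organization, comparisons = comparisons,
      subgroups = subgroups, patients = patients, manifest = manifest,
      cohort_truth = inputs$cohort
    ),
    class = "shg_study"
  )
}

#' Write study tables to a directory
#'
#' Writes `roi_results.csv`, `patient_results.csv`, `organization.csv`,
#' `comparisons.csv`, `subgroups.csv` and `manifest.json`. Output is
#' deterministic: re-running an identical config produces byte-identical
#' files.
#'
#' @param study An `shg_study` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$roi_results, file.path(dir, "roi_results.csv"))
  readr::write_csv(study$patient_results, file.path(dir, "patient_results.csv"))
  if (!is.null(study$organization)) {
    readr::write_csv(study$organization, file.path(dir, "organization.csv"))
  }
  readr::write_csv(study$comparisons, file.path(dir, "comparisons.csv"))
  readr::write_csv(study$subgroups, file.path(dir, "subgroups.csv"))
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a simulated study to the on-disk layout
#'
#' Materializes a [simulate_spec()] as the directory convention consumed by
#' [study_config()] (`<root>/<patient>/<timepoint>/<region>/roi<k>_{F,B}.tif`
#' plus `patients.csv`), for exercising the file-based pipeline.
#'
#' @param config A [study_config()] in simulate mode.
#' @param root Output directory.
#' @return `root`, invisibly.
#' @export
write_simulated_study <- function(config, root) {
  stopifnot(!is.null(config$simulate))
  inputs <- simulate_study_images(config)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(inputs$patients, file.path(root, "patients.csv"))
  for (s in inputs$scenes) {
    d <- file.path(root, s$patient_id, s$timepoint, s$region)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_stack(s$scene$F, file.path(d, sprintf("roi%d_F.tif", s$roi)))
    write_stack(s$scene$B, file.path(d, sprintf("roi%d_B.tif", s$roi)))
  }
  invisible(root)
}

#' @export
print.shg_study <- function(x, ...) {
  cat(sprintf(
    "<shg_study> %d patients, %d fields, methods: %s\n",
    nrow(x$patients), x$manifest$n_fields,
    paste(x$manifest$methods, collapse = ", ")
  ))
  cat("comparisons:\n")
  print(x$comparisons)
  invisible(x)
}
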