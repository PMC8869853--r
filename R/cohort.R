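# Patient-level cohort simulation: paired pre/post values per region drawn
# from bivariate normals with stated group means and spreads, plus residual
# cancer burden (RCB) class labels.

#' Reference cohort parameter tables
#'
#' Group means and standard deviations of patient-level F/B (per masking
#' method and region) and of fiber-orientation dispersion, for the two
#' breast cancer subtypes studied (HER2+ and triple-negative). Group spreads
#' are reconstructed from reported standard errors of the mean as
#' `SD = SEM * sqrt(22)` (22 patients per cohort).
#'
#' @param subtype `"HER2+"` or `"TNBC"`.
#' @param method Masking method the F/B parameters refer to: `"manual"` or
#'   `"adaptive"`.
#' @return Tibble of cells: `measure`, `region`, `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd`.
#' @export
cohort_cells <- function(subtype = c("HER2+", "TNBC"),
                         method = c("manual", "adaptive")) {
  subtype <- match.arg(subtype)
  method <- match.arg(method)
  n <- 22
  sem <- function(x) x * sqrt(n)
  fb <- if (subtype == "HER2+") {
    if (method == "manual") {
      tibble::tribble(
        ~region, ~pre_mean, ~pre_sem, ~post_mean, ~post_sem,
        "bulk", 5.25, 0.36, 6.24, 0.37,
        "interface", 7.26, 0.49, 7.62, 0.43
      )
    } else {
      tibble::tribble(
        ~region, ~pre_mean, ~pre_sem, ~post_mean, ~post_sem,
        "bulk", 6.51, 0.55, 8.02, 0.56,
        "interface", 8.95, 0.63, 9.44, 0.48
      )
    }
  } else {
    if (method == "manual") {
      tibble::tribble(
        ~region, ~pre_mean, ~pre_sem, ~post_mean, ~post_sem,
        "bulk", 5.37, 0.34, 6.81, 0.56,
        "interface", 8.18, 0.41, 8.11, 0.35
      )
    } else {
      tibble::tribble(
        ~region, ~pre_mean, ~pre_sem, ~post_mean, ~post_sem,
        "bulk", 6.73, 0.45, 8.37, 0.62,
        "interface", 9.92, 0.56, 9.77, 0.41
      )
    }
  }
  org <- if (subtype == "HER2+") {
    tibble::tibble(region = "bulk", pre_mean = 40.2, pre_sem = 7.32,
                   post_mean = 42.3, post_sem = 8.82)
  } else {
    tibble::tibble(region = "bulk", pre_mean = 45.2, pre_sem = 8.78,
                   post_mean = 36.9, post_sem = 7.73)
  }
  dplyr::bind_rows(
    dplyr::mutate(fb, measure = "fb"),
    dplyr::mutate(org, measure = "orientation_sd")
  ) |>
    dplyr::mutate(pre_sd = sem(pre_sem), post_sd = sem(post_sem)) |>
    dplyr::select(measure, region, pre_mean, pre_sd, post_mean, post_sd)
}

#' Configure a simulated patient cohort
#'
#' @param n_patients Number of patients (>= 2).
#' @param subtype Cohort subtype label.
#' @param cells Parameter tibble as returned by [cohort_cells()] (columns
#'   `measure`, `region`, `pre_mean`, `pre_sd`, `post_mean`, `post_sd`).
#' @param rho Pre/post correlation within a patient, in `[0, 1]`.
#' @param rcb_probs Named probabilities for classes `0`, `I`, `II`, `III`.
#'   The default reproduces the reference split of 22 patients into 10
#'   (pooled 0/I) and 12 (pooled II/III).
#' @param allocation `"sampled"` draws classes from `rcb_probs`;
#'   `"proportional"` allocates them deterministically in proportion.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 22, subtype = "HER2+",
                          cells = cohort_cells(subtype), rho = 0.6,
                          rcb_probs = c("0" = 5, "I" = 5, "II" = 6, "III" = 6) / 22,
                          allocation = c("sampled", "proportional"),
                          seed = 1L) {
  allocation <- match.arg(allocation)
  if (n_patients < 2) abort("`n_patients` must be >= 2.")
  if (rho < 0 || rho > 1) abort("`rho` must lie in [0, 1].")
  if (any(c(cells$pre_sd, cells$post_sd) <= 0)) abort("cell SDs must be > 0.")
  if (!setequal(names(rcb_probs), c("0", "I", "II", "III"))) {
    abort("`rcb_probs` must be named with classes 0, I, II, III.")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), subtype = subtype, cells = cells,
      rho = rho, rcb_probs = rcb_probs / sum(rcb_probs),
      allocation = allocation, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate a patient cohort with paired pre/post values
#'
#' For every cell (measure x region), each patient's pre- and post-treatment
#' values are drawn from a bivariate normal with the cell's means and SDs
#' and the configured pre/post correlation. RCB classes are attached per
#' patient. Identical configs (including the seed) reproduce the table
#' exactly.
#'
#' @param config A [cohort_config()].
#' @return Long tibble: `patient_id`, `subtype`, `rcb_class`, `measure`,
#'   `region`, `timepoint`, `value`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  with_seed(derive_seed(config$seed, 17L), {
    classes <- names(config$rcb_probs)
    rcb <- if (config$allocation == "sampled") {
      sample(classes, n, replace = TRUE, prob = config$rcb_probs)
    } else {
      counts <- floor(config$rcb_probs * n)
      rem <- n - sum(counts)
      if (rem > 0) {
        frac <- config$rcb_probs * n - counts
        extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1
      }
      sample(base::rep(classes, times = counts))
    }
    patients <- tibble::tibble(
      patient_id = sprintf("P%02d", seq_len(n)),
      subtype = config$subtype,
      rcb_class = rcb
    )
    draws <- purrr::pmap_dfr(
      config$cells,
      function(measure, region, pre_mean, pre_sd, post_mean, post_sd) {
        sig <- matrix(c(
          pre_sd^2, config$rho * pre_sd * post_sd,
          config$rho * pre_sd * post_sd, post_sd^2
        ), 2)
        xy <- MASS::mvrnorm(n, mu = c(pre_mean, post_mean), Sigma = sig)
        tibble::tibble(
          patient_id = base::rep(patients$patient_id, 2),
          measure = measure, region = region,
          timepoint = base::rep(c("pre", "post"), each = n),
          value = c(xy[, 1], xy[, 2])
        )
      }
    )
    dplyr::left_join(draws, patients, by = "patient_id") |>
      dplyr::select(patient_id, subtype, rcb_class, measure, region,
                    timepoint, value)
  })
}
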