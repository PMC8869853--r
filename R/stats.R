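# Normality-routed paired/unpaired comparisons, RCB pooling, and logistic
# association of baseline measures with binarized outcome class.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) transformed skewness Z and the
#' Anscombe-Glynn (1983) transformed kurtosis Z into the omnibus statistic
#' `K2 = Z_skew^2 + Z_kurt^2`, referred to a chi-squared distribution with
#' 2 degrees of freedom. Requires n >= 8 for the kurtosis approximation.
#'
#' @param x Numeric sample, n >= 8.
#' @return An object of class `htest` with `statistic` (K2), `p.value`, and
#'   the two component Z scores in `estimate`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) abort("the omnibus normality test requires n >= 8.")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 == 0) abort("sample has zero variance; normality is undefined.")
  # skewness: D'Agostino (1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
    ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z_skew^2 + z_kurt^2
  structure(
    list(
      statistic = c(K2 = k2),
      p.value = pchisq(k2, df = 2, lower.tail = FALSE),
      estimate = c(z_skew = z_skew, z_kurt = z_kurt),
      method = "D'Agostino-Pearson omnibus normality test",
      data.name = deparse(substitute(x)), n = n
    ),
    class = "htest"
  )
}

#' Route a comparison to a parametric or nonparametric test
#'
#' Paired designs assess normality of the pairwise differences (that is what
#' the paired t-test assumes normal); unpaired designs assess each sample.
#' The parametric route is taken only when every relevant normality p-value
#' exceeds `alpha_norm`.
#'
#' @param a,b Numeric samples (`b` may be `NULL` for a one-sample check).
#' @param paired Logical; is this a paired design?
#' @param alpha_norm Normality gate (default 0.05).
#' @return A list with `route` (`"parametric"` / `"nonparametric"`),
#'   `normality` (tibble of the normality p-values), and `rationale`.
#' @export
route_test <- function(a, b = NULL, paired = FALSE, alpha_norm = 0.05) {
  check_n <- function(x, lab) {
    if (length(x) < 8) {
      abort(sprintf(
        "%s has n = %d < 8: the omnibus normality test cannot run; use the nonparametric route explicitly.",
        lab, length(x)
      ))
    }
  }
  if (paired) {
    if (length(a) != length(b)) abort("paired samples must have equal length.")
    d <- a - b
    check_n(d, "the difference sample")
    if (var(d) == 0) {
      # identical pairs: normality is undefined but the routed tests are
      # degenerate anyway; route parametric with a note
      norm <- tibble::tibble(sample = "differences", p_normality = NA_real_)
      return(list(route = "parametric", normality = norm,
                  rationale = "zero-variance differences (degenerate)"))
    }
    p <- dagostino_pearson(d)$p.value
    norm <- tibble::tibble(sample = "differences", p_normality = p)
    ps <- p
  } else {
    check_n(a, "sample a")
    check_n(b, "sample b")
    pa <- dagostino_pearson(a)$p.value
    pb <- dagostino_pearson(b)$p.value
    norm <- tibble::tibble(sample = c("a", "b"), p_normality = c(pa, pb))
    ps <- c(pa, pb)
  }
  route <- if (all(ps > alpha_norm)) "parametric" else "nonparametric"
  list(
    route = route, normality = norm,
    rationale = sprintf(
      "min normality p = %.3g %s %.2f", min(ps),
      if (route == "parametric") ">" else "<=", alpha_norm
    )
  )
}

# Routing for the compare_* front-ends: below n = 8 the omnibus normality
# test cannot run, so the comparison falls to the distribution-free route.
safe_route <- function(a, b, paired, alpha_norm) {
  n_min <- if (paired) length(a) else min(length(a), length(b))
  if (n_min < 8) {
    return(list(
      route = "nonparametric",
      normality = tibble::tibble(sample = character(), p_normality = double()),
      rationale = "n < 8: omnibus normality test unavailable"
    ))
  }
  route_test(a, b, paired = paired, alpha_norm = alpha_norm)
}

group_summary <- function(values, group) {
  tibble::tibble(
    group = group,
    n = length(values),
    mean = mean(values),
    sem = sd(values) / sqrt(length(values))
  )
}

new_comparison <- function(test_name, statistic, p_value, n, summaries,
                           route, flags = character(0)) {
  structure(
    list(
      test_name = test_name, statistic = statistic, p_value = p_value,
      n = n, summaries = summaries, route = route, flags = flags
    ),
    class = "shg_comparison"
  )
}

# exact rank tests when feasible (no ties/zeros, n <= 25), else the normal
# approximation with continuity correction
rank_test_exact <- function(x, n_limit = 25) {
  length(x) <= n_limit && !any(duplicated(abs(x))) && !any(x == 0)
}

#' Paired two-sample comparison with normality routing
#'
#' Assesses normality of the pairwise differences; runs a paired t-test on
#' the parametric route and a Wilcoxon signed-rank test otherwise (exact
#' when n <= 25 without ties or zero differences, else the
#' continuity-corrected normal approximation). All-zero differences yield
#' the degenerate p = 1 with a flag.
#'
#' @param a,b Paired numeric samples of equal length, n >= 3.
#' @param alpha_norm Normality gate for [route_test()].
#' @return An `shg_comparison` with [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
compare_paired <- function(a, b, alpha_norm = 0.05) {
  if (length(a) != length(b)) abort("paired samples must have equal length.")
  n <- length(a)
  if (n < 3) abort("need n >= 3 pairs.")
  summ <- dplyr::bind_rows(group_summary(a, "a"), group_summary(b, "b"))
  d <- a - b
  if (all(d == 0)) {
    return(new_comparison(
      "paired-t", statistic = 0, p_value = 1, n = n, summaries = summ,
      route = list(route = "parametric", rationale = "all differences zero"),
      flags = "degenerate"
    ))
  }
  rt <- safe_route(a, b, paired = TRUE, alpha_norm = alpha_norm)
  if (rt$route == "parametric") {
    ht <- t.test(a, b, paired = TRUE)
    new_comparison("paired-t", unname(ht$statistic), ht$p.value, n, summ, rt)
  } else {
    exact <- rank_test_exact(d)
    ht <- suppressWarnings(
      wilcox.test(a, b, paired = TRUE, exact = exact, correct = TRUE)
    )
    new_comparison("wilcoxon-signed-rank", unname(ht$statistic), ht$p.value,
                   n, summ, rt)
  }
}

#' Unpaired two-sample comparison with normality routing
#'
#' Assesses normality of each sample; runs Welch's t-test on the parametric
#' route and a Mann-Whitney test otherwise. Two zero-variance samples with
#' equal means yield the degenerate p = 1 with a flag.
#'
#' @param a,b Numeric samples, each n >= 3.
#' @param alpha_norm Normality gate for [route_test()].
#' @return An `shg_comparison`.
#' @export
compare_unpaired <- function(a, b, alpha_norm = 0.05) {
  if (length(a) < 3 || length(b) < 3) abort("need n >= 3 per group.")
  summ <- dplyr::bind_rows(group_summary(a, "a"), group_summary(b, "b"))
  n <- c(a = length(a), b = length(b))
  if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b)) {
    return(new_comparison(
      "unpaired-t", statistic = 0, p_value = 1, n = n, summaries = summ,
      route = list(route = "parametric", rationale = "both samples constant and equal"),
      flags = "degenerate"
    ))
  }
  rt <- safe_route(a, b, paired = FALSE, alpha_norm = alpha_norm)
  if (rt$route == "parametric") {
    ht <- t.test(a, b)
    new_comparison("unpaired-t", unname(ht$statistic), ht$p.value, n, summ, rt)
  } else {
    exact <- length(a) <= 25 && length(b) <= 25 &&
      !any(duplicated(c(a, b)))
    ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    new_comparison("mann-whitney", unname(ht$statistic), ht$p.value, n, summ, rt)
  }
}

#' Pool residual cancer burden classes by long-term prognosis
#'
#' Classes 0 (pathologic complete response) and I share a favorable
#' five-year prognosis and are pooled as `"0/I"`; classes II and III are
#' pooled as `"II/III"`.
#'
#' @param rcb_class Vector of classes among `"0"`, `"I"`, `"II"`, `"III"`.
#' @return Factor with levels `"0/I"` and `"II/III"`.
#' @export
rcb_binarize <- function(rcb_class) {
  x <- as.character(rcb_class)
  known <- c("0" = "0/I", "I" = "0/I", "II" = "II/III", "III" = "II/III")
  if (any(!x %in% names(known))) {
    abort(sprintf(
      "unknown RCB class label(s): %s",
      paste(unique(x[!x %in% names(known)]), collapse = ", ")
    ))
  }
  factor(unname(known[x]), levels = c("0/I", "II/III"))
}

# Firth-penalized logistic regression (Jeffreys-prior score correction),
# used as the fallback under complete separation. Returns the coefficient,
# standard error and Wald p for the single predictor.
firth_logistic <- function(y, x, max_iter = 100, tol = 1e-8) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    wv <- p * (1 - p)
    XtW <- t(X * wv)
    info <- XtW %*% X
    inv <- solve(info)
    hat <- rowSums((X %*% inv) * (X * wv))
    score <- t(X) %*% (y - p + hat * (0.5 - p))
    step <- inv %*% score
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(inv))
  list(
    coef = beta[[2]], se = se[[2]],
    p_value = 2 * pnorm(-abs(beta[[2]] / se[[2]]))
  )
}

#' Logistic association of a baseline measure with binarized outcome
#'
#' Single-predictor logistic regression of the pooled outcome class on a
#' baseline measurement, reporting the two-sided Wald p-value for the
#' predictor coefficient. Complete (or quasi-complete) separation is
#' detected and handled by a Firth-penalized fit, flagged in the result.
#'
#' @param outcome Binarized outcome per patient (`"0/I"` / `"II/III"`
#'   factor from [rcb_binarize()], logical, or 0/1).
#' @param predictor Numeric baseline values, same length.
#' @return A one-row tibble: `estimate`, `std_error`, `p_value`, `n`,
#'   `method` (`"logistic"` or `"logistic-firth"`), `separation`.
#' @export
associate_binary <- function(outcome, predictor) {
  if (is.factor(outcome) || is.character(outcome)) {
    y <- as.integer(factor(as.character(outcome))) - 1L
  } else {
    y <- as.integer(outcome)
  }
  if (length(y) != length(predictor)) abort("lengths differ.")
  keep <- is.finite(predictor) & !is.na(y)
  y <- y[keep]
  predictor <- predictor[keep]
  if (length(y) < 10) abort("need n >= 10 for the logistic association.")
  if (length(unique(y)) < 2) abort("both outcome levels must be present.")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ predictor, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)$coefficients
  if (!sep && (abs(co["predictor", "Estimate"]) > 20 ||
               co["predictor", "Std. Error"] > 100)) {
    sep <- TRUE
  }
  if (sep) {
    warn("separation detected; reporting the Firth-penalized fit.")
    ff <- firth_logistic(y, predictor)
    return(tibble::tibble(
      estimate = ff$coef, std_error = ff$se, p_value = ff$p_value,
      n = length(y), method = "logistic-firth", separation = TRUE
    ))
  }
  tibble::tibble(
    estimate = co["predictor", "Estimate"],
    std_error = co["predictor", "Std. Error"],
    p_value = co["predictor", "Pr(>|z|)"],
    n = length(y), method = "logistic", separation = FALSE
  )
}

#' Pre/post comparisons within pooled outcome subgroups
#'
#' Runs the routed paired comparison of pre- versus post-treatment values
#' overall and within each pooled RCB subgroup for one measure and region.
#' Subgroups with fewer than 3 complete pairs are flagged, not computed.
#'
#' @param records Long tibble with columns `patient_id`, `rcb_class`,
#'   `region`, `timepoint` (`"pre"` / `"post"`), and `value`.
#' @param region Region to analyse (e.g. `"bulk"`).
#' @param alpha_norm Normality gate.
#' @return Tibble: `subgroup`, `n`, `test_name`, `statistic`, `p_value`,
#'   `flag`.
#' @export
subgroup_analysis <- function(records, region, alpha_norm = 0.05) {
  reg <- region
  wide <- records |>
    dplyr::filter(region == reg) |>
    dplyr::select(patient_id, rcb_class, timepoint, value) |>
    tidyr::pivot_wider(names_from = timepoint, values_from = value) |>
    dplyr::filter(is.finite(pre), is.finite(post)) |>
    dplyr::mutate(rcb_group = rcb_binarize(rcb_class))
  run_one <- function(df, label) {
    if (nrow(df) < 3) {
      return(tibble::tibble(
        subgroup = label, n = nrow(df), test_name = NA_character_,
        statistic = NA_real_, p_value = NA_real_, flag = "undersized"
      ))
    }
    cmp <- compare_paired(df$pre, df$post, alpha_norm = alpha_norm)
    tibble::tibble(
      subgroup = label, n = nrow(df), test_name = cmp$test_name,
      statistic = cmp$statistic, p_value = cmp$p_value,
      flag = if (length(cmp$flags)) paste(cmp$flags, collapse = ";") else ""
    )
  }
  dplyr::bind_rows(
    run_one(wide, "all"),
    run_one(dplyr::filter(wide, rcb_group == "0/I"), "0/I"),
    run_one(dplyr::filter(wide, rcb_group == "II/III"), "II/III")
  )
}
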