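# Expected values for the omnibus normality test were computed once with an
# independent implementation (scipy.stats.normaltest / skewtest /
# kurtosistest) and frozen here.
test_that("omnibus normality statistic matches the independent reference", {
  x_norm <- c(
    10.609434, 7.920032, 11.500902, 11.881129, 6.09793, 7.395641, 10.255681,
    9.367515, 9.966398, 8.293912, 11.758796, 11.555584, 10.132061, 12.254482,
    10.935019, 8.281415, 10.737502, 8.082235, 11.756901, 9.900148, 9.630275,
    8.638141
  )
  ht <- dagostino_pearson(x_norm)
  expect_equal(unname(ht$statistic), 1.2838315, tolerance = 1e-6)
  expect_equal(ht$p.value, 0.52628323, tolerance = 1e-6)
  expect_equal(unname(ht$estimate),
               c(-1.02647960, -0.47976153), tolerance = 1e-6)

  x_lnorm <- c(
    7.228511, 2.402179, 1.929648, 2.05093, 4.161382, 3.641353, 3.781747,
    3.83687, 15.079227, 1.963774, 1.80436, 1.417623, 4.449464, 6.707175,
    2.481447, 1.388015, 1.405531, 4.574394, 4.926375, 4.197644, 1.596146,
    3.273072
  )
  ht2 <- dagostino_pearson(x_lnorm)
  expect_equal(unname(ht2$statistic), 31.4145278, tolerance = 1e-6)
  expect_equal(ht2$p.value, 1.5080716e-07, tolerance = 1e-4)

  x8 <- c(0.116686, 0.218689, 0.871429, 0.223596, 0.678914, 0.067579,
          0.289119, 0.631288)
  expect_equal(unname(dagostino_pearson(x8)$statistic), 1.5482090,
               tolerance = 1e-6)
  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
})

test_that("routing keeps normal data parametric and heavy tails nonparametric", {
  set.seed(101)
  routes_norm <- replicate(300, {
    d <- rnorm(22)
    route_test(d + 1, rep(1, 22), paired = TRUE)$route
  })
  expect_gte(mean(routes_norm == "parametric"), 0.90)
  routes_heavy <- replicate(300, {
    d <- exp(rnorm(22, 0, 1.2))
    route_test(d, rep(0, 22), paired = TRUE)$route
  })
  expect_gt(mean(routes_heavy == "nonparametric"), 0.5)
  expect_error(route_test(rnorm(5), rnorm(5), paired = TRUE),
               "nonparametric route")
})

test_that("paired comparison handles degenerate and permuted input", {
  a <- rnorm(12, 5)
  cmp <- compare_paired(a, a)
  expect_equal(cmp$p_value, 1)
  expect_true("degenerate" %in% cmp$flags)
  set.seed(7)
  x <- rnorm(22, 5)
  y <- x + rnorm(22, 0.5, 0.4)
  c1 <- compare_paired(x, y)
  ord <- sample(22)
  c2 <- compare_paired(x[ord], y[ord])
  expect_equal(c1$p_value, c2$p_value)
  expect_equal(c1$statistic, c2$statistic)
  td <- tidy(c1)
  expect_named(td, c("test_name", "statistic", "p_value", "n", "route", "flags"))
  expect_equal(nrow(glance(c1)), 2)
})

test_that("paired route has power for the tumor-bulk effect size", {
  set.seed(202)
  sd_pre <- 0.36 * sqrt(22)
  sd_post <- 0.37 * sqrt(22)
  rej <- replicate(200, {
    cells <- tibble::tibble(measure = "fb", region = "bulk",
                            pre_mean = 5.25, pre_sd = sd_pre,
                            post_mean = 6.24, post_sd = sd_post)
    sig <- matrix(c(sd_pre^2, 0.6 * sd_pre * sd_post,
                    0.6 * sd_pre * sd_post, sd_post^2), 2)
    xy <- MASS::mvrnorm(22, c(5.25, 6.24), sig)
    compare_paired(xy[, 1], xy[, 2])$p_value < 0.05
  })
  expect_gte(mean(rej), 0.6)
})

test_that("unpaired comparison is symmetric and detects large shifts", {
  set.seed(55)
  a <- rnorm(22, 5, 1)
  b <- rnorm(22, 5.5, 1)
  c1 <- compare_unpaired(a, b)
  c2 <- compare_unpaired(b, a)
  expect_equal(c1$p_value, c2$p_value)
  if (c1$test_name == "unpaired-t") {
    expect_equal(c1$statistic, -c2$statistic)
  }
  rej <- replicate(100, {
    x <- rnorm(22)
    y <- rnorm(22, 3)
    compare_unpaired(x, y)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.99)
  cd <- compare_unpaired(rep(2, 5), rep(2, 5))
  expect_equal(cd$p_value, 1)
  expect_true("degenerate" %in% cd$flags)
})

test_that("RCB classes pool by long-term prognosis", {
  expect_equal(as.character(rcb_binarize(c("0", "I", "II", "III"))),
               c("0/I", "0/I", "II/III", "II/III"))
  expect_equal(as.character(rcb_binarize("0")), "0/I")
  expect_error(rcb_binarize("IV"), "unknown")
})

test_that("logistic association is calibrated and flags separation", {
  set.seed(77)
  ps <- replicate(400, {
    y <- rep(c(0, 1), each = 11)
    x <- rnorm(22)
    associate_binary(y, x)$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
  expect_error(associate_binary(rep(1, 22), rnorm(22)), "both outcome levels")
  expect_error(associate_binary(rep(c(0, 1), 3), rnorm(6)), "n >= 10")
  y <- rep(c(0, 1), each = 10)
  x <- y + rnorm(20, 0, 1e-4)
  expect_warning(res <- associate_binary(y, x), "separation")
  expect_true(res$separation)
  expect_equal(res$method, "logistic-firth")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("firth fallback agrees with plain logistic away from separation", {
  set.seed(91)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(0.8 * x))
  plain <- summary(glm(y ~ x, family = binomial()))$coefficients["x", ]
  firth <- shgfb:::firth_logistic(y, x)
  expect_equal(firth$coef, unname(plain["Estimate"]), tolerance = 0.05)
  expect_equal(firth$se, unname(plain["Std. Error"]), tolerance = 0.05)
})

test_that("subgroup analysis detects stratum-specific effects", {
  set.seed(303)
  sig_01 <- 0
  sig_23 <- 0
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    n <- 22
    rcb <- rep(c("0", "I", "II", "III"), times = c(5, 5, 6, 6))
    pre <- rnorm(n, 5, 1)
    eff <- ifelse(rcb %in% c("0", "I"), 1.5, 0)
    post <- pre + eff + rnorm(n, 0, 0.8)
    recs <- tibble::tibble(
      patient_id = sprintf("P%02d", 1:n), rcb_class = rcb, region = "bulk",
      timepoint = rep("pre", n), value = pre
    ) |>
      dplyr::bind_rows(tibble::tibble(
        patient_id = sprintf("P%02d", 1:n), rcb_class = rcb, region = "bulk",
        timepoint = rep("post", n), value = post
      ))
    tab <- subgroup_analysis(recs, "bulk")
    expect_equal(tab$subgroup, c("all", "0/I", "II/III"))
    expect_equal(tab$n[tab$subgroup == "0/I"], 10)
    expect_equal(tab$n[tab$subgroup == "II/III"], 12)
    sig_01 <- sig_01 + (tab$p_value[tab$subgroup == "0/I"] < 0.05)
    sig_23 <- sig_23 + (tab$p_value[tab$subgroup == "II/III"] < 0.05)
  }
  expect_gt(sig_01, sig_23)
})

test_that("undersized subgroups are flagged rather than computed", {
  recs <- tibble::tibble(
    patient_id = rep(sprintf("P%d", 1:4), 2),
    rcb_class = rep(c("0", "II", "II", "III"), 2),
    region = "bulk",
    timepoint = rep(c("pre", "post"), each = 4),
    value = rnorm(8, 5)
  )
  tab <- subgroup_analysis(recs, "bulk")
  expect_equal(tab$flag[tab$subgroup == "0/I"], "undersized")
  expect_true(is.na(tab$p_value[tab$subgroup == "0/I"]))
})
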