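test_that("log-normal calibration reproduces the requested median and IQR", {
  p <- calibrate_lognormal(17.565, 9.46)
  expect_equal(unname(p["location"]), log(17.565))
  expect_equal(unname(p["scale"]), asinh(9.46 / (2 * 17.565)) / qnorm(0.75),
               tolerance = 1e-12)
  expect_equal(unname(p["scale"]), 0.395, tolerance = 0.002)

  # empirical check of the law itself
  set.seed(1)
  draws <- exp(p["location"] + p["scale"] * rnorm(2e5))
  expect_equal(median(draws), 17.565, tolerance = 0.06)
  expect_equal(IQR(draws), 9.46, tolerance = 0.08)

  # limit cases
  expect_equal(unname(calibrate_lognormal(17.565, 1e-12)["scale"]), 0,
               tolerance = 1e-10)
  expect_equal(unname(calibrate_lognormal(1, 5)["location"]), 0)
  expect_error(calibrate_lognormal(-1, 2), "median")
  expect_error(calibrate_lognormal(0, 2), "median")
})

test_that("stratum counts are exact for every seed and configuration", {
  for (seed in c(1, 99)) {
    g <- generate_cohort(scenario_config(seed = seed))
    co <- g$cohort
    expect_equal(nrow(co), 1326L)
    expect_equal(sum(co$sex == "M"), 635L)
    expect_equal(sum(co$sex == "F"), 691L)
    dec <- table(cut(co$age, c(35, 45, 55, 65, 75), right = FALSE,
                     include.lowest = TRUE))
    expect_equal(unname(c(dec)), c(295L, 350L, 353L, 328L))
  }
  # proportional scaling for other totals
  cfg <- scenario_config(n_total = 400)
  expect_equal(cfg$n_male + cfg$n_female, 400L)
  expect_equal(sum(cfg$decade_counts), 400L)
  g <- generate_cohort(cfg)
  expect_equal(nrow(g$cohort), 400L)
})

test_that("generation is deterministic in the seed and respects ranges", {
  a <- generate_cohort(scenario_config(seed = 5))
  b <- generate_cohort(scenario_config(seed = 5))
  expect_identical(a$cohort, b$cohort)
  d <- generate_cohort(scenario_config(seed = 6))
  expect_false(identical(a$cohort, d$cohort))

  co <- a$cohort
  expect_false(anyNA(co))
  expect_true(all(co$age >= 35 & co$age <= 75))
  for (oc in c("cst_pct", "dna_integrity_pct", "dna_damage_38gy_pct")) {
    expect_true(all(co[[oc]] >= 0 & co[[oc]] <= 100))
  }
})

test_that("calibrated medians match their targets within order-statistic error", {
  co <- generate_cohort(scenario_config(seed = 314))$cohort
  n <- nrow(co)
  se_med <- function(med, iqr) {
    s <- calibrate_lognormal(med, iqr)[["scale"]]
    f <- 1 / (med * s * sqrt(2 * pi))  # log-normal density at its median
    1 / (2 * f * sqrt(n))
  }
  expect_lt(abs(median(co$ldlox) - 17.565), 3 * se_med(17.565, 9.46))
  expect_lt(abs(median(co$nox) - 25.808), 3 * se_med(25.808, 15.505))
})

test_that("null scenario outcomes are exchangeable between arms", {
  rejections <- 0L
  for (s in 1:50) {
    g <- generate_cohort(scenario_config(
      n_total = 400, strength = 0,
      injected_effect = list(intervention = "LDLox_Q50",
                             outcome = "cst_pct", tau = 0),
      seed = 700 + s))
    tr <- apply_intervention(default_intervention_specs()[["LDLox_Q50"]],
                             g$cohort)$indicator
    p <- wilcox.test(g$cohort$cst_pct[tr == 1],
                     g$cohort$cst_pct[tr == 0])$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 4L)  # binomial(50, 0.01): P(>4) < 1e-4
})

test_that("naive contrast under confounding matches the copula closed form", {
  # single-axis configuration so the contrast is analytically tractable:
  # exposure latent u has cov(u, G_N) = a; log-outcome S = b * G_N.
  a <- 0.3; b <- 0.15
  cs <- default_confounding_strengths()
  cs$exposures <- lapply(cs$exposures, function(w) w * 0)
  cs$outcomes <- lapply(cs$outcomes, function(w) w * 0)
  cs$exposures$nox[["G_N"]] <- a
  cs$outcomes$cst_pct[["G_N"]] <- b
  cs$shared <- 0

  total <- unname(calibrate_lognormal(19.733, 14.017)["scale"])
  rho <- a * b                       # cov(log Y, u)
  cc <- qnorm(0.125)                 # latent cut for the Q12.5 indicator
  ey <- 19.733 * exp(total^2 / 2)
  analytic <- ey * (pnorm(cc - rho, lower.tail = FALSE) / 0.875 -
                    pnorm(cc - rho) / 0.125)

  naive <- vapply(1:30, function(s) {
    g <- generate_cohort(scenario_config(
      confounding_strengths = cs,
      injected_effect = list(intervention = "NOx_Q12.5",
                             outcome = "cst_pct", tau = 0),
      seed = 900 + s))
    g$truth$naive_contrast
  }, numeric(1))
  se <- sd(naive) / sqrt(length(naive))
  expect_gt(analytic, 1)            # the configured coefficients imply real bias
  expect_lt(abs(mean(naive) - analytic), 3 * se)
})

test_that("infeasible outcome spread is rejected as a configuration error", {
  cfg <- scenario_config(seed = 1)
  cfg$noise_scales[["cst_pct"]] <- 3
  expect_error(generate_cohort(cfg), "clipping")
})

test_that("cohort summary reports medians, IQRs and level counts", {
  g <- small_cohort(n = 300, seed = 11)
  sm <- summarize_cohort(g$cohort)
  ld <- sm[sm$variable == "ldlox", ]
  expect_equal(ld$median, median(g$cohort$ldlox))
  expect_equal(ld$iqr, IQR(g$cohort$ldlox))
  sx <- sm[sm$variable == "sex", ]
  expect_equal(sum(sx$count), 300L)

  cst <- g$cohort
  cst$const <- 5
  expect_equal(summarize_cohort(cst)[summarize_cohort(cst)$variable == "const", "iqr"], 0)
  expect_error(summarize_cohort(data.frame()), "non-empty")
})

test_that("cohort and truth record round-trip through plain text", {
  g <- small_cohort(n = 120, seed = 3)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".txt")
  write_cohort(g$cohort, f1)
  back <- read_cohort(f1)
  expect_equal(names(back), names(g$cohort))
  expect_equal(back$ldlox, g$cohort$ldlox, tolerance = 1e-12)
  expect_identical(back$sex, g$cohort$sex)

  write_truth_record(g$truth, f2)
  tr <- read_truth_record(f2)
  expect_identical(tr$intervention, g$truth$intervention)
  expect_identical(tr$outcome, g$truth$outcome)
  expect_equal(tr$injected_effect, g$truth$injected_effect)
  expect_equal(tr$naive_contrast, g$truth$naive_contrast, tolerance = 1e-12)
  expect_identical(tr$seed, g$truth$seed)
  unlink(c(f1, f2))
})
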