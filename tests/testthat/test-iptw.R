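test_that("propensity model recovers known logistic structure", {
  set.seed(8)
  n <- 2e4
  x <- rnorm(n)
  tr <- rbinom(n, 1, plogis(0.5 + 1.2 * x))
  pm <- fit_propensity(matrix(x, ncol = 1), tr)
  expect_true(pm$converged)
  expect_equal(unname(pm$coefficients[2]), 1.2, tolerance = 0.08)

  # treatment independent of covariates at prevalence 1/2
  tr0 <- rbinom(n, 1, 0.5)
  pm0 <- fit_propensity(matrix(x, ncol = 1), tr0)
  expect_true(all(abs(pm0$fitted - 0.5) < 0.05))
})

test_that("perfect separation is flagged and probabilities are clipped", {
  sc <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1)
  tr <- c(rep(0L, 10), rep(1L, 10))
  pm <- fit_propensity(sc, tr, clip = c(0.01, 0.99))
  expect_false(pm$converged)
  expect_true(all(pm$fitted %in% c(0.01, 0.99)))
  expect_error(fit_propensity(sc, rep(1L, 20)), "arms")
})

test_that("weights follow the inverse-probability identities", {
  n <- 100
  tr <- rep(c(1L, 0L), n / 2)
  pm <- structure(list(fitted = rep(0.5, n)), class = "propensity_model")
  expect_equal(compute_weights(pm, tr, stabilized = FALSE), rep(2, n))

  # stabilized weights are 1 when e equals the prevalence
  tr2 <- rep(c(1L, 0L, 0L, 0L), n / 4)
  pm2 <- structure(list(fitted = rep(0.25, n)), class = "propensity_model")
  expect_equal(compute_weights(pm2, tr2, stabilized = TRUE), rep(1, n))

  # arm means of unstabilized weights approximate inverse prevalences
  set.seed(10)
  nn <- 5e4
  x <- rnorm(nn)
  e <- plogis(-1 + x)
  trs <- rbinom(nn, 1, e)
  pm3 <- fit_propensity(matrix(x, ncol = 1), trs)
  w <- compute_weights(pm3, trs, stabilized = FALSE)
  expect_equal(mean(w[trs == 1]), 1 / mean(trs), tolerance = 0.05)
  expect_equal(mean(w[trs == 0]), 1 / mean(1 - trs), tolerance = 0.05)
})

test_that("the Hajek estimate reduces to hand arithmetic", {
  expect_equal(estimate_ate(c(3, 5, 1, 1), c(1, 1, 0, 0), rep(1, 4)), 3)
  expect_equal(estimate_ate(rep(7, 10), rep(c(1, 0), 5), runif(10)), 0)
  # invariant to rescaling weights within an arm
  y <- rnorm(20); tr <- rep(c(1, 0), 10); w <- runif(20)
  w2 <- w; w2[tr == 1] <- w2[tr == 1] * 13
  expect_equal(estimate_ate(y, tr, w), estimate_ate(y, tr, w2))
  expect_error(estimate_ate(y, rep(1, 20), w), "arms")
})

test_that("constant propensities make IPTW equal the naive contrast exactly", {
  set.seed(11)
  y <- rlnorm(300); tr <- rbinom(300, 1, 0.3)
  pm <- fit_propensity(matrix(0, 300, 2), tr)  # uninformative design
  expect_equal(pm$fitted, rep(mean(tr), 300), tolerance = 1e-6)
  expect_equal(length(unique(pm$fitted)), 1L)  # constant across subjects
  w <- compute_weights(pm, tr)
  naive <- mean(y[tr == 1]) - mean(y[tr == 0])
  expect_equal(estimate_ate(y, tr, w), naive, tolerance = 1e-12)
})

test_that("bootstrap p-values are deterministic and leave the RNG untouched", {
  g <- small_cohort(n = 300, seed = 17)
  co <- g$cohort
  tr <- apply_intervention(default_intervention_specs()[["LDLox_Q50"]], co)$indicator
  conf <- co[, confounder_columns(co)]; class(conf) <- "data.frame"
  sc <- fit_famd(conf)$scores

  set.seed(123); before <- runif(3)
  set.seed(123); runif_probe <- runif(1)
  p1 <- bootstrap_pvalue(sc, tr, co$cst_pct, B = 99, seed = 4)$p_value
  after <- runif(2)
  expect_identical(c(runif_probe, after), before)  # global stream undisturbed

  p2 <- bootstrap_pvalue(sc, tr, co$cst_pct, B = 99, seed = 4)$p_value
  expect_identical(p1, p2)
  expect_true(p1 >= 1 / 100 && p1 <= 1)
  expect_error(bootstrap_pvalue(sc, tr, co$cst_pct, B = 50), "B >= 99")
})

test_that("run_iptw composes the stages and reports diagnostics", {
  g <- small_cohort(n = 1000, seed = 19, tau = 5)
  est <- run_iptw(g$cohort, "HDL-C_60", "cst_pct",
                  iptw_config(B = 199L, seed = 2))
  expect_s3_class(est, "causal_estimate")
  expect_equal(est$n_treated + est$n_control, 1000L)
  expect_lte(est$ess_treated, est$n_treated)
  expect_lte(est$ess_control, est$n_control)
  expect_true(est$p_value >= 0 && est$p_value <= 1)

  # a strongly injected effect is detected
  expect_lt(est$p_value, 0.05)

  # constant intervention column errors
  co2 <- g$cohort; co2$hdl_c <- co2$hdl_c + 1000
  expect_error(run_iptw(co2, "HDL-C_60", "cst_pct"), "constant")
  expect_error(run_iptw(g$cohort, "HDL-C_60", "nope"), "outcome")
})

test_that("IPTW shrinks confounding bias relative to the naive contrast", {
  est <- c(); naive <- c()
  for (s in 1:24) {
    g <- small_cohort(n = 1326, seed = 5000 + s, intervention = "HDL-C_60",
                      tau = 3.214)
    r <- run_iptw(g$cohort, "HDL-C_60", "cst_pct",
                  iptw_config(compute_p = FALSE))
    est <- c(est, r$effect); naive <- c(naive, g$truth$naive_contrast)
  }
  expect_lt(abs(mean(est) - 3.214), abs(mean(naive) - 3.214))
})
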