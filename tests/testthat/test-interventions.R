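test_that("octile cut points follow the interpolated order-statistic convention", {
  # hand evaluation of h = (n-1)p + 1 on 1..8
  expect_equal(unname(compute_octiles(1:8)),
               c(1.875, 2.75, 3.625, 4.5, 5.375, 6.25, 7.125))
  expect_equal(unname(compute_octiles(rep(4, 10))), rep(4, 7))
  expect_equal(compute_octiles(8:1), compute_octiles(1:8))
  expect_error(compute_octiles(1:7), ">= 8")
  expect_error(compute_octiles(c(1:8, NA)), ">= 8")
  expect_error(compute_octiles(c(1:8, Inf)), ">= 8")
})

test_that("binarize honours threshold direction and reports exact frequencies", {
  # tie-free even-length vector at its interpolated median: exactly half at or above
  set.seed(42)
  x <- rnorm(500)  # even n, ties impossible
  med <- unname(quantile(x, 0.5, type = 7))
  col <- binarize(x, med, "at_or_above")
  expect_equal(col$frequency, 50)
  expect_equal(binarize(x, min(x) - 1, "at_or_above")$frequency, 100)
  expect_equal(binarize(c(1, 2, 3, 4), 2.5, "below")$indicator, c(1L, 1L, 0L, 0L))
  expect_equal(binarize(c(1, 2, 3, 4), 2.5, "below")$frequency, 50)
  expect_error(binarize(c(1, NA), 1), "finite")
})

test_that("combined indicators are the elementwise conjunction", {
  a <- binarize(c(1, 1, 0, 0), 0.5, "at_or_above", name = "a")
  b <- binarize(c(1, 0, 1, 0), 0.5, "at_or_above", name = "b")
  ab <- combine_indicators(a, b, "ab")
  expect_equal(ab$indicator, c(1L, 0L, 0L, 0L))
  expect_equal(ab$frequency, 25)
  expect_lte(ab$frequency, min(a$frequency, b$frequency))

  ones <- binarize(rep(1, 4), 0, "at_or_above")
  expect_equal(combine_indicators(a, ones, "id")$indicator, a$indicator)
  short <- binarize(c(1, 0), 0.5, "at_or_above")
  expect_error(combine_indicators(a, short, "x"), "length")
})

test_that("independent indicators combine close to the product law", {
  set.seed(9)
  n <- 2e5
  a <- binarize(runif(n), 0.875, "at_or_above", name = "a")
  b <- binarize(runif(n), 0.875, "at_or_above", name = "b")
  ab <- combine_indicators(a, b, "ab")
  expect_equal(ab$frequency, 100 * 0.125^2, tolerance = 0.15)
})

test_that("HOMA-IR is insulin x glucose / 405", {
  expect_equal(homa_ir(10, 100), 1000 / 405)
  expect_equal(homa_ir(c(10, 2), c(100, 81)), c(1000, 162) / 405)
  expect_equal(homa_ir(1e-9, 90), 1e-9 * 90 / 405)
  expect_error(homa_ir(0, 90), "positive")
  expect_error(homa_ir(5, -1), "positive")
})

test_that("the default intervention table has 33 rows with sane frequencies", {
  co <- small_cohort(n = 800, seed = 21)$cohort
  cols <- build_intervention_table(co)
  expect_length(cols, 33L)
  freqs <- vapply(cols, `[[`, numeric(1), "frequency")
  expect_true(all(freqs > 0 & freqs < 100))

  # octile indicator frequencies are within one subject of nominal mass
  n <- nrow(co)
  for (p in c(0.125, 0.25, 0.375, 0.5, 0.625, 0.75, 0.875)) {
    nm <- paste0("LDLox_Q", sub("\\.?0+$", "", sprintf("%.1f", 100 * p)))
    cnt <- sum(cols[[nm]]$indicator)
    expect_true(cnt %in% c(floor((1 - p) * n), ceiling((1 - p) * n)),
                info = nm)
  }
  # non-increasing in probability level; combined below both members
  ldlox_freq <- freqs[grep("^LDLox_Q", names(freqs))]
  expect_true(all(diff(ldlox_freq) < 0))
  for (q in c("12.5", "25", "50", "87.5")) {
    expect_lte(freqs[[paste0("Risk_NOx+LDLox_Q", q)]],
               min(freqs[[paste0("NOx_Q", q)]], freqs[[paste0("LDLox_Q", q)]]))
  }
})

test_that("octile membership depends only on ranks", {
  co <- small_cohort(n = 200, seed = 33)$cohort
  spec <- default_intervention_specs()[["LDLox_Q75"]]
  before <- apply_intervention(spec, co)$indicator
  co$ldlox <- exp(co$ldlox / 10)  # strictly increasing transform
  expect_identical(apply_intervention(spec, co)$indicator, before)
})

test_that("sex-specific and composite rules read the right columns", {
  co <- data.frame(
    sex = c("M", "M", "F", "F"),
    hdl_c = c(39, 45, 49, 55),
    sbp = c(150, 120, 139, 141),
    dbp = c(80, 95, 89, 60),
    hypertension_treated = c("no", "no", "yes", "no"),
    stringsAsFactors = FALSE)
  specs <- default_intervention_specs()
  expect_equal(apply_intervention(specs[["HDL-C_40_50"]], co)$indicator,
               c(1L, 0L, 1L, 0L))
  expect_equal(apply_intervention(specs[["HBP_uncontrolled_stage1"]], co)$indicator,
               c(1L, 1L, 0L, 1L))
  expect_equal(apply_intervention(specs[["HBP_stage1"]], co)$indicator,
               c(1L, 1L, 1L, 1L))

  # a cohort in which nobody is below the sex-specific threshold
  co2 <- co; co2$hdl_c <- c(41, 45, 51, 55)
  expect_equal(apply_intervention(specs[["HDL-C_40_50"]], co2)$frequency, 0)

  expect_error(apply_intervention(specs[["HDL-C_60"]], co[, "sex", drop = FALSE]),
               "missing")
})

test_that("intervention specs validate their arguments", {
  expect_error(intervention_spec("x", "octile", "nox", level = 0.3), "level")
  expect_error(intervention_spec("x", "combined", "nox", level = 0.5),
               "two variables")
  expect_error(intervention_spec("x", "fixed", "ldl_c", threshold = 1,
                                 direction = "below"), "HDL")
})

test_that("the threshold report mirrors the indicator frequencies", {
  co <- small_cohort(n = 600, seed = 55)$cohort
  rep <- intervention_report(co)
  expect_equal(nrow(rep), 33L)
  expect_equal(rep$sign[rep$intervention == "HDL-C_60"], "<")
  expect_equal(rep$sign[rep$intervention == "NOx_Q50"], ">=")
  cols <- build_intervention_table(co)
  expect_equal(rep$pct_subjects,
               unname(round(vapply(cols, `[[`, numeric(1), "frequency"), 2)))
})
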