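test_that("identical groups show no difference under either test", {
  withr::local_seed(51)
  x <- rnorm(30)
  d <- tibble::tibble(v = c(x, x), g = rep(c("a", "b"), each = 30))
  res <- compare_groups(d, v, g)
  expect_gte(res$p.value, 0.99)
})

test_that("normal well-separated groups route to the t-test and reject", {
  withr::local_seed(52)
  d <- tibble::tibble(v = c(rnorm(50, 0, 1), rnorm(50, 3, 1)),
                      g = rep(c("a", "b"), each = 50))
  res <- compare_groups(d, v, g)
  expect_equal(res$test, "Welch t-test")
  expect_true(res$normal)
  expect_lt(res$p.value, 0.001)
  expect_match(res$summary_1, "±")
})

test_that("skewed groups route to the Mann-Whitney U test with median summaries", {
  withr::local_seed(53)
  d <- tibble::tibble(v = c(rlnorm(60, 0, 1.5), rlnorm(60, 1, 1.5)),
                      g = rep(c("a", "b"), each = 60))
  res <- compare_groups(d, v, g)
  expect_equal(res$test, "Mann-Whitney U")
  expect_false(res$normal)
  expect_match(res$summary_1, "\\[")
})

test_that("tiny groups fall back to the rank test with a warning", {
  d <- tibble::tibble(v = c(1, 2, 5, 6, 7, 8), g = c("a", "a", "b", "b", "b", "b"))
  expect_warning(res <- compare_groups(d, v, g), "fewer than 3")
  expect_equal(res$test, "Mann-Whitney U")
})

test_that("exact linear relations give unit correlations", {
  withr::local_seed(54)
  x <- rnorm(40)
  expect_equal(correlate_pair(tibble::tibble(x = x, y = 2 * x + 1), x, y)$estimate,
               1, tolerance = 1e-12)
  res_neg <- correlate_pair(tibble::tibble(x = x, y = -x), x, y)
  expect_equal(res_neg$estimate, -1, tolerance = 1e-12)
  expect_equal(res_neg$method, "Pearson")
})

test_that("monotone nonlinear relations on skewed data select Spearman with rho 1", {
  withr::local_seed(55)
  x <- rlnorm(50, 0, 1.5)
  res <- correlate_pair(tibble::tibble(x = x, y = x^3), x, y)
  expect_equal(res$method, "Spearman")
  expect_equal(res$estimate, 1)
  expect_error(correlate_pair(tibble::tibble(x = x, y = rep(1, 50)), x, y),
               class = "bstmap_validation_error")
  expect_error(correlate_pair(tibble::tibble(x = 1:3, y = 1:3), x, y),
               class = "bstmap_validation_error")
})

test_that("the ICC sample-size formula reproduces the published design", {
  expect_identical(icc_sample_size(rho0 = 0, rho1 = 0.5, k = 3,
                                   alpha = 0.05, power = 0.9), 15L)
  expect_identical(inflate_for_dropout(15, 0.30), 20L)
  expect_identical(inflate_for_dropout(10, 0), 10L)
  expect_identical(inflate_for_dropout(7, 0.30), 10L)
})

test_that("sample size is monotone in power, effect size and ratings count", {
  n_ref <- icc_sample_size(power = 0.9)
  expect_lt(icc_sample_size(power = 0.8), n_ref)
  expect_lt(icc_sample_size(rho1 = 0.7), n_ref)
  expect_gt(icc_sample_size(k = 2), n_ref)
  # vanishing effect size diverges
  expect_gt(icc_sample_size(rho0 = 0, rho1 = 1e-9), 1e6)
  expect_error(icc_sample_size(rho0 = 0.5, rho1 = 0.3),
               class = "bstmap_validation_error")
  expect_error(icc_sample_size(alpha = 0), class = "bstmap_validation_error")
  expect_error(inflate_for_dropout(0, 0.3), class = "bstmap_validation_error")
})

test_that("cohort analysis mirrors the grouped-summary report layout", {
  withr::local_seed(56)
  n_valgus <- 20
  n_varus <- 20
  tws_x <- c(rnorm(n_valgus, 0.02, 0.005), rnorm(n_varus, -0.02, 0.005))
  tws_y <- c(rnorm(30, 0.02, 0.005), rnorm(10, -0.02, 0.005))
  cohort <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:40),
    tws_x = tws_x, tws_y = tws_y,
    tsa_deg = c(rnorm(n_valgus, 94, 2), rnorm(n_varus, 87, 2)),
    alpha_deg = rnorm(40, 90, 8),
    beta_deg = c(rnorm(30, 84, 2), rnorm(10, 93, 2)),
    ttr_mm = c(rnorm(30, 42, 3), rnorm(10, 54, 3))
  )
  report <- cohort_analysis(cohort)
  comp <- tidy(report, "comparisons")
  # TSA differs strongly between coronal groups, beta/TTR between sagittal
  expect_lt(comp$p.value[comp$variable == "tsa_deg"], 0.05)
  expect_lt(comp$p.value[comp$variable == "beta_deg"], 0.05)
  expect_lt(comp$p.value[comp$variable == "ttr_mm"], 0.05)
  corr <- tidy(report, "correlations")
  expect_true(corr$significant[corr$pair == "tws_x vs tsa_deg"])
  expect_true(all(corr$p.value >= 0 & corr$p.value <= 1))
  expect_equal(glance(report)$n_patients, 40L)
})

test_that("comparisons with a near-empty group are skipped with a warning", {
  withr::local_seed(57)
  cohort <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:12),
    tws_x = rnorm(12, 0.02, 0.005),
    tws_y = c(rep(0.02, 11), -0.02),   # a single posterior patient
    beta_deg = rnorm(12, 85, 3),
    ttr_mm = rnorm(12, 43, 3),
    tsa_deg = rnorm(12, 90, 5)
  )
  expect_warning(report <- cohort_analysis(cohort), "fewer than 2")
  comp <- tidy(report, "comparisons")
  expect_false(any(comp$variable %in% c("beta_deg", "ttr_mm")))
  # the coronal comparison is likewise skipped: every patient is valgus
  expect_false("tsa_deg" %in% comp$variable)
  # correlations are still produced
  expect_equal(nrow(tidy(report, "correlations")), 3L)
})
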