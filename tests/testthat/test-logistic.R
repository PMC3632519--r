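test_that("2x2 odds ratio matches the closed form and its symmetries", {
  r <- odds_ratio_2x2(10, 90, 5, 95)
  expect_equal(r$or, (10 * 95) / (90 * 5))
  expect_equal(r$beta, log(19 / 9))
  expect_equal(r$se, sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95))
  expect_equal(r$ci_low, exp(r$beta - 1.959964 * r$se))
  expect_true(r$ci_low <= r$or && r$or <= r$ci_high)

  expect_equal(odds_ratio_2x2(7, 7, 7, 7)$or, 1)           # symmetry
  expect_error(odds_ratio_2x2(7, 7, 0, 7), "zero cell")    # degenerate
})

test_that("IRLS reproduces the cross-product MLE of a 2x2 table", {
  x <- cbind(1, rep(c(1, 0), c(100, 100)))
  y <- c(rep(1:0, c(10, 90)), rep(1:0, c(5, 95)))
  fit <- fit_logistic(x, y)
  expect_equal(unname(fit$coef[2]), log(19 / 9), tolerance = 1e-9)
  expect_equal(unname(sqrt(fit$vcov[2, 2])),
               sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95), tolerance = 1e-9)
  expect_true(fit$converged)
  expect_true(isSymmetric(fit$vcov))
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > 0))

  # no association: balanced table gives beta exactly 0
  y0 <- c(rep(1:0, c(10, 90)), rep(1:0, c(10, 90)))
  expect_equal(unname(fit_logistic(x, y0)$coef[2]), 0, tolerance = 1e-9)
})

test_that("IRLS agrees with a brute-force likelihood grid on a small fixture", {
  set.seed(77)
  x <- c(0.3, -1.2, 0.8, 2.1, -0.5, 1.4, 0.0, -2.0, 0.9, 1.1,
         -0.7, 0.2, 1.8, -1.5, 0.6, -0.1, 2.4, -0.9, 1.0, 0.4)
  y <- c(1, 0, 1, 1, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  oracle <- grid_mle_logistic(x, y)
  fit <- fit_logistic(cbind(1, x), y)
  expect_equal(unname(fit$coef), oracle, tolerance = 1e-6)
})

test_that("degenerate inputs are refused rather than silently fitted", {
  x <- cbind(1, c(rep(1, 10), rep(0, 10)))
  expect_error(fit_logistic(x, rep(1, 20)), "single class")
  # complete separation: exposure perfectly predicts the outcome
  expect_error(fit_logistic(x, c(rep(1, 10), rep(0, 10))), "separation")
  expect_error(fit_logistic(x[1:2, ], c(1, 0)), "more observations")
})

test_that("crude single-exposure estimate equals the 2x2 oracle on the same analysis set", {
  cc <- derive_exposures(generate_cohort(cohort_config(n = 6000), seed = 31))
  est <- estimate_or(cc, "phd", "diabetes", sex = "male")
  oracle <- do.call(odds_ratio_2x2, as.list(est$counts))
  expect_equal(est$beta, oracle$beta, tolerance = 1e-9)
  expect_equal(est$se, oracle$se, tolerance = 1e-9)
  expect_equal(est$or, oracle$or, tolerance = 1e-9)
})

test_that("relabelling the exposure reference inverts the odds ratio", {
  cc <- derive_exposures(generate_cohort(cohort_config(n = 6000), seed = 32))
  cc$phd_flipped <- 1L - cc$phd
  a <- estimate_or(cc, "phd", "diabetes")
  b <- estimate_or(cc, "phd_flipped", "diabetes")
  expect_equal(a$or, 1 / b$or, tolerance = 1e-8)
})

test_that("adjusted models drop incomplete records and count them", {
  cc <- derive_exposures(generate_cohort(cohort_config(n = 8000), seed = 33))
  est <- estimate_or(cc, "phd", "diabetes",
                     covariates = c("smoking", "leisure_inactive",
                                    "work_inactive", "bmi"))
  expect_true(est$dropped[["incomplete"]] > 0)
  expect_identical(unname(est$dropped[["analysed"]] +
                            est$dropped[["incomplete"]]),
                   unname(est$dropped[["entered"]]))
  # maternal-history analyses exclude reported paternal diabetes
  mat <- estimate_or(cc, "maternal_history", "diabetes")
  expect_true(mat$dropped[["ineligible"]] > 0)
})

test_that("parameter recovery: a configured main-effect odds ratio is re-estimated", {
  cfg <- cohort_config(n = 20000, male_frac = 1,
                       men = list(beta = log(c(1, 2.4, 2.4)),
                                  gamma = c(bmi_gt30 = 0, phd = 0)))
  cc <- derive_exposures(generate_cohort(cfg, seed = 41))
  est <- estimate_or(cc, "phd", "diabetes", sex = "male")
  expect_lt(abs(est$beta - log(2.4)), 3 * est$se)
})
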