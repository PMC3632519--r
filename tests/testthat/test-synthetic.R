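test_that("generation is deterministic given seed and config", {
  cfg <- cohort_config(n = 500)
  c1 <- generate_cohort(cfg, seed = 7)
  c2 <- generate_cohort(cfg, seed = 7)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, p1); write_cohort(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the draw
  expect_false(identical(generate_cohort(cfg, seed = 8)$fasting_glucose,
                         c1$fasting_glucose))
  # the caller's RNG stream is not consumed
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_cohort(cfg, seed = 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("configured exposure prevalences are realised at large n", {
  cfg <- cohort_config(n = 100000)
  cc <- derive_exposures(generate_cohort(cfg, seed = 17))
  women <- cc[cc$sex == "female", ]
  men <- cc[cc$sex == "male", ]
  expect_lt(abs(mean(women$phd) - cfg$women$phd), 0.005)
  expect_lt(abs(mean(men$phd) - cfg$men$phd), 0.005)
  expect_lt(abs(mean(men$bmi_gt30) - cfg$men$p_bmi30), 0.01)
  expect_lt(abs(mean(women$bmi_gt30) - cfg$women$p_bmi30), 0.01)
  expect_lt(abs(mean(men$current_smoker, na.rm = TRUE) -
                  cfg$men$smoking[["current"]]), 0.01)
})

test_that("latent class equals the classification of every generated record", {
  cfg <- cohort_config(n = 30000)
  coh <- generate_cohort(cfg, seed = 23)
  cc <- derive_exposures(coh)
  expect_identical(cc$outcome_class, attr(coh, "latent_class"))
})

test_that("a null generator yields odds ratios near one", {
  cfg <- cohort_config(n = 30000,
                       men = list(beta = c(0, 0, 0), gamma = c(bmi_gt30 = 0, phd = 0)),
                       women = list(beta = c(0, 0, 0), gamma = c(bmi_gt30 = 0, phd = 0)))
  cc <- derive_exposures(generate_cohort(cfg, seed = 29))
  for (expo in c("phd", "bmi_gt30", "current_smoker")) {
    est <- estimate_or(cc, expo, "diabetes")
    expect_lt(abs(est$beta), 3 * est$se)
  }
})

test_that("ground-truth interaction parameters follow from the configuration", {
  truth <- true_interaction(cohort_config())
  expect_equal(truth$or10, 3.4)
  expect_equal(truth$or01, 2.0)
  expect_equal(truth$or11, 9.1)
  expect_equal(truth$s, 8.1 / 3.4)
  expect_identical(truth$status, "ok")

  add <- true_interaction(cohort_config(men = list(beta = log(c(2, 2, 3)))))
  expect_equal(add$s, 1)

  null <- true_interaction(cohort_config(men = list(beta = c(0, 0, 0))))
  expect_identical(null$status, "no_result")
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(men = list(phd = 1.5)), "probabilities")
  expect_error(cohort_config(men = list(target_p_diabetes = 0.9,
                                        target_p_prediabetes = 0.9)),
               "infeasible|calibrate")
})

test_that("configuration YAML round-trips through the constructor", {
  cfg <- cohort_config(n = 1234, men = list(beta = log(c(2, 2, 3))))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back$n, 1234)
  expect_equal(back$men$beta, cfg$men$beta)
  expect_equal(back$men$b0, cfg$men$b0, tolerance = 1e-10)
  c1 <- generate_cohort(cfg, seed = 3)
  c2 <- generate_cohort(back, seed = 3)
  expect_identical(c1$fasting_glucose, c2$fasting_glucose)
})

test_that("self-report and medication structure matches the configuration", {
  cfg <- cohort_config(n = 60000)
  coh <- generate_cohort(cfg, seed = 37)
  cc <- derive_exposures(coh)
  men_d <- cc[cc$sex == "male" & cc$outcome_class == "diabetes", ]
  sr <- mean(men_d$selfreport_diabetes == "yes")
  expect_lt(abs(sr - cfg$men$p_selfreport_given_d), 0.03)
  med <- mean(men_d$antidiabetic_medication[men_d$selfreport_diabetes == "yes"] == "yes")
  expect_lt(abs(med - cfg$men$p_med_given_selfreport), 0.04)
  # glucose-identified diabetics all have glucose >= 7
  gi <- men_d[men_d$selfreport_diabetes == "no", ]
  expect_true(all(gi$fasting_glucose >= 7.0))
})
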