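test_that("joint indicator coding enumerates the four exposure cells", {
  jc <- joint_indicator_coding(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_identical(jc$i10, c(0L, 1L, 0L, 0L))
  expect_identical(jc$i01, c(0L, 0L, 1L, 0L))
  expect_identical(jc$i11, c(0L, 0L, 0L, 1L))
  expect_true(all(jc$i10 + jc$i01 + jc$i11 <= 1))

  set.seed(9)
  a <- rbinom(500, 1, 0.3); b <- rbinom(500, 1, 0.4)
  jc <- joint_indicator_coding(a, b)
  expect_identical(sum(jc$i10), sum(a == 1 & b == 0))
  expect_identical(sum(jc$i01), sum(a == 0 & b == 1))
  expect_identical(sum(jc$i11), sum(a == 1 & b == 1))

  a[1] <- NA
  expect_identical(attr(joint_indicator_coding(a, b), "n_dropped"), 1L)
})

test_that("synergy index reproduces worked examples and degenerate statuses", {
  # obesity-by-history odds ratios: strong super-additivity
  s <- synergy_index_from_ors(9.1, 3.4, 2.0)
  expect_identical(s$status, "ok")
  expect_equal(s$s, 8.1 / 3.4)
  expect_equal(round_half_away(s$s, 1), 2.4)

  # exact additivity: or11 = or10 + or01 - 1 gives S = 1
  expect_equal(synergy_index_from_ors(3.0, 2.0, 2.0)$s, 1.0)

  # protective joint odds ratio: no synergy index is reported
  expect_identical(synergy_index_from_ors(0.8, 2.3, 1.7)$status, "no_result")

  # sub-additivity with a protective single exposure
  expect_equal(synergy_index_from_ors(1.7, 0.9, 2.5)$s, 0.5)

  # null odds ratios: numerator non-positive
  expect_identical(synergy_index_from_ors(1, 1, 1)$status, "no_result")

  # antagonistic denominator with a harmful joint effect
  expect_identical(synergy_index_from_ors(1.5, 0.7, 0.8)$status,
                   "undefined_antagonism_denominator")
})

test_that("RERI and AP follow from the three odds ratios", {
  ra <- reri_ap_from_ors(9.1, 3.4, 2.0)
  expect_equal(ra$reri, 4.7)
  expect_equal(ra$ap, 4.7 / 9.1)
  expect_equal(reri_ap_from_ors(3.0, 2.0, 2.0)$reri, 0)
  expect_equal(reri_ap_from_ors(3.0, 2.0, 2.0)$ap, 0)
  expect_equal(reri_ap_from_ors(1, 1, 1)$reri, 0)
})

test_that("fitted interaction results are internally consistent", {
  cc <- derive_exposures(generate_cohort(cohort_config(n = 20000), seed = 51))
  r <- interaction_analysis(cc, "bmi_gt30", "phd", sex = "male")
  expect_identical(r$status, "ok")
  # S recomputed from the fitted odds ratios is the reported S, exactly
  expect_identical(r$s, synergy_index_from_ors(r$or11$or, r$or10$or, r$or01$or)$s)
  # RERI and AP identities hold exactly
  expect_equal(r$reri, r$or11$or - r$or10$or - r$or01$or + 1)
  expect_equal(r$ap, r$reri / r$or11$or)
  expect_true(r$s_ci[1] <= r$s && r$s <= r$s_ci[2])
  # sign coherence between RERI and S
  expect_true((r$reri > 0) == (r$s > 1))
  # cell case counts reconcile with the analysis set
  expect_identical(unname(sum(r$cells)),
                   sum(cc$outcome_class == "diabetes" & cc$sex == "male" &
                         !is.na(cc$bmi_gt30) & !is.na(cc$phd)))
})

test_that("interaction measures are symmetric in the two exposures", {
  cc <- derive_exposures(generate_cohort(cohort_config(n = 15000), seed = 52))
  r1 <- interaction_analysis(cc, "bmi_gt30", "phd", sex = "male")
  r2 <- interaction_analysis(cc, "phd", "bmi_gt30", sex = "male")
  expect_equal(r1$s, r2$s, tolerance = 1e-8)
  expect_equal(r1$reri, r2$reri, tolerance = 1e-8)
  expect_equal(r1$ap, r2$ap, tolerance = 1e-8)
  expect_equal(r1$se_lns, r2$se_lns, tolerance = 1e-6)
})

test_that("delta-method interval narrows like n^(-1/2)", {
  widths <- sapply(c(5000, 80000), function(n) {
    cfg <- cohort_config(n = n, male_frac = 1)
    cc <- derive_exposures(generate_cohort(cfg, seed = 53))
    interaction_analysis(cc, "bmi_gt30", "phd", sex = "male")$se_lns
  })
  expect_equal(widths[1] / widths[2], 4, tolerance = 0.30)
})

test_that("adjustment for independent covariates leaves S essentially unchanged", {
  cfg <- cohort_config(n = 50000, male_frac = 1)
  cc <- derive_exposures(generate_cohort(cfg, seed = 54))
  r0 <- interaction_analysis(cc, "bmi_gt30", "phd", sex = "male")
  r1 <- interaction_analysis(cc, "bmi_gt30", "phd", sex = "male",
                             covariates = c("smoking", "leisure_inactive",
                                            "work_inactive"))
  expect_lt(abs(log(r1$s) - log(r0$s)), 0.75 * r0$se_lns)
})

test_that("bootstrap interval broadly agrees with the delta interval", {
  cfg <- cohort_config(n = 8000, male_frac = 1)
  cc <- derive_exposures(generate_cohort(cfg, seed = 55))
  rd <- interaction_analysis(cc, "bmi_gt30", "phd", sex = "male")
  rb <- interaction_analysis(cc, "bmi_gt30", "phd", sex = "male",
                             ci_method = "bootstrap", boot_b = 200,
                             boot_seed = 99)
  expect_identical(rb$s, rd$s)  # point estimate unaffected
  # intervals overlap substantially
  expect_lt(rb$s_ci[1], rd$s_ci[2])
  expect_lt(rd$s_ci[1], rb$s_ci[2])
  # bootstrap is reproducible under its seed
  rb2 <- interaction_analysis(cc, "bmi_gt30", "phd", sex = "male",
                              ci_method = "bootstrap", boot_b = 200,
                              boot_seed = 99)
  expect_identical(rb$s_ci, rb2$s_ci)
})
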