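test_that("outcome classification honours the glucose thresholds and criteria", {
  # three-way diabetes definition: self-report, glucose >= 7.0, medication
  expect_identical(classify_outcome("yes", 5.0, "no"), "diabetes")
  expect_identical(classify_outcome("no", 5.0, "yes"), "diabetes")
  expect_identical(classify_outcome("blank", NA, "yes"), "diabetes")
  # boundary cases at 6.0 / 6.1 / 6.9 / 7.0 mmol/l
  expect_identical(classify_outcome("no", c(6.0, 6.1, 6.9, 7.0), "no"),
                   c("reference", "prediabetes", "prediabetes", "diabetes"))
  # unrounded values inside (6.9, 7.0) stay in the impaired band
  expect_identical(classify_outcome("no", 6.95, "no"), "prediabetes")
  # unclassifiable: no glucose and no diabetes indication
  expect_identical(classify_outcome("blank", NA, "no"), "excluded")
  expect_identical(classify_outcome("no", NA, "no"), "excluded")
})

test_that("classification partitions any cohort and is monotone in glucose", {
  set.seed(404)
  n <- 2000
  sr <- sample(c("yes", "no", "blank"), n, TRUE, prob = c(0.05, 0.9, 0.05))
  glu <- ifelse(runif(n) < 0.05, NA, round(runif(n, 3.5, 12), 1))
  med <- sample(c("yes", "no"), n, TRUE, prob = c(0.03, 0.97))
  cls <- classify_outcome(sr, glu, med)
  expect_true(all(cls %in% c("diabetes", "prediabetes", "reference", "excluded")))
  expect_length(cls, n)  # exactly one class per record

  rank_of <- function(x) match(x, c("excluded", "reference", "prediabetes", "diabetes"))
  bumped <- classify_outcome(sr, glu + 0.5, med)
  keep <- !is.na(glu)
  expect_true(all(rank_of(bumped[keep]) >= rank_of(cls[keep])))

  # purity: same inputs, same answer
  expect_identical(cls, classify_outcome(sr, glu, med))
})

test_that("BMI derivation is exact and propagates missingness", {
  expect_equal(derive_bmi(180, 81), 25)
  expect_equal(derive_bmi(100, 30), 30)
  expect_true(is.na(derive_bmi(NA, 81)))
  expect_error(derive_bmi(-180, 81), "positive")
})

test_that("percentile cut-offs use type-7 interpolation and flag strictly above", {
  # order-statistic oracle for 1..100 at q = 0.9: h = 1 + 99 * 0.9 = 90.1,
  # cut-off = x[90] + 0.1 * (x[91] - x[90]) = 90.1
  vals <- c(1:100, 1:100)
  sex <- rep(c("male", "female"), each = 100)
  cut <- percentile_cutoff(vals, sex, q = 0.90)
  expect_equal(cut$male, 90.1)
  expect_equal(cut$female, 90.1)

  # degenerate constant vector: cut-off equals the constant, nobody "high"
  cutc <- percentile_cutoff(rep(7, 20), rep("male", 20))
  expect_equal(cutc$male, 7)
  cc <- derive_exposures(make_cohort(sad = rep(7, 20), n = 20))
  expect_true(all(cc$high_sad == 0L))

  expect_error(percentile_cutoff(1:5, rep("male", 5)), "male")
})

test_that("exposure panel encodes history, smoking, inactivity and BMI flags", {
  coh <- make_cohort(
    mother_diabetes = c("yes", "no", "yes", "no"),
    father_diabetes = c("no", "yes", "yes", "no"),
    sibling_diabetes = c("no", "no", "no", "yes"),
    smoking = c("current", "ex", "never", NA),
    leisure_pa = c(1L, 2L, NA, 4L),
    work_sedentary = c(1L, 3L, 2L, NA),
    weight = c(81.1, 97.2, 120, 64.8),  # bmi 25.03, 30, 37, 20 at 180 cm
    sad = rnorm(4, 21, 2)
  )
  fixed_cuts <- list(sad = list(male = 25.0), waist = list(male = 111),
                     whr = list(male = 1.03), bmi = list(male = 31.7))
  cc <- derive_exposures(coh, cutoffs = fixed_cuts)
  expect_identical(cc$phd, c(1L, 1L, 1L, 0L))
  expect_identical(cc$maternal_history, c(1L, 0L, 1L, 0L))
  expect_identical(cc$maternal_eligible, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(cc$paternal_eligible, c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(cc$biparental_history, c(0L, 0L, 1L, 0L))
  expect_identical(cc$family_history, c(1L, 1L, 1L, 1L))
  expect_identical(cc$current_smoker, c(1L, 0L, 0L, NA_integer_))
  expect_identical(cc$ex_smoker, c(0L, 1L, 0L, NA_integer_))
  expect_identical(cc$leisure_inactive, c(1L, 0L, NA_integer_, 0L))
  expect_identical(cc$work_inactive, c(1L, 0L, 0L, NA_integer_))
  # strict ">" at both BMI cut-offs: bmi of exactly 30 is not obesity
  expect_identical(cc$bmi_gt25, c(1L, 1L, 1L, 0L))
  expect_identical(cc$bmi_gt30, c(0L, 0L, 1L, 0L))
})

test_that("obesity implies overweight on arbitrary generated cohorts", {
  cc <- derive_exposures(generate_cohort(cohort_config(n = 3000), seed = 21))
  expect_true(all(cc$bmi_gt25[cc$bmi_gt30 == 1L] == 1L))
  expect_true(all(cc$biparental_history <= cc$phd))
  expect_true(all(cc$phd <= cc$family_history))
  # maternal analyses never include a reported paternal history
  expect_true(all(cc$paternal_history[cc$maternal_eligible] == 0L))
})

test_that("synthetic adiposity cut-offs sit near their calibration targets", {
  cc <- derive_exposures(generate_cohort(paper_default_config(20000), seed = 2))
  cuts <- attr(cc, "cutoffs")
  expect_equal(cuts$sad$male, 25.0, tolerance = 0.04)    # cm, relative tol
  expect_equal(cuts$sad$female, 23.5, tolerance = 0.04)
  expect_equal(cuts$waist$male, 111, tolerance = 0.04)
  expect_equal(cuts$waist$female, 102, tolerance = 0.04)
  expect_equal(cuts$bmi$male, 31.7, tolerance = 0.04)
})
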