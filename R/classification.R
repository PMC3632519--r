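# Outcome and exposure classification.
#
# All rules are pure, vectorised functions of the raw record. The outcome is a
# partition of the cohort into diabetes / prediabetes / reference / excluded;
# exposures are binary flags with missingness propagated from the raw fields.

OUTCOME_LEVELS <- c("diabetes", "prediabetes", "reference", "excluded")

#' Classify the study outcome
#'
#' A participant is classified as `diabetes` if any of three criteria holds:
#' self-reported diabetes, fasting glucose >= 7.0 mmol/l, or use of
#' antidiabetic medication. Otherwise `prediabetes` (impaired fasting
#' glucose) if fasting glucose lies in the band 6.1-6.9 mmol/l, implemented
#' as the half-open interval \[6.1, 7.0) so that unrounded values in
#' (6.9, 7.0) are not left unclassified; otherwise `reference` when a glucose
#' value is present. Participants with no glucose value who meet no diabetes
#' criterion cannot be classified and are `excluded`.
#'
#' @param selfreport_diabetes Character, one of `"yes"`, `"no"`, `"blank"`.
#' @param fasting_glucose Numeric, fasting glucose in mmol/l (NA if missing).
#' @param antidiabetic_medication Character, `"yes"` or `"no"`.
#' @return Character vector over `diabetes`, `prediabetes`, `reference`,
#'   `excluded`; always a total function of its inputs.
#' @export
#' @examples
#' classify_outcome("yes", 5.0, "no")       # diabetes by self-report
#' classify_outcome("no", c(6.0, 6.1, 6.9, 7.0), "no")
#' classify_outcome("blank", NA, "no")      # excluded
classify_outcome <- function(selfreport_diabetes, fasting_glucose,
                             antidiabetic_medication) {
  n <- max(length(selfreport_diabetes), length(fasting_glucose),
           length(antidiabetic_medication))
  sr <- rep_len(selfreport_diabetes, n)
  glu <- rep_len(fasting_glucose, n)
  med <- rep_len(antidiabetic_medication, n)
  diab <- (!is.na(sr) & sr == "yes") |
    (!is.na(glu) & glu >= 7.0) |
    (!is.na(med) & med == "yes")
  pre <- !diab & !is.na(glu) & glu >= 6.1 & glu < 7.0
  ref <- !diab & !pre & !is.na(glu)
  out <- rep("excluded", n)
  out[diab] <- "diabetes"
  out[pre] <- "prediabetes"
  out[ref] <- "reference"
  out
}

#' Body mass index from height and weight
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @return BMI in kg/m^2; NA where either input is missing.
#' @export
#' @examples
#' derive_bmi(180, 81)  # 25
derive_bmi <- function(height_cm, weight_kg) {
  bad <- !is.na(height_cm) & height_cm <= 0 |
    !is.na(weight_kg) & weight_kg <= 0
  if (any(bad)) stop("height and weight must be strictly positive", call. = FALSE)
  weight_kg / (height_cm / 100)^2
}

#' Sex-specific percentile cut-off
#'
#' Computes per-sex cut-offs at fraction `q` of the distribution of a
#' measurement, by linear interpolation between order statistics (the
#' standard type-7 sample quantile). A record is flagged "high" when its
#' value lies strictly above its sex's cut-off.
#'
#' @param values Numeric measurements (NA allowed).
#' @param sex Character vector (`"male"`/`"female"`) parallel to `values`.
#' @param q Fraction in (0, 1); default 0.90.
#' @param groups Sexes to compute cut-offs for; defaults to those present.
#' @return Named list with one numeric cut-off per group.
#' @export
#' @examples
#' percentile_cutoff(1:100, rep(c("male", "female"), 50))
percentile_cutoff <- function(values, sex, q = 0.90,
                              groups = intersect(c("male", "female"),
                                                 unique(sex))) {
  stopifnot(q > 0, q < 1)
  lapply(stats::setNames(groups, groups), function(s) {
    v <- values[!is.na(values) & sex == s]
    if (length(v) < 10) {
      stop(sprintf("fewer than 10 non-missing values for group '%s'", s),
           call. = FALSE)
    }
    unname(stats::quantile(v, q, type = 7))
  })
}

flag_high <- function(values, sex, cutoff) {
  cut <- ifelse(sex == "male", cutoff$male %||% NA_real_,
                cutoff$female %||% NA_real_)
  as.integer(values > cut)
}

#' Derive the exposure panel for a classified analysis
#'
#' Adds to the cohort the study outcome, derived continuous measures (BMI,
#' waist-to-hip ratio) and every dichotomous exposure: parental history of
#' diabetes (either parent), maternal/paternal history with their
#' eligibility flags (a paternal analysis excludes participants reporting a
#' diabetic mother, and vice versa), biparental history, family history
#' (parent or sibling), current smoking (ex- and never-smokers form the
#' reference), leisure-time and at-work physical inactivity (most sedentary
#' of four ordinal levels), BMI > 25 and BMI > 30, and "high" flags at
#' sex-specific 90th-percentile cut-offs of SAD, waist circumference, WHR
#' and BMI. Missing raw fields propagate to missing flags.
#'
#' @param cohort A `cohort`.
#' @param cutoffs Optional list of per-sex cut-off sets with elements `sad`,
#'   `waist`, `whr`, `bmi` (each a list with `male` and `female`). When NULL
#'   (default) they are computed from this cohort at `q`.
#' @param q Percentile fraction for the adiposity cut-offs (default 0.90).
#' @return A `classified_cohort`: the input tibble plus outcome and exposure
#'   columns, with the cut-off set in `attr(x, "cutoffs")`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 500), seed = 1)
#' cc <- derive_exposures(coh)
#' table(cc$outcome_class, cc$sex)
derive_exposures <- function(cohort, cutoffs = NULL, q = 0.90) {
  stopifnot(inherits(cohort, "cohort"))
  x <- tibble::as_tibble(as.data.frame(cohort))
  x$outcome_class <- classify_outcome(x$selfreport_diabetes, x$fasting_glucose,
                                      x$antidiabetic_medication)
  x$bmi <- derive_bmi(x$height, x$weight)
  x$whr <- x$waist / x$hip

  # "yes"/"no" to 0/1; NA propagates
  yn <- function(v) ifelse(is.na(v), NA_integer_, as.integer(v == "yes"))
  # logical OR over 0/1 flags where a known 1 dominates an NA
  or01 <- function(a, b) {
    out <- pmax(a, b, na.rm = TRUE)
    out[is.na(a) & is.na(b)] <- NA_integer_
    as.integer(out)
  }
  mo <- yn(x$mother_diabetes); fa <- yn(x$father_diabetes)
  x$phd <- or01(mo, fa)
  x$maternal_history <- mo
  x$maternal_eligible <- is.na(fa) | fa == 0L
  x$paternal_history <- fa
  x$paternal_eligible <- is.na(mo) | mo == 0L
  x$biparental_history <- as.integer(mo & fa)
  x$family_history <- or01(x$phd, yn(x$sibling_diabetes))

  x$current_smoker <- ifelse(is.na(x$smoking), NA_integer_,
                             as.integer(x$smoking == "current"))
  x$ex_smoker <- ifelse(is.na(x$smoking), NA_integer_,
                        as.integer(x$smoking == "ex"))
  x$leisure_inactive <- ifelse(is.na(x$leisure_pa), NA_integer_,
                               as.integer(x$leisure_pa == 1L))
  x$work_inactive <- ifelse(is.na(x$work_sedentary), NA_integer_,
                            as.integer(x$work_sedentary == 1L))

  x$bmi_gt25 <- ifelse(is.na(x$bmi), NA_integer_, as.integer(x$bmi > 25))
  x$bmi_gt30 <- ifelse(is.na(x$bmi), NA_integer_, as.integer(x$bmi > 30))

  if (is.null(cutoffs)) {
    cutoffs <- list(
      sad = percentile_cutoff(x$sad, x$sex, q),
      waist = percentile_cutoff(x$waist, x$sex, q),
      whr = percentile_cutoff(x$whr, x$sex, q),
      bmi = percentile_cutoff(x$bmi, x$sex, q)
    )
  }
  x$high_sad <- flag_high(x$sad, x$sex, cutoffs$sad)
  x$high_waist <- flag_high(x$waist, x$sex, cutoffs$waist)
  x$high_whr <- flag_high(x$whr, x$sex, cutoffs$whr)
  x$high_bmi_p90 <- flag_high(x$bmi, x$sex, cutoffs$bmi)

  out <- structure(x, class = c("classified_cohort", class(tibble::tibble())))
  attr(out, "provenance") <- attr(cohort, "provenance")
  attr(out, "cutoffs") <- cutoffs
  out
}
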