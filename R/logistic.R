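# Prevalence odds ratios by maximum-likelihood logistic regression.
#
# Model fitting is delegated to stats::glm.fit (IRLS) with a tightened
# convergence tolerance; this module adds the coefficient covariance from the
# observed information at the MLE, explicit separation detection, the
# closed-form 2x2 oracle, and the analysis-set construction (cases vs the
# reference outcome class, complete cases, eligibility filters).

#' Fit a logistic regression by IRLS
#'
#' Maximum-likelihood fit of `P(y = 1 | x) = expit(x beta)` with coefficient
#' covariance equal to the inverse observed information at the MLE.
#' Complete or quasi-complete separation is reported as an error (detected
#' as a diverging coefficient, |beta| > 15 on the log-odds scale) rather
#' than returned as a silently huge odds ratio.
#'
#' @param x Numeric design matrix, n x p, including the intercept column.
#' @param y Binary outcome vector (0/1) of length n, both classes present.
#' @return A `logistic_fit`: list with `coef`, `vcov`, `loglik`, `converged`,
#'   `n`.
#' @export
#' @examples
#' x <- cbind(1, c(rep(1, 100), rep(0, 100)))
#' y <- c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95))
#' fit_logistic(x, y)$coef
fit_logistic <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("design and outcome must be complete", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (nrow(x) <= ncol(x)) stop("need more observations than parameters", call. = FALSE)
  if (length(unique(y)) < 2) stop("outcome has a single class", call. = FALSE)

  fit <- suppressWarnings(stats::glm.fit(
    x, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 50)
  ))
  beta <- fit$coefficients
  if (anyNA(beta)) stop("design matrix is rank deficient", call. = FALSE)
  if (any(abs(beta) > 15)) {
    stop("separation detected: a coefficient diverged beyond |beta| > 15; ",
         "the data cannot identify a finite odds ratio", call. = FALSE)
  }
  mu <- expit(drop(x %*% beta))
  info <- crossprod(x, x * (mu * (1 - mu)))
  vcov <- solve(info)
  vcov <- (vcov + t(vcov)) / 2
  structure(
    list(coef = beta, vcov = vcov,
         loglik = sum(y * log(mu) + (1 - y) * log1p(-mu)),
         converged = fit$converged, n = nrow(x)),
    class = "logistic_fit"
  )
}

new_or_result <- function(or, ci_low, ci_high, beta, se, counts = NULL,
                          n = NA_integer_) {
  structure(list(or = or, ci_low = ci_low, ci_high = ci_high, beta = beta,
                 se = se, counts = counts, n = n),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), beta %.4f, SE %.4f, n = %s\n",
              x$or, x$ci_low, x$ci_high, x$beta, x$se,
              ifelse(is.na(x$n), "?", x$n)))
  invisible(x)
}

#' Closed-form odds ratio for a 2x2 table
#'
#' Cross-product odds ratio `ad/(bc)` with Woolf's standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` on the log scale and a 95% Wald interval.
#' Serves as the analytic oracle for a single-binary-covariate logistic fit,
#' whose MLE coincides with the cross-product ratio.
#'
#' @param a,b,c,d Cell counts: exposed cases, exposed non-cases, unexposed
#'   cases, unexposed non-cases. All must be positive; no continuity
#'   correction is applied.
#' @return An `or_result`.
#' @export
#' @examples
#' odds_ratio_2x2(10, 90, 5, 95)
odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (any(cells == 0)) {
    stop("zero cell in 2x2 table (", paste(names(cells)[cells == 0], collapse = ", "),
         "): the odds ratio is not estimable; consider collapsing the exposure ",
         "or reporting the row as degenerate (no continuity correction is applied)",
         call. = FALSE)
  }
  beta <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  new_or_result(exp(beta), exp(beta - Z95 * se), exp(beta + Z95 * se),
                beta, se, counts = cells, n = sum(cells))
}

# Build the case/reference analysis set for one outcome target.
# Cases are the target class; the comparison group is the reference class
# (neither diabetes nor prediabetes); the other outcome class and excluded
# records are dropped.
analysis_set <- function(classified, outcome = c("diabetes", "prediabetes"),
                         sex = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(classified, "classified_cohort"))
  x <- tibble::as_tibble(as.data.frame(classified))
  if (!is.null(sex)) x <- x[x$sex %in% sex, ]
  x <- x[x$outcome_class %in% c(outcome, "reference"), ]
  x$case <- as.integer(x$outcome_class == outcome)
  x
}

# covariate design columns (complete-case handled by the caller)
covariate_columns <- function(data, covariates,
                              bmi_coding = c("continuous", "categories")) {
  bmi_coding <- match.arg(bmi_coding)
  cols <- list()
  for (cv in covariates) {
    if (cv == "smoking") {
      cols$smoker_current <- as.integer(data$smoking == "current")
      cols$smoker_ex <- as.integer(data$smoking == "ex")
    } else if (cv == "bmi") {
      if (bmi_coding == "continuous") {
        cols$bmi <- data$bmi
      } else {
        cols$bmi_gt25 <- data$bmi_gt25
        cols$bmi_gt30 <- data$bmi_gt30
      }
    } else if (cv == "sex") {
      cols$sex_female <- as.integer(data$sex == "female")
    } else if (cv %in% names(data)) {
      cols[[cv]] <- data[[cv]]
    } else {
      stop("unknown covariate: ", cv, call. = FALSE)
    }
  }
  cols
}

#' Estimate a prevalence odds ratio for one exposure
#'
#' Contrasts cases of the target outcome against the reference outcome class
#' (participants with neither diabetes nor prediabetes). The crude estimate
#' (no covariates) on a single binary exposure coincides with the closed-form
#' 2x2 odds ratio. Adjusted models add indicator (dummy) terms for current
#' and ex-smoking (never-smokers the reference), leisure-time and at-work
#' inactivity, BMI (continuous by default, or the >25/>30 indicators), and a
#' sex indicator for both-sex models. Records missing any model term are
#' dropped (complete-case) and counted; maternal/paternal-history analyses
#' additionally drop ineligible records (diabetes reported in the other
#' parent).
#'
#' @param classified A `classified_cohort` from [derive_exposures()].
#' @param exposure Name of a binary exposure column (e.g. `"phd"`,
#'   `"bmi_gt30"`, `"current_smoker"`, `"maternal_history"`).
#' @param outcome `"diabetes"` or `"prediabetes"`.
#' @param covariates Character vector of adjustment terms from
#'   `"smoking"`, `"leisure_inactive"`, `"work_inactive"`, `"bmi"`, `"sex"`;
#'   empty (default) for the crude estimate.
#' @param sex Optional `"male"`/`"female"` restriction.
#' @param bmi_coding `"continuous"` (default) or `"categories"` for the BMI
#'   adjustment term.
#' @return An `or_result` for the exposure; `$dropped` holds the counts of
#'   records removed as incomplete or ineligible.
#' @export
#' @examples
#' cc <- derive_exposures(generate_cohort(cohort_config(n = 4000), seed = 7))
#' estimate_or(cc, "phd", "diabetes", sex = "male")
estimate_or <- function(classified, exposure, outcome = "diabetes",
                        covariates = character(), sex = NULL,
                        bmi_coding = "continuous") {
  data <- analysis_set(classified, outcome, sex)
  n0 <- nrow(data)
  n_inelig <- 0L
  if (exposure == "maternal_history") {
    n_inelig <- sum(!data$maternal_eligible)
    data <- data[data$maternal_eligible, ]
  } else if (exposure == "paternal_history") {
    n_inelig <- sum(!data$paternal_eligible)
    data <- data[data$paternal_eligible, ]
  }
  cols <- c(list(exposure = data[[exposure]]),
            covariate_columns(data, covariates, bmi_coding))
  keep <- stats::complete.cases(as.data.frame(cols))
  n_incomplete <- sum(!keep)
  data <- data[keep, ]
  cols <- lapply(cols, function(v) v[keep])
  if (nrow(data) == 0) stop("analysis set is empty", call. = FALSE)
  x <- cbind(`(intercept)` = rep(1, nrow(data)), do.call(cbind, cols))
  fit <- fit_logistic(x, data$case)
  beta <- fit$coef[["exposure"]]
  se <- sqrt(fit$vcov["exposure", "exposure"])
  counts <- NULL
  if (all(data[[exposure]] %in% c(0, 1))) {
    counts <- c(a = sum(data$case == 1 & data[[exposure]] == 1),
                b = sum(data$case == 0 & data[[exposure]] == 1),
                c = sum(data$case == 1 & data[[exposure]] == 0),
                d = sum(data$case == 0 & data[[exposure]] == 0))
  }
  out <- new_or_result(exp(beta), exp(beta - Z95 * se), exp(beta + Z95 * se),
                       beta, se, counts, n = nrow(data))
  out$dropped <- c(ineligible = n_inelig, incomplete = n_incomplete,
                   analysed = nrow(data), entered = n0)
  out$fit <- fit
  out
}
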