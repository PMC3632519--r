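# Additive interaction between two binary exposures on the odds-ratio scale.
#
# The joint exposure is coded with three indicators against the doubly
# unexposed reference; departure from additivity is summarised by Rothman's
# synergy index S = (OR11 - 1) / ((OR10 - 1) + (OR01 - 1)), the relative
# excess risk due to interaction RERI = OR11 - OR10 - OR01 + 1, and the
# attributable proportion AP = RERI / OR11. Confidence intervals propagate
# the fitted coefficient covariance by the delta method (on ln S for S); a
# seeded percentile bootstrap is available as a cross-check.

#' Joint indicator coding of two binary exposures
#'
#' Codes the four exposure cells as three indicators `i10` (A only), `i01`
#' (B only) and `i11` (both), the doubly unexposed cell being the all-zero
#' reference. Records with either exposure missing are dropped and counted.
#'
#' @param a,b Binary (0/1) exposure vectors of equal length; NA allowed.
#' @return Tibble with integer columns `i10`, `i01`, `i11` and the attribute
#'   `n_dropped` (records removed for a missing exposure).
#' @export
#' @examples
#' joint_indicator_coding(c(0, 1, 0, 1), c(0, 0, 1, 1))
joint_indicator_coding <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  stopifnot(all(a %in% 0:1), all(b %in% 0:1))
  out <- tibble::tibble(
    i10 = as.integer(a == 1 & b == 0),
    i01 = as.integer(a == 0 & b == 1),
    i11 = as.integer(a == 1 & b == 1)
  )
  attr(out, "keep") <- keep
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Synergy index from three odds ratios
#'
#' `S = (or11 - 1) / ((or10 - 1) + (or01 - 1))`, where `or11` is the odds
#' ratio for the doubly exposed and `or10`, `or01` those for each single
#' exposure, all against the doubly unexposed reference. S > 1 indicates
#' synergy (super-additivity of odds-ratio effects), S < 1 antagonism.
#' When `or11 <= 1` the numerator is non-positive and no synergy index is
#' reported (`status = "no_result"`); when the denominator is non-positive
#' while `or11 > 1` the index is undefined
#' (`status = "undefined_antagonism_denominator"`).
#'
#' @param or11,or10,or01 Positive odds ratios.
#' @return List with `s` (NA unless `status == "ok"`) and `status`.
#' @export
#' @examples
#' synergy_index_from_ors(9.1, 3.4, 2.0)  # s approx 2.38
#' synergy_index_from_ors(0.8, 2.3, 1.7)  # no_result
synergy_index_from_ors <- function(or11, or10, or01) {
  stopifnot(or11 > 0, or10 > 0, or01 > 0)
  if (or11 <= 1) {
    return(list(s = NA_real_, status = "no_result"))
  }
  denom <- (or10 - 1) + (or01 - 1)
  if (denom <= 0) {
    return(list(s = NA_real_, status = "undefined_antagonism_denominator"))
  }
  list(s = (or11 - 1) / denom, status = "ok")
}

#' RERI and attributable proportion from three odds ratios
#'
#' `RERI = or11 - or10 - or01 + 1` (zero under exact additivity) and
#' `AP = RERI / or11`, the proportion of the doubly-exposed odds ratio
#' attributable to interaction.
#'
#' @inheritParams synergy_index_from_ors
#' @return List with `reri` and `ap`.
#' @export
#' @examples
#' reri_ap_from_ors(9.1, 3.4, 2.0)  # reri 4.7, ap approx 0.516
reri_ap_from_ors <- function(or11, or10, or01) {
  stopifnot(or11 > 0, or10 > 0, or01 > 0)
  reri <- or11 - or10 - or01 + 1
  list(reri = reri, ap = reri / or11)
}

# delta-method variances of ln S, RERI and AP from the (b10, b01, b11)
# coefficient vector and its 3x3 covariance
interaction_delta <- function(beta, V) {
  e10 <- exp(beta[1]); e01 <- exp(beta[2]); e11 <- exp(beta[3])
  denom <- e10 + e01 - 2
  grad_lns <- c(-e10 / denom, -e01 / denom, e11 / (e11 - 1))
  grad_reri <- c(-e10, -e01, e11)
  # AP = 1 - (e10 + e01 - 1)/e11
  grad_ap <- c(-e10 / e11, -e01 / e11, (e10 + e01 - 1) / e11)
  list(se_lns = sqrt(drop(t(grad_lns) %*% V %*% grad_lns)),
       se_reri = sqrt(drop(t(grad_reri) %*% V %*% grad_reri)),
       se_ap = sqrt(drop(t(grad_ap) %*% V %*% grad_ap)))
}

#' Additive-interaction analysis of two exposures
#'
#' Fits a single logistic model of the target outcome (cases vs the
#' reference outcome class) on the three joint-exposure indicators plus any
#' adjustment terms, and derives the three odds ratios, the synergy index S,
#' RERI and AP with 95% confidence intervals. The S interval is a delta
#' method interval on ln S using the fitted coefficient covariance,
#' exponentiated back; RERI and AP intervals are delta-method Wald intervals
#' on their own scales. With sparse double-exposure cells these intervals
#' are honest but wide. A percentile bootstrap (resampling analysis rows,
#' refitting, seeded) can be requested as a cross-check.
#'
#' @inheritParams estimate_or
#' @param exposure_a,exposure_b Names of binary exposure columns.
#' @param ci_method `"delta"` (default) or `"bootstrap"`.
#' @param boot_b Number of bootstrap replicates (when
#'   `ci_method = "bootstrap"`).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return An `interaction_result`: list with `or10`, `or01`, `or11`
#'   (`or_result`s), `s`, `s_ci`, `reri`, `reri_ci`, `ap`, `ap_ci`,
#'   `status`, `cells` (case counts in the four exposure cells), `n`,
#'   `dropped`.
#' @export
#' @examples
#' cc <- derive_exposures(generate_cohort(cohort_config(n = 20000), seed = 3))
#' interaction_analysis(cc, "bmi_gt30", "phd", sex = "male")
interaction_analysis <- function(classified, exposure_a, exposure_b,
                                 outcome = "diabetes",
                                 covariates = character(), sex = NULL,
                                 bmi_coding = "continuous",
                                 ci_method = c("delta", "bootstrap"),
                                 boot_b = 1000, boot_seed = 1) {
  ci_method <- match.arg(ci_method)
  data <- analysis_set(classified, outcome, sex)
  n0 <- nrow(data)
  jc <- joint_indicator_coding(data[[exposure_a]], data[[exposure_b]])
  data <- data[attr(jc, "keep"), ]
  cols <- c(as.list(jc), covariate_columns(data, covariates, bmi_coding))
  keep <- stats::complete.cases(as.data.frame(cols))
  data <- data[keep, ]
  cols <- lapply(cols, function(v) v[keep])
  if (nrow(data) == 0) stop("analysis set is empty", call. = FALSE)
  x <- cbind(`(intercept)` = rep(1, nrow(data)), do.call(cbind, cols))

  cell <- 1L + cols$i10 + 2L * cols$i01 + 3L * cols$i11
  cells <- vapply(1:4, function(k) sum(data$case == 1 & cell == k), 0L)
  names(cells) <- c("neither", "a_only", "b_only", "both")

  fit <- fit_logistic(x, data$case)
  idx <- c("i10", "i01", "i11")
  beta <- fit$coef[idx]
  V <- fit$vcov[idx, idx]
  or_of <- function(j) {
    se <- sqrt(V[j, j])
    new_or_result(exp(beta[j]), exp(beta[j] - Z95 * se),
                  exp(beta[j] + Z95 * se), beta[j], se, n = nrow(data))
  }
  or10 <- or_of(1); or01 <- or_of(2); or11 <- or_of(3)

  syn <- synergy_index_from_ors(or11$or, or10$or, or01$or)
  ra <- reri_ap_from_ors(or11$or, or10$or, or01$or)
  dl <- interaction_delta(beta, V)
  s_ci <- c(NA_real_, NA_real_)
  if (syn$status == "ok") {
    if (ci_method == "delta") {
      lns <- log(syn$s)
      s_ci <- exp(c(lns - Z95 * dl$se_lns, lns + Z95 * dl$se_lns))
    } else {
      s_ci <- bootstrap_s_ci(x, data$case, boot_b, boot_seed)
    }
  }
  res <- list(
    or10 = or10, or01 = or01, or11 = or11,
    s = syn$s, s_ci = s_ci, status = syn$status,
    reri = ra$reri,
    reri_ci = c(ra$reri - Z95 * dl$se_reri, ra$reri + Z95 * dl$se_reri),
    ap = ra$ap,
    ap_ci = c(ra$ap - Z95 * dl$se_ap, ra$ap + Z95 * dl$se_ap),
    se_lns = dl$se_lns,
    cells = cells, n = nrow(data),
    dropped = c(missing_exposure = attr(jc, "n_dropped"),
                incomplete = sum(!keep), entered = n0),
    exposure_a = exposure_a, exposure_b = exposure_b, outcome = outcome
  )
  structure(res, class = "interaction_result")
}

# percentile bootstrap for S on a fixed design: resample rows, refit
bootstrap_s_ci <- function(x, y, b, seed) {
  n <- length(y)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  svals <- rep(NA_real_, b)
  for (i in seq_len(b)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(fit_logistic(x[idx, , drop = FALSE], y[idx]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ors <- exp(fit$coef[c("i11", "i10", "i01")])
    syn <- synergy_index_from_ors(ors[1], ors[2], ors[3])
    if (syn$status == "ok") svals[i] <- syn$s
  }
  stats::quantile(svals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("Additive interaction: %s x %s on %s (n = %d)\n",
              x$exposure_a, x$exposure_b, x$outcome, x$n))
  cat(sprintf("  OR10 %.2f (%.2f-%.2f)  OR01 %.2f (%.2f-%.2f)  OR11 %.2f (%.2f-%.2f)\n",
              x$or10$or, x$or10$ci_low, x$or10$ci_high,
              x$or01$or, x$or01$ci_low, x$or01$ci_high,
              x$or11$or, x$or11$ci_low, x$or11$ci_high))
  if (x$status == "ok") {
    cat(sprintf("  S %.2f (95%% CI %.2f-%.2f)   RERI %.2f (%.2f-%.2f)   AP %.2f (%.2f-%.2f)\n",
                x$s, x$s_ci[1], x$s_ci[2], x$reri, x$reri_ci[1], x$reri_ci[2],
                x$ap, x$ap_ci[1], x$ap_ci[2]))
  } else {
    cat("  S: ", x$status, "\n", sep = "")
  }
  cat("  exposed cases: ", paste(names(x$cells), x$cells, sep = "=",
                                 collapse = ", "), "\n", sep = "")
  invisible(x)
}
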