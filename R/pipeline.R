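# End-to-end orchestration: descriptive, odds-ratio and interaction report
# tables, count reconciliation, and a small command-line front end.
#
# Reports are produced at full precision; one-decimal rounding (half away
# from zero) happens only in the human-readable TSV layer, so rounding never
# contaminates downstream computation.

DESCRIPTIVE_VARS <- list(
  categorical = c("phd", "maternal_history", "paternal_history",
                  "current_smoker", "ex_smoker", "leisure_inactive",
                  "work_inactive", "bmi_gt25", "bmi_gt30"),
  normal = c("bmi", "whr", "waist", "sbp", "dbp", "ldl"),
  skewed = c("fasting_glucose", "sad", "insulin", "hdl", "triglycerides")
)

#' Descriptive table by outcome class within sex
#'
#' For each sex and each of the diabetes and prediabetes classes versus the
#' reference class: categorical variables as percentages with a chi-square
#' p-value (no continuity correction), approximately normal continuous
#' variables as mean +/- SD with a two-sample Student t-test p-value, and
#' skewed continuous variables (glucose, insulin, triglycerides, SAD, HDL)
#' as median (IQR) with a Kruskal-Wallis p-value. Missing counts are
#' reported per cell; empty strata yield unavailable (NA) cells rather than
#' an error.
#'
#' @param classified A `classified_cohort`.
#' @return Tibble with columns `sex`, `variable`, `type`, `class`,
#'   `summary`, `value`, `spread`, `n_missing`, `p_vs_reference`.
#' @export
#' @examples
#' cc <- derive_exposures(generate_cohort(cohort_config(n = 3000), seed = 1))
#' descriptive_table(cc)
descriptive_table <- function(classified) {
  stopifnot(inherits(classified, "classified_cohort"))
  x <- tibble::as_tibble(as.data.frame(classified))
  rows <- list()
  for (sx in c("male", "female")) {
    xs <- x[x$sex == sx, ]
    ref <- xs[xs$outcome_class == "reference", ]
    for (cls in c("diabetes", "prediabetes", "reference")) {
      grp <- xs[xs$outcome_class == cls, ]
      for (v in DESCRIPTIVE_VARS$categorical) {
        val <- grp[[v]]
        p <- NA_real_
        if (cls != "reference" && nrow(grp) > 0 && nrow(ref) > 0) {
          tab <- table(factor(c(grp[[v]], ref[[v]]), levels = 0:1),
                       rep(c(cls, "reference"), c(nrow(grp), nrow(ref))))
          if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0)) {
            p <- stats::chisq.test(tab, correct = FALSE)$p.value
          }
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          sex = sx, variable = v, type = "categorical", class = cls,
          summary = "percent",
          value = if (nrow(grp) > 0) 100 * mean(val, na.rm = TRUE) else NA_real_,
          spread = NA_real_, n_missing = sum(is.na(val)), p_vs_reference = p)
      }
      for (v in DESCRIPTIVE_VARS$normal) {
        val <- grp[[v]]
        p <- NA_real_
        if (cls != "reference" && sum(!is.na(val)) > 1 &&
            sum(!is.na(ref[[v]])) > 1 && stats::var(val, na.rm = TRUE) +
            stats::var(ref[[v]], na.rm = TRUE) > 0) {
          p <- stats::t.test(val, ref[[v]], var.equal = TRUE)$p.value
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          sex = sx, variable = v, type = "normal", class = cls,
          summary = "mean_sd",
          value = if (sum(!is.na(val)) > 0) mean(val, na.rm = TRUE) else NA_real_,
          spread = stats::sd(val, na.rm = TRUE),
          n_missing = sum(is.na(val)), p_vs_reference = p)
      }
      for (v in DESCRIPTIVE_VARS$skewed) {
        val <- grp[[v]]
        p <- NA_real_
        if (cls != "reference" && sum(!is.na(val)) > 0 &&
            sum(!is.na(ref[[v]])) > 0) {
          p <- stats::kruskal.test(
            list(val[!is.na(val)], ref[[v]][!is.na(ref[[v]])]))$p.value
        }
        qs <- if (sum(!is.na(val)) > 0) {
          stats::quantile(val, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
        } else c(NA_real_, NA_real_, NA_real_)
        rows[[length(rows) + 1]] <- tibble::tibble(
          sex = sx, variable = v, type = "skewed", class = cls,
          summary = "median_iqr", value = qs[2], spread = qs[3] - qs[1],
          n_missing = sum(is.na(val)), p_vs_reference = p)
      }
    }
  }
  do.call(rbind, rows)
}

TABLE2_EXPOSURES <- c("phd", "paternal_history", "maternal_history",
                      "biparental_history", "family_history")
ADJUSTMENT_SET <- c("smoking", "leisure_inactive", "work_inactive", "bmi")

#' Odds-ratio report table (parental-history exposures)
#'
#' For outcomes diabetes and prediabetes, exposures parental / paternal /
#' maternal / biparental / family history, and strata men, women and both
#' sexes: crude and adjusted prevalence odds ratios against the reference
#' outcome class. Adjusted models include dummy terms for smoking and
#' physical inactivity, BMI, and for both-sex rows a sex indicator.
#' Maternal and paternal rows use the eligibility-filtered analysis sets.
#' A row whose model fails (zero cell, separation) is flagged in `note` and
#' the run continues.
#'
#' @param classified A `classified_cohort`.
#' @param bmi_coding Passed to [estimate_or()].
#' @return Tibble with one row per outcome x exposure x stratum x model.
#' @export
run_table2 <- function(classified, bmi_coding = "continuous") {
  rows <- list()
  for (outc in c("diabetes", "prediabetes")) {
    for (expo in TABLE2_EXPOSURES) {
      for (stratum in c("male", "female", "both")) {
        sex <- if (stratum == "both") NULL else stratum
        for (model in c("crude", "adjusted")) {
          cov <- if (model == "crude") character() else
            c(ADJUSTMENT_SET, if (stratum == "both") "sex")
          res <- tryCatch(
            estimate_or(classified, expo, outc, covariates = cov, sex = sex,
                        bmi_coding = bmi_coding),
            error = function(e) conditionMessage(e))
          if (is.character(res)) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              outcome = outc, exposure = expo, stratum = stratum,
              model = model, or = NA_real_, ci_low = NA_real_,
              ci_high = NA_real_, n = NA_integer_, note = res)
          } else {
            rows[[length(rows) + 1]] <- tibble::tibble(
              outcome = outc, exposure = expo, stratum = stratum,
              model = model, or = res$or, ci_low = res$ci_low,
              ci_high = res$ci_high, n = res$n, note = NA_character_)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

TABLE3_PAIRS <- c("bmi_gt25", "bmi_gt30", "leisure_inactive",
                  "work_inactive", "current_smoker")

#' Interaction report table (synergy of paired exposures)
#'
#' Per sex, for each partner exposure crossed with the history exposure
#' (parental history by default): the four-cell exposed case counts, the
#' three joint-coding odds ratios with 95% CIs, and the synergy index with
#' its delta-method CI and status. Partner exposures default to the BMI
#' cut-offs, physical inactivity and current smoking; pass the
#' 90th-percentile adiposity flags (`high_sad`, `high_waist`, `high_whr`,
#' `high_bmi_p90`) or `family_history` as the history exposure for the
#' companion analyses. A failing pair is flagged and the run continues.
#'
#' @param classified A `classified_cohort`.
#' @param partners Character vector of partner exposures.
#' @param history History exposure (default `"phd"`).
#' @param outcome Outcome target (default `"diabetes"`).
#' @param covariates Optional adjustment terms for every pair.
#' @return Tibble with one row per sex x partner exposure.
#' @export
run_table3 <- function(classified, partners = TABLE3_PAIRS, history = "phd",
                       outcome = "diabetes", covariates = character()) {
  rows <- list()
  for (sx in c("male", "female")) {
    for (expo in partners) {
      res <- tryCatch(
        interaction_analysis(classified, expo, history, outcome = outcome,
                             covariates = covariates, sex = sx),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          sex = sx, exposure = expo, history = history,
          cases_neither = NA_integer_, cases_exposure_only = NA_integer_,
          cases_history_only = NA_integer_, cases_both = NA_integer_,
          or10 = NA_real_, or10_low = NA_real_, or10_high = NA_real_,
          or01 = NA_real_, or01_low = NA_real_, or01_high = NA_real_,
          or11 = NA_real_, or11_low = NA_real_, or11_high = NA_real_,
          s = NA_real_, s_low = NA_real_, s_high = NA_real_,
          status = "error", n = NA_integer_, note = res)
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          sex = sx, exposure = expo, history = history,
          cases_neither = res$cells[["neither"]],
          cases_exposure_only = res$cells[["a_only"]],
          cases_history_only = res$cells[["b_only"]],
          cases_both = res$cells[["both"]],
          or10 = res$or10$or, or10_low = res$or10$ci_low,
          or10_high = res$or10$ci_high,
          or01 = res$or01$or, or01_low = res$or01$ci_low,
          or01_high = res$or01$ci_high,
          or11 = res$or11$or, or11_low = res$or11$ci_low,
          or11_high = res$or11$ci_high,
          s = res$s, s_low = res$s_ci[1], s_high = res$s_ci[2],
          status = res$status, n = res$n, note = NA_character_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Human-readable interaction TSV
#'
#' Formats a [run_table3()] result with one-decimal rounding (half away
#' from zero) and the `"No result"` convention for a non-positive synergy
#' numerator, and writes a UTF-8 tab-separated file.
#'
#' @param table3 Result of [run_table3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table3_tsv <- function(table3, path) {
  r1 <- function(v) ifelse(is.na(v), "", sprintf("%.1f", round_half_away(v, 1)))
  out <- tibble::tibble(
    sex = table3$sex, exposure = table3$exposure, history = table3$history,
    exposed_cases = table3$cases_both,
    or11 = r1(table3$or11),
    or11_ci = ifelse(is.na(table3$or11), "",
                     paste0(r1(table3$or11_low), "-", r1(table3$or11_high))),
    s = ifelse(table3$status == "ok", r1(table3$s),
               ifelse(table3$status == "no_result", "No result", "")),
    s_ci = ifelse(table3$status == "ok",
                  paste0("(", r1(table3$s_low), "-", r1(table3$s_high), ")"), ""),
    status = table3$status
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Run the full analysis and assemble a report
#'
#' Classifies the cohort, produces the descriptive, odds-ratio and
#' interaction tables, and returns them with per-stage record counts that
#' reconcile exactly (classified + excluded = input n).
#'
#' @param cohort A `cohort`.
#' @param tables Which tables to compute (subset of
#'   `c("descriptive", "table2", "table3")`).
#' @return A `run_report` list: `counts`, `cutoffs`, the requested tables,
#'   `provenance`, `version`.
#' @export
#' @examples
#' rep <- run_report(generate_cohort(cohort_config(n = 3000), seed = 1))
#' rep$counts
run_report <- function(cohort, tables = c("descriptive", "table2", "table3")) {
  stopifnot(inherits(cohort, "cohort"))
  cc <- derive_exposures(cohort)
  cls <- table(factor(cc$outcome_class, levels = OUTCOME_LEVELS))
  counts <- c(input = nrow(cohort), as.vector(cls))
  names(counts) <- c("input", OUTCOME_LEVELS)
  stopifnot(sum(cls) == nrow(cohort))
  out <- list(counts = counts,
              cutoffs = attr(cc, "cutoffs"),
              provenance = attr(cohort, "provenance"),
              version = as.character(utils::packageVersion("cohortsynergy")))
  if ("descriptive" %in% tables) out$descriptive <- descriptive_table(cc)
  if ("table2" %in% tables) out$table2 <- run_table2(cc)
  if ("table3" %in% tables) out$table3 <- run_table3(cc)
  structure(out, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$provenance, "\n", sep = "")
  cat("  counts: ", paste(names(x$counts), x$counts, sep = "=",
                          collapse = ", "), "\n", sep = "")
  for (tb in intersect(c("descriptive", "table2", "table3"), names(x))) {
    cat(sprintf("  %s: %d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package functions:
#' `simulate --seed S --out FILE [--n N] [--config FILE.yaml]`,
#' `classify --in FILE --out FILE`, and
#' `analyze --in FILE --out DIR [--tables descriptive,table2,table3]`
#' (writes full-precision JSON and rounded TSV reports). Progress goes to
#' stderr; the return value is the process exit status (0 on success).
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: simulate --seed S --out FILE [--n N] [--config FILE.yaml]",
    "       classify --in FILE --out FILE",
    "       analyze --in FILE --out DIR [--tables descriptive,table2,table3]",
    sep = "\n")
  status <- tryCatch({
    if (length(argv) < 1) stop(usage, call. = FALSE)
    cmd <- argv[1]
    opts <- parse_flags(argv[-1])
    if (cmd == "simulate") {
      cfg <- if (!is.null(opts$config)) read_cohort_config(opts$config)
        else cohort_config(n = as.integer(opts$n %||% 4232))
      coh <- generate_cohort(cfg, seed = as.integer(opts$seed %||% 1))
      write_cohort(coh, opts$out %||% stop("--out required", call. = FALSE))
      message(sprintf("wrote %d records to %s", nrow(coh), opts$out))
    } else if (cmd == "classify") {
      coh <- read_cohort(opts$`in` %||% stop("--in required", call. = FALSE))
      cc <- derive_exposures(coh)
      readr::write_csv(tibble::as_tibble(as.data.frame(cc)),
                       opts$out %||% stop("--out required", call. = FALSE),
                       na = "", progress = FALSE)
      message(sprintf("classified %d records (%s)", nrow(cc),
                      paste(names(table(cc$outcome_class)),
                            table(cc$outcome_class), sep = "=", collapse = ", ")))
    } else if (cmd == "analyze") {
      coh <- read_cohort(opts$`in` %||% stop("--in required", call. = FALSE))
      tables <- strsplit(opts$tables %||% "descriptive,table2,table3", ",")[[1]]
      rep <- run_report(coh, tables = tables)
      dir.create(opts$out %||% stop("--out required", call. = FALSE),
                 showWarnings = FALSE, recursive = TRUE)
      report_json <- rep[intersect(c("counts", "cutoffs", "provenance",
                                     "version", "descriptive", "table2",
                                     "table3"), names(rep))]
      jsonlite::write_json(report_json, file.path(opts$out, "report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      if (!is.null(rep$table3)) {
        write_table3_tsv(rep$table3, file.path(opts$out, "table3.tsv"))
      }
      if (!is.null(rep$table2)) {
        readr::write_tsv(rep$table2, file.path(opts$out, "table2.tsv"),
                         progress = FALSE)
      }
      message("report written to ", opts$out)
    } else {
      stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
    }
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) {
      stop("unexpected argument '", args[i], "'", call. = FALSE)
    }
    key <- substring(args[i], 3)
    if (i + 1 > length(args) || startsWith(args[i + 1], "--")) {
      stop("flag --", key, " needs a value", call. = FALSE)
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}
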