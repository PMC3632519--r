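# Participant-level cohort container and CSV I/O.
#
# A cohort is a tibble with one row per participant and a fixed set of typed
# columns. Missing values are plain NA internally and empty strings in CSV;
# no numeric sentinels are ever used, so per-variable missing counts can be
# reported exactly.

# canonical column order and types
COHORT_CHR <- c("id", "sex", "selfreport_diabetes", "antidiabetic_medication",
                "mother_diabetes", "father_diabetes", "sibling_diabetes",
                "smoking")
COHORT_INT <- c("leisure_pa", "work_sedentary")
COHORT_DBL <- c("fasting_glucose", "height", "weight", "waist", "hip", "sad",
                "insulin", "hdl", "ldl", "triglycerides", "sbp", "dbp")
COHORT_COLS <- c("id", "sex", "selfreport_diabetes", "fasting_glucose",
                 "antidiabetic_medication", "mother_diabetes", "father_diabetes",
                 "sibling_diabetes", "smoking", "leisure_pa", "work_sedentary",
                 "height", "weight", "waist", "hip", "sad",
                 "insulin", "hdl", "ldl", "triglycerides", "sbp", "dbp")
REQUIRED_COLS <- c("id", "sex", "selfreport_diabetes", "fasting_glucose",
                   "antidiabetic_medication", "mother_diabetes",
                   "father_diabetes", "sibling_diabetes", "smoking",
                   "leisure_pa", "work_sedentary", "height", "weight")

ENUMS <- list(
  sex = c("male", "female"),
  selfreport_diabetes = c("yes", "no", "blank"),
  antidiabetic_medication = c("yes", "no"),
  mother_diabetes = c("yes", "no"),
  father_diabetes = c("yes", "no"),
  sibling_diabetes = c("yes", "no"),
  smoking = c("current", "ex", "never")
)

#' Default column codebook for cohort CSV files
#'
#' Maps internal variable names to the column headers expected in a CSV file.
#' Pass a modified copy to [read_cohort()] to adapt an export whose headers
#' differ; unmapped optional variables are simply absent from the cohort.
#'
#' @return Named character vector, `names()` are internal variable names and
#'   values are CSV column headers.
#' @export
#' @examples
#' cb <- cohort_codebook()
#' cb[["fasting_glucose"]] <- "fp_gluc_mmol"
cohort_codebook <- function() {
  stats::setNames(COHORT_COLS, COHORT_COLS)
}

new_cohort <- function(data, provenance = "in-memory") {
  structure(data, class = c("cohort", class(tibble::tibble()))) -> x
  attr(x, "provenance") <- provenance
  x
}

#' Build a cohort from a data frame
#'
#' Validates column types, enumerations and id uniqueness, fills absent
#' optional columns with NA, and orders columns canonically.
#'
#' @param data A data frame with at least the required participant columns
#'   (see [cohort_codebook()] for names).
#' @param provenance Free-text provenance note stored as an attribute.
#' @return A `cohort` object (a tibble subclass).
#' @export
as_cohort <- function(data, provenance = "in-memory") {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(REQUIRED_COLS, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(COHORT_COLS, names(data))) {
    data[[col]] <- if (col %in% COHORT_CHR) NA_character_
      else if (col %in% COHORT_INT) NA_integer_ else NA_real_
  }
  data <- data[COHORT_COLS]
  data$id <- as.character(data$id)
  for (col in COHORT_DBL) data[[col]] <- as.numeric(data[[col]])
  for (col in COHORT_INT) data[[col]] <- as.integer(data[[col]])
  validate_cohort_columns(data)
  if (nrow(data) == 0) stop("cohort must be non-empty", call. = FALSE)
  dup <- unique(data$id[duplicated(data$id)])
  if (length(dup) > 0) {
    stop("duplicate participant id(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  new_cohort(data, provenance)
}

validate_cohort_columns <- function(data) {
  for (col in names(ENUMS)) {
    bad <- !is.na(data[[col]]) & !(data[[col]] %in% ENUMS[[col]])
    if (any(bad)) {
      stop(sprintf("column '%s' contains value(s) outside {%s}: %s", col,
                   paste(ENUMS[[col]], collapse = ", "),
                   paste(utils::head(unique(data[[col]][bad]), 3),
                         collapse = ", ")), call. = FALSE)
    }
  }
  if (anyNA(data$sex)) stop("column 'sex' may not be missing", call. = FALSE)
  for (col in c("leisure_pa", "work_sedentary")) {
    bad <- !is.na(data[[col]]) & !(data[[col]] %in% 1:4)
    if (any(bad)) stop(sprintf("column '%s' must be in 1..4", col), call. = FALSE)
  }
  for (col in c("fasting_glucose", "height", "weight", "waist", "hip", "sad")) {
    bad <- !is.na(data[[col]]) & data[[col]] <= 0
    if (any(bad)) {
      stop(sprintf("column '%s' must be strictly positive", col), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a participant cohort from CSV
#'
#' Reads an RFC-4180, UTF-8 CSV with one row per participant. Column headers
#' are mapped through `codebook`; empty cells are missing values (for
#' `selfreport_diabetes` an empty cell means the questionnaire item was left
#' blank). Numeric cells that fail to parse become missing and are tallied in
#' the parse report (`attr(x, "parse_report")`), a named count of coerced
#' cells per column.
#'
#' @param path Path to a CSV file.
#' @param codebook Named character vector mapping internal variable names to
#'   file column headers; defaults to [cohort_codebook()].
#' @return A `cohort` with attributes `provenance` and `parse_report`.
#' @export
#' @examples
#' cfg <- cohort_config(n = 50)
#' path <- tempfile(fileext = ".csv")
#' write_cohort(generate_cohort(cfg, seed = 1), path)
#' coh <- read_cohort(path)
#' attr(coh, "parse_report")
read_cohort <- function(path, codebook = cohort_codebook()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  required_headers <- codebook[REQUIRED_COLS]
  absent <- required_headers[!(required_headers %in% names(raw))]
  if (length(absent) > 0) {
    stop("CSV is missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  present <- codebook[codebook %in% names(raw)]
  data <- tibble::as_tibble(stats::setNames(raw[unname(present)], names(present)))

  parse_report <- integer(0)
  to_num <- function(x, col) {
    x[x == ""] <- NA_character_
    # decimal separator is always "."; no locale inference
    out <- suppressWarnings(as.numeric(x))
    n_bad <- sum(!is.na(x) & is.na(out))
    if (n_bad > 0) parse_report[[col]] <<- n_bad
    out
  }
  for (col in intersect(COHORT_DBL, names(data))) {
    data[[col]] <- to_num(data[[col]], col)
  }
  for (col in intersect(COHORT_INT, names(data))) {
    data[[col]] <- as.integer(to_num(data[[col]], col))
  }
  for (col in intersect(COHORT_CHR, names(data))) {
    x <- data[[col]]
    x[x == ""] <- if (col == "selfreport_diabetes") "blank" else NA_character_
    data[[col]] <- x
  }
  out <- as_cohort(data, provenance = paste0("file:", path))
  attr(out, "parse_report") <- parse_report
  out
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()] under the default codebook: fields are written
#' in canonical order, missing values as empty cells, a blank diabetes
#' self-report as an empty cell, and numbers with full (shortest round-trip)
#' precision, so `read_cohort(write_cohort(x))` reproduces every field
#' including missingness and the output is byte-stable for a given cohort.
#'
#' @param cohort A `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  out <- tibble::as_tibble(as.data.frame(cohort))[COHORT_COLS]
  out$selfreport_diabetes[out$selfreport_diabetes == "blank"] <- NA_character_
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants (%d male, %d female) — %s\n",
              nrow(x), sum(x$sex == "male"), sum(x$sex == "female"),
              attr(x, "provenance") %||% "unknown provenance"))
  NextMethod()
}
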