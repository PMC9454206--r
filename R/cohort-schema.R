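#' @keywords internal
"_PACKAGE"

#' Canonical cohort schema
#'
#' Column names, types and (for categorical columns) admissible levels of
#' the participant-level cohort table every other function in the package
#' consumes. Continuous anthropometry is stored in SI-adjacent units
#' (BMI kg/m^2, waist and height cm, physical activity MET-h/day); risk
#' model specification files perform any rescaling their source model
#' requires, so a single canonical table serves all models.
#'
#' Calendar fields (`entry_day`, `exit_day`) are integer days since an
#' arbitrary epoch; follow-up time in years is `(exit_day - entry_day) /
#' 365.25`. `aspirin_use` is observable only for participants with a
#' history of coronary heart disease and is `NA` elsewhere. `icd10` is
#' populated if and only if `exit_reason == "crc"`.
#'
#' @return A named list with elements `version` (schema version string),
#'   `columns` (named character vector of column types) and `levels`
#'   (named list of admissible factor levels).
#' @export
cohort_schema <- function() {
  list(
    version = "crcval-cohort-v1",
    columns = c(
      id = "integer", age = "numeric", sex = "categorical",
      region = "character", urban = "logical",
      bmi = "numeric", height_cm = "numeric", waist_cm = "numeric",
      smoking_status = "categorical",
      alcohol_weekly = "logical", alcohol_category = "categorical",
      diabetes = "logical", physical_activity = "numeric",
      sitting_time = "categorical",
      red_meat_freq = "categorical", processed_meat_freq = "categorical",
      vegetable_freq = "categorical", dairy_freq = "categorical",
      egg_freq = "categorical", sugar_freq = "categorical",
      defecation_frequency = "categorical",
      education = "categorical", marital_status = "categorical",
      nsaid_use = "logical", metabolic_syndrome = "logical",
      chd_history = "logical", aspirin_use = "logical",
      prior_intestinal_cancer = "logical",
      entry_day = "integer", exit_day = "integer",
      exit_reason = "categorical", icd10 = "character"
    ),
    levels = list(
      sex = c("male", "female"),
      smoking_status = c("never", "ex_regular", "current"),
      alcohol_category = c("none", "occasional", "weekly", "daily"),
      sitting_time = c("low", "medium", "high"),
      red_meat_freq = c("never", "monthly", "weekly", "daily"),
      processed_meat_freq = c("never", "monthly", "weekly", "daily"),
      vegetable_freq = c("never", "monthly", "weekly", "daily"),
      dairy_freq = c("never", "monthly", "weekly", "daily"),
      egg_freq = c("never", "monthly", "weekly", "daily"),
      sugar_freq = c("never", "monthly", "weekly", "daily"),
      defecation_frequency = c("lt_daily", "daily", "gt_daily"),
      education = c("none", "primary", "middle", "high_school", "tertiary"),
      marital_status = c("married", "not_married"),
      exit_reason = c("crc", "death_other", "ltfu", "admin")
    )
  )
}

#' Validate a cohort table against the canonical schema
#'
#' Checks column presence, types, admissible categorical levels, and the
#' structural invariants of the schema: ages within 30--79, exit after
#' entry, `icd10` present iff the exit reason is CRC, and `aspirin_use`
#' missing only outside the coronary-heart-disease subgroup.
#'
#' @param cohort A data frame.
#' @param require_exit If `FALSE`, the follow-up fields (`exit_day`,
#'   `exit_reason`, `icd10`) may be absent or all-`NA` (a baseline-only
#'   table awaiting outcome simulation).
#' @return `cohort`, invisibly, on success; otherwise an error whose
#'   message names the offending column(s).
#' @export
validate_cohort <- function(cohort, require_exit = TRUE) {
  sch <- cohort_schema()
  cols <- names(sch$columns)
  if (!require_exit) cols <- setdiff(cols, c("exit_day", "exit_reason", "icd10"))
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in cols) {
    kind <- sch$columns[[col]]
    x <- cohort[[col]]
    ok <- switch(kind,
      integer = is.numeric(x),
      numeric = is.numeric(x),
      logical = is.logical(x),
      character = is.character(x) || all(is.na(x)),
      categorical = is.character(x) || is.factor(x)
    )
    if (!ok) {
      stop("cohort schema error: column '", col, "' must be ", kind,
           call. = FALSE)
    }
    if (kind == "categorical" && !is.null(sch$levels[[col]])) {
      bad <- setdiff(unique(as.character(x[!is.na(x)])), sch$levels[[col]])
      if (length(bad) > 0L) {
        stop("cohort schema error: column '", col, "' has unknown level(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (any(cohort$age < 30 | cohort$age > 79, na.rm = TRUE)) {
    stop("cohort schema error: age outside [30, 79]", call. = FALSE)
  }
  bad_asp <- !is.na(cohort$aspirin_use) & !cohort$chd_history
  if (any(bad_asp, na.rm = TRUE)) {
    stop("cohort schema error: aspirin_use observed outside the CHD subgroup",
         call. = FALSE)
  }
  if (require_exit) {
    if (any(cohort$exit_day < cohort$entry_day, na.rm = TRUE)) {
      stop("cohort data error: exit_day precedes entry_day", call. = FALSE)
    }
    is_crc <- !is.na(cohort$exit_reason) & cohort$exit_reason == "crc"
    if (any(is_crc & is.na(cohort$icd10)) || any(!is_crc & !is.na(cohort$icd10))) {
      stop("cohort schema error: icd10 must be present iff exit_reason is crc",
           call. = FALSE)
    }
  }
  invisible(cohort)
}

#' Write a cohort table to delimited text
#'
#' Writes CSV with a versioned header line (`#crcval-cohort-v1`) so that
#' readers can detect schema drift. Missing values are empty fields.
#'
#' @param cohort A schema-conforming data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", cohort_schema()$version), con)
  utils::write.table(cohort, con, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from delimited text
#'
#' Expects the versioned header written by [write_cohort()] and validates
#' the table against the canonical schema on read.
#'
#' @param path Input file path.
#' @param require_exit Passed to [validate_cohort()].
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path, require_exit = TRUE) {
  header <- readLines(path, n = 1L)
  if (!identical(header, paste0("#", cohort_schema()$version))) {
    stop("cohort I/O error: '", path, "' lacks the ",
         cohort_schema()$version, " header", call. = FALSE)
  }
  x <- utils::read.csv(path, skip = 1L, na.strings = "",
                       stringsAsFactors = FALSE)
  logi <- names(which(cohort_schema()$columns == "logical"))
  for (col in intersect(logi, names(x))) {
    if (!is.logical(x[[col]])) x[[col]] <- as.logical(x[[col]])
  }
  if (!"icd10" %in% names(x)) x$icd10 <- NA_character_
  if (all(is.na(x$icd10))) x$icd10 <- as.character(x$icd10)
  validate_cohort(x, require_exit = require_exit)
  x
}
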