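#' Outcome composites by ICD-10 range
#'
#' The five anatomical outcome sets used in the validation: colorectal
#' cancer (C18--C20), colon (C18), rectal (C19--C20), right-sided colon
#' (C18.0--C18.3) and left-sided colon (C18.5--C18.7). C18.4 (transverse
#' colon) and C18.8/C18.9 (overlapping/unspecified) count toward colon
#' and CRC but toward neither sided subset, reading the stated ranges
#' literally.
#'
#' @return Character vector of outcome-set names.
#' @export
outcome_sets <- function() c("CRC", "colon", "rectal", "right_colon",
                             "left_colon")

#' Classify an ICD-10 code against an outcome composite
#'
#' @param icd10 Character vector of ICD-10 codes (e.g. `"C18.2"`,
#'   `"C19"`) or `NA`.
#' @param outcome_set One of [outcome_sets()].
#' @return Logical vector: does the code fall in the composite? `NA`
#'   codes give `FALSE`.
#' @export
classify_outcome <- function(icd10, outcome_set) {
  outcome_set <- match.arg(outcome_set, outcome_sets())
  out <- rep(FALSE, length(icd10))
  ok <- !is.na(icd10)
  code <- icd10[ok]
  bad <- !grepl("^C[0-9]{2}(\\.[0-9])?$", code)
  if (any(bad)) {
    stop("parse error: malformed ICD-10 code(s): ",
         paste(unique(code[bad])[1:3], collapse = ", "), call. = FALSE)
  }
  major <- as.integer(substr(code, 2L, 3L))
  minor <- ifelse(nchar(code) > 3L,
                  as.integer(substr(code, 5L, 5L)), NA_integer_)
  hit <- switch(outcome_set,
    CRC = major >= 18L & major <= 20L,
    colon = major == 18L,
    rectal = major %in% c(19L, 20L),
    right_colon = major == 18L & !is.na(minor) & minor >= 0L & minor <= 3L,
    left_colon = major == 18L & !is.na(minor) & minor >= 5L & minor <= 7L
  )
  out[ok] <- hit
  out
}

#' Apply the validation cohort exclusions
#'
#' Removes participants with a prior intestinal cancer diagnosis and
#' participants with missing BMI, and reports counts per rule together
#' with their overlap, so the retention arithmetic
#' (`n - prior - bmi + overlap = retained`) is always auditable.
#'
#' @param cohort A schema-conforming cohort data frame.
#' @return A list with `cohort` (retained records) and `log`, a data
#'   frame with columns `rule` (`prior_intestinal_cancer`,
#'   `missing_bmi`, `overlap`, `removed`, `retained`) and `count`.
#' @export
apply_exclusions <- function(cohort) {
  prior <- !is.na(cohort$prior_intestinal_cancer) &
    cohort$prior_intestinal_cancer
  nobmi <- is.na(cohort$bmi)
  drop <- prior | nobmi
  log <- data.frame(
    rule = c("prior_intestinal_cancer", "missing_bmi", "overlap",
             "removed", "retained"),
    count = c(sum(prior), sum(nobmi), sum(prior & nobmi), sum(drop),
              sum(!drop)),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort[!drop, , drop = FALSE], log = log)
}

#' Build follow-up records for an outcome composite
#'
#' Derives each participant's follow-up time and binary event label for
#' one outcome set. Follow-up runs from entry to CRC diagnosis, death
#' from other causes, loss to follow-up, or 10 years, whichever comes
#' first. A CRC event whose site code falls outside `outcome_set` is
#' censored at its event time (it still ends follow-up but is not an
#' event for this composite).
#'
#' @param cohort A cohort with exit fields populated.
#' @param outcome_set One of [outcome_sets()].
#' @return A data frame with columns `id`, `time_years` (in `(0, 10]`),
#'   `event` (logical), `event_class` (`crc`, `death_other`, `ltfu`,
#'   `admin`), `outcome_set`.
#' @export
build_followup <- function(cohort, outcome_set = "CRC") {
  outcome_set <- match.arg(outcome_set, outcome_sets())
  if (any(cohort$exit_day < cohort$entry_day, na.rm = TRUE)) {
    stop("data error: exit before entry", call. = FALSE)
  }
  raw_years <- (cohort$exit_day - cohort$entry_day) / 365.25
  time_years <- pmin(raw_years, 10)
  event_class <- cohort$exit_reason
  truncated <- raw_years > 10
  event_class[truncated] <- "admin"
  is_event <- event_class == "crc" &
    classify_outcome(ifelse(truncated, NA_character_, cohort$icd10),
                     outcome_set)
  data.frame(id = cohort$id, time_years = time_years, event = is_event,
             event_class = event_class, outcome_set = outcome_set,
             stringsAsFactors = FALSE)
}
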