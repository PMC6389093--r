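# Referral domain model: the referral table, cohort container, and the
# missing-data filter cascade applied before analysis.

# Mandatory (non-symptom) columns of the referral schema, in canonical order.
REFERRAL_COLUMNS <- c(
  "id", "age_years", "systolic_mmHg", "diastolic_mmHg", "duration_minutes",
  "diabetes", "onset_datetime", "referral_datetime", "arrival_datetime",
  "abcd_score_recorded", "diagnosis", "cohort", "spectra_flag"
)

# Columns that must be present in any referral file; the rest may be absent
# and are filled with missing values.
REQUIRED_COLUMNS <- c("id", "diagnosis", "cohort", "referral_datetime",
                      "diabetes", "spectra_flag")

#' Construct a referral cohort
#'
#' A referral cohort is the unit of data exchanged between modules: a referral
#' table (one row per referred patient, symptom checkboxes in `sym_*` columns),
#' a cohort label, and a log of how many records each filter step removed.
#'
#' @param referrals data frame following the referral schema (see
#'   [referral_schema()]). Symptom checkboxes are 0/1 columns whose names
#'   start with `"sym_"`; unknown checkbox names are preserved opaquely.
#' @param label cohort tag, `"PRE_QUEUE"` or `"POST_QUEUE"`.
#' @param filter_log named integer vector of records removed per filter step.
#' @param validate check schema and record-level invariants.
#' @return an object of class `referral_cohort` with elements `referrals`,
#'   `label`, `filter_log`.
#' @export
#' @examples
#' rc <- referral_cohort(example_referrals(3), "POST_QUEUE")
#' nrow(rc$referrals)
referral_cohort <- function(referrals, label,
                            filter_log = integer(0), validate = TRUE) {
  if (!label %in% COHORTS) {
    stop(sprintf("unknown cohort tag '%s'; expected one of %s", label,
                 paste(COHORTS, collapse = ", ")), call. = FALSE)
  }
  referrals <- normalize_referrals(referrals)
  if (validate) validate_referrals(referrals)
  structure(
    list(referrals = referrals, label = label,
         filter_log = as.integer(filter_log) |> stats::setNames(names(filter_log))),
    class = "referral_cohort"
  )
}

#' The referral table schema
#'
#' @return data frame describing each mandatory column: name, type, whether
#'   missing values are allowed.
#' @export
referral_schema <- function() {
  data.frame(
    column = REFERRAL_COLUMNS,
    type = c("character", "numeric", "numeric", "numeric", "numeric",
             "integer 0/1", "datetime", "datetime", "datetime",
             "integer 0-6", "enum", "enum", "integer 0/1"),
    allow_missing = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE,
                      TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Coerce a data frame into canonical referral-table form (column types,
# ordering; sym_* columns kept after the mandatory block).
normalize_referrals <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("referral table is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in setdiff(REFERRAL_COLUMNS, names(df))) {
    df[[col]] <- switch(col,
      age_years = , systolic_mmHg = , diastolic_mmHg = ,
      duration_minutes = NA_real_,
      abcd_score_recorded = NA_integer_,
      onset_datetime = , arrival_datetime = as.POSIXct(NA, tz = TZ),
      NA
    )
  }
  df$id <- as.character(df$id)
  for (col in c("age_years", "systolic_mmHg", "diastolic_mmHg",
                "duration_minutes")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$diabetes <- as.integer(df$diabetes)
  df$spectra_flag <- as.integer(df$spectra_flag)
  df$abcd_score_recorded <- as.integer(df$abcd_score_recorded)
  for (col in c("onset_datetime", "referral_datetime", "arrival_datetime")) {
    df[[col]] <- parse_datetime(df[[col]])
  }
  df$diagnosis <- as.character(df$diagnosis)
  df$cohort <- as.character(df$cohort)
  sym <- grep("^sym_", names(df), value = TRUE)
  for (col in sym) df[[col]] <- as.integer(df[[col]])
  extra <- setdiff(names(df), c(REFERRAL_COLUMNS, sym))
  df[, c(REFERRAL_COLUMNS, sort(sym), extra), drop = FALSE]
}

#' Validate referral-record invariants
#'
#' Checks enum membership, value ranges, and timestamp ordering
#' (onset <= referral <= arrival where present). Errors name the offending
#' row ids.
#'
#' @param df referral table.
#' @return invisibly `TRUE`.
#' @export
validate_referrals <- function(df) {
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop(sprintf("%s for referral id(s): %s", what,
                   paste(utils::head(df$id[idx], 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad(duplicated(df$id), "duplicated id")
  bad(!df$diagnosis %in% DIAGNOSES, "unknown diagnosis")
  bad(!df$cohort %in% COHORTS, "unknown cohort tag")
  bad(!is.na(df$age_years) & df$age_years < 0, "negative age")
  bad(!is.na(df$systolic_mmHg) & df$systolic_mmHg <= 0, "non-positive systolic BP")
  bad(!is.na(df$diastolic_mmHg) & df$diastolic_mmHg <= 0, "non-positive diastolic BP")
  bad(!is.na(df$duration_minutes) & df$duration_minutes < 0, "negative duration")
  bad(!df$diabetes %in% c(0L, 1L), "diabetes must be 0/1")
  bad(!df$spectra_flag %in% c(0L, 1L), "spectra_flag must be 0/1")
  bad(!is.na(df$abcd_score_recorded) &
        (df$abcd_score_recorded < 0L | df$abcd_score_recorded > 6L),
      "recorded ABCD score outside [0, 6]")
  bad(is.na(df$referral_datetime), "missing referral_datetime")
  both <- !is.na(df$onset_datetime)
  bad(both & df$onset_datetime > df$referral_datetime,
      "onset after referral")
  arr <- !is.na(df$arrival_datetime)
  bad(arr & df$arrival_datetime < df$referral_datetime,
      "arrival before referral")
  invisible(TRUE)
}

#' @export
print.referral_cohort <- function(x, ...) {
  cat(sprintf("<referral_cohort> %s: %d referrals\n", x$label,
              nrow(x$referrals)))
  if (length(x$filter_log)) {
    cat("  filter cascade removals:",
        paste(sprintf("%s=%d", names(x$filter_log), x$filter_log),
              collapse = ", "), "\n")
  }
  diag_tab <- table(factor(x$referrals$diagnosis, levels = DIAGNOSES))
  cat("  diagnoses:", paste(sprintf("%s=%d", names(diag_tab), diag_tab),
                            collapse = ", "), "\n")
  invisible(x)
}

#' A small fabricated referral table for examples
#'
#' @param n number of rows (max 5).
#' @return a referral data frame.
#' @export
example_referrals <- function(n = 3) {
  df <- data.frame(
    id = sprintf("EX-%03d", 1:5),
    age_years = c(72, 55, 81, 64, NA),
    systolic_mmHg = c(150, 128, 160, NA, 140),
    diastolic_mmHg = c(85, 76, 95, NA, 88),
    duration_minutes = c(70, 5, 120, 30, 15),
    diabetes = c(1L, 0L, 0L, 1L, 0L),
    onset_datetime = parse_datetime(c("2015-03-02 08:30:00",
                                      "2015-03-02 12:00:00",
                                      "2015-03-03 21:15:00",
                                      "2015-03-04 06:00:00",
                                      "2015-03-04 10:00:00")),
    referral_datetime = parse_datetime(c("2015-03-02 14:00:00",
                                         "2015-03-03 09:30:00",
                                         "2015-03-04 08:00:00",
                                         "2015-03-04 16:45:00",
                                         "2015-03-05 11:00:00")),
    arrival_datetime = as.POSIXct(NA, tz = TZ),
    abcd_score_recorded = NA_integer_,
    diagnosis = c("TIA_MINOR_STROKE", "MIMIC", "TIA_MINOR_STROKE",
                  "MIMIC", "TIA_MINOR_STROKE"),
    cohort = "POST_QUEUE",
    spectra_flag = 0L,
    sym_unilateral_weakness = c(1L, 0L, 1L, 0L, 1L),
    sym_speech_disturbance = c(0L, 0L, 1L, 1L, 0L),
    sym_headache = c(0L, 1L, 0L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  df[seq_len(min(n, 5L)), , drop = FALSE]
}
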