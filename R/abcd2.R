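# ABCD2 scoring: mean-substitution imputation, the component rule table,
# legacy ABCD conversion, and risk-stratum assignment.

#' Mean-substitution imputation constants
#'
#' Population means substituted for missing age and blood pressure before
#' ABCD2 scoring, mirroring how the live triage system scores incomplete
#' referral forms. Defaults are the unit's previously established values.
#'
#' @param mean_age_years mean age in years.
#' @param mean_systolic_mmHg mean systolic blood pressure.
#' @param mean_diastolic_mmHg mean diastolic blood pressure.
#' @return an object of class `imputation_constants`.
#' @export
imputation_constants <- function(mean_age_years = 68.277,
                                 mean_systolic_mmHg = 141.606,
                                 mean_diastolic_mmHg = 78.042) {
  stopifnot(mean_age_years > 0, mean_systolic_mmHg > 0,
            mean_diastolic_mmHg > 0)
  structure(list(mean_age_years = mean_age_years,
                 mean_systolic_mmHg = mean_systolic_mmHg,
                 mean_diastolic_mmHg = mean_diastolic_mmHg),
            class = "imputation_constants")
}

#' Impute missing age and blood pressure
#'
#' Replaces missing `age_years`, `systolic_mmHg`, and `diastolic_mmHg` with
#' the supplied constants; every other field is untouched. Duration is
#' deliberately never imputed — a missing duration remains a scoring error.
#' The fields imputed for each record are recorded in an `imputed_fields`
#' column (comma-separated, empty when nothing was imputed).
#'
#' @param x a [referral_cohort()] or referral data frame.
#' @param constants an [imputation_constants()].
#' @return object of the same type with missing values filled in.
#' @export
impute_missing <- function(x, constants = imputation_constants()) {
  stopifnot(inherits(constants, "imputation_constants"))
  df <- if (inherits(x, "referral_cohort")) x$referrals else x
  imp <- matrix(FALSE, nrow(df), 3,
                dimnames = list(NULL, c("age_years", "systolic_mmHg",
                                        "diastolic_mmHg")))
  imp[, "age_years"] <- is.na(df$age_years)
  imp[, "systolic_mmHg"] <- is.na(df$systolic_mmHg)
  imp[, "diastolic_mmHg"] <- is.na(df$diastolic_mmHg)
  df$age_years[imp[, 1]] <- constants$mean_age_years
  df$systolic_mmHg[imp[, 2]] <- constants$mean_systolic_mmHg
  df$diastolic_mmHg[imp[, 3]] <- constants$mean_diastolic_mmHg
  df$imputed_fields <- apply(imp, 1L, function(r) {
    paste(colnames(imp)[r], collapse = ",")
  })
  if (inherits(x, "referral_cohort")) {
    x$referrals <- df
    x
  } else {
    df
  }
}

#' ABCD2 component rule table
#'
#' The conventional point rules: Age >= 60 (1 pt); systolic BP >= 140 or
#' diastolic >= 90 (1 pt); Clinical presentation — unilateral weakness (2 pts)
#' else speech disturbance without weakness (1 pt); Duration >= 60 min (2 pts),
#' 10-59 min (1 pt); Diabetes (1 pt). All thresholds are inclusive and every
#' threshold is overridable, so a unit using a local variant can supply its
#' own table.
#'
#' @param age_threshold years at/above which the age point is scored.
#' @param systolic_threshold,diastolic_threshold mmHg thresholds for the BP
#'   point (either suffices).
#' @param duration_long,duration_short minutes at/above which duration scores
#'   2 points and 1 point respectively.
#' @param weakness_points,speech_points clinical-presentation points for
#'   unilateral weakness and for speech disturbance without weakness.
#' @return an object of class `abcd2_rules`.
#' @export
abcd2_rules <- function(age_threshold = 60, systolic_threshold = 140,
                        diastolic_threshold = 90, duration_long = 60,
                        duration_short = 10, weakness_points = 2L,
                        speech_points = 1L) {
  stopifnot(duration_short < duration_long)
  structure(list(age_threshold = age_threshold,
                 systolic_threshold = systolic_threshold,
                 diastolic_threshold = diastolic_threshold,
                 duration_long = duration_long,
                 duration_short = duration_short,
                 weakness_points = as.integer(weakness_points),
                 speech_points = as.integer(speech_points)),
            class = "abcd2_rules")
}

#' Compute ABCD2 scores
#'
#' Scores each referral from its form fields: age, blood pressure, clinical
#' presentation (the `sym_unilateral_weakness` / `sym_speech_disturbance`
#' checkboxes), symptom duration, and diabetes. Inputs must be complete
#' (apply [impute_missing()] first for age/BP); a missing age, blood
#' pressure, or duration is a scoring error naming the blocking fields and
#' record ids.
#'
#' @param x a [referral_cohort()] or referral data frame.
#' @param rules an [abcd2_rules()] table.
#' @return data frame with one row per referral: `id`, the five component
#'   scores (`age_pts`, `bp_pts`, `clinical_pts`, `duration_pts`,
#'   `diabetes_pts`), and the total `abcd2` in 0-7.
#' @export
#' @examples
#' rc <- referral_cohort(example_referrals(2), "POST_QUEUE")
#' compute_abcd2(impute_missing(rc))
compute_abcd2 <- function(x, rules = abcd2_rules()) {
  stopifnot(inherits(rules, "abcd2_rules"))
  df <- if (inherits(x, "referral_cohort")) x$referrals else x
  blocking <- c(
    if (anyNA(df$age_years)) "age_years",
    if (anyNA(df$systolic_mmHg)) "systolic_mmHg",
    if (anyNA(df$diastolic_mmHg)) "diastolic_mmHg",
    if (anyNA(df$duration_minutes)) "duration_minutes"
  )
  if (length(blocking)) {
    bad_ids <- df$id[!stats::complete.cases(
      df[, c("age_years", "systolic_mmHg", "diastolic_mmHg",
             "duration_minutes")])]
    stop(sprintf(
      "cannot score: missing %s (e.g. id %s); impute or supply values",
      paste(blocking, collapse = ", "),
      paste(utils::head(bad_ids, 3L), collapse = ", ")), call. = FALSE)
  }
  weakness <- symptom_indicator(df, "unilateral_weakness")
  speech <- symptom_indicator(df, "speech_disturbance")
  comp <- abcd2_components(df$age_years, df$systolic_mmHg, df$diastolic_mmHg,
                           weakness, speech, df$duration_minutes,
                           df$diabetes, rules)
  cbind(data.frame(id = df$id, stringsAsFactors = FALSE), comp)
}

# Vectorized component scorer over raw field values.
abcd2_components <- function(age, systolic, diastolic, weakness, speech,
                             duration, diabetes, rules = abcd2_rules()) {
  age_pts <- as.integer(age >= rules$age_threshold)
  bp_pts <- as.integer(systolic >= rules$systolic_threshold |
                         diastolic >= rules$diastolic_threshold)
  clinical_pts <- ifelse(weakness == 1L, rules$weakness_points,
                         ifelse(speech == 1L, rules$speech_points, 0L))
  duration_pts <- ifelse(duration >= rules$duration_long, 2L,
                         ifelse(duration >= rules$duration_short, 1L, 0L))
  diabetes_pts <- as.integer(diabetes == 1L)
  data.frame(age_pts = age_pts, bp_pts = bp_pts,
             clinical_pts = as.integer(clinical_pts),
             duration_pts = as.integer(duration_pts),
             diabetes_pts = diabetes_pts,
             abcd2 = as.integer(age_pts + bp_pts + clinical_pts +
                                  duration_pts + diabetes_pts))
}

symptom_indicator <- function(df, key) {
  col <- paste0("sym_", key)
  if (col %in% names(df)) {
    v <- df[[col]]
    v[is.na(v)] <- 0L  # absent checkbox = not reported
    as.integer(v)
  } else {
    rep(0L, nrow(df))
  }
}

#' Convert a legacy ABCD score to ABCD2
#'
#' The pre-queue era recorded the 0-6 ABCD score, which lacks the diabetes
#' point; the ABCD2 score is obtained by adding the patient's diabetes status.
#'
#' @param abcd integer vector of ABCD scores in 0-6.
#' @param diabetes 0/1 vector of diabetes status.
#' @return integer vector of ABCD2 scores in 0-7.
#' @export
abcd_to_abcd2 <- function(abcd, diabetes) {
  if (any(is.na(abcd)) || any(abcd < 0L | abcd > 6L)) {
    stop("ABCD scores must be integers in [0, 6]", call. = FALSE)
  }
  if (any(!diabetes %in% c(0L, 1L))) {
    stop("diabetes must be 0/1", call. = FALSE)
  }
  as.integer(abcd) + as.integer(diabetes)
}

#' Assign ABCD2 risk strata
#'
#' Fixed partition of the 0-7 range: LOW = 0-3, MODERATE = 4-5, HIGH = 6-7.
#'
#' @param score integer vector of ABCD2 scores.
#' @return factor with levels LOW, MODERATE, HIGH.
#' @export
risk_stratum <- function(score) {
  if (any(is.na(score)) || any(score < 0L | score > 7L)) {
    stop("ABCD2 scores must be integers in [0, 7]", call. = FALSE)
  }
  cut(as.integer(score), breaks = c(-1L, 3L, 5L, 7L), labels = STRATA)
}

#' Derive ABCD2 scores and strata for a cohort, era-appropriately
#'
#' PRE_QUEUE cohorts carry a staff-recorded ABCD score; their ABCD2 score is
#' that score plus diabetes status. POST_QUEUE cohorts are scored from the
#' assessment-form fields after mean-substitution imputation, replicating the
#' live triage computation.
#'
#' @param cohort a filtered [referral_cohort()].
#' @param constants an [imputation_constants()] (POST_QUEUE only).
#' @param rules an [abcd2_rules()] table (POST_QUEUE only).
#' @param fallback for PRE_QUEUE cohorts, score records missing the recorded
#'   ABCD score from their form fields (as POST_QUEUE) instead of erroring;
#'   used when scoring a full unfiltered referral stream for simulation.
#' @return the cohort with `abcd2` and `stratum` columns added.
#' @export
derive_abcd2 <- function(cohort, constants = imputation_constants(),
                         rules = abcd2_rules(), fallback = FALSE) {
  stopifnot(inherits(cohort, "referral_cohort"))
  df <- cohort$referrals
  if (cohort$label == "PRE_QUEUE") {
    missing_rec <- is.na(df$abcd_score_recorded)
    if (any(missing_rec) && !fallback) {
      stop("PRE_QUEUE cohort has missing recorded ABCD scores; ",
           "run apply_cohort_filters() first", call. = FALSE)
    }
    rec <- df$abcd_score_recorded
    if (any(missing_rec)) {
      computed <- compute_abcd2(impute_missing(df, constants), rules)
      rec[missing_rec] <- computed$abcd2[missing_rec] -
        computed$diabetes_pts[missing_rec]
    }
    df$abcd2 <- abcd_to_abcd2(rec, df$diabetes)
  } else {
    imputed <- impute_missing(df, constants)
    scores <- compute_abcd2(imputed, rules)
    df <- imputed
    df$abcd2 <- scores$abcd2
  }
  df$stratum <- risk_stratum(df$abcd2)
  cohort$referrals <- df
  cohort
}
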