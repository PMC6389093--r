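# Missing-data filter cascade applied to raw referral extracts before any
# scoring or survival analysis.

FILTER_STEPS <- c("diagnosis", "dates", "abcd", "spectra")

#' Apply the cohort filter cascade
#'
#' Restricts a raw referral extract to analysable records, in a fixed, logged
#' order:
#'
#' 1. `diagnosis` — keep only final diagnoses of TIA/minor stroke or mimic
#'    (drops OTHER and UNKNOWN, which include never-attended referrals).
#' 2. `dates` — drop records missing a symptom-onset or referral timestamp;
#'    with `require_arrival = TRUE` (evaluation of observed arrival data) a
#'    missing arrival timestamp is also dropped.
#' 3. `abcd` — for the PRE_QUEUE era only, listwise-delete records missing
#'    the staff-recorded ABCD score (the pre-queue stratification variable).
#'    POST_QUEUE records are retained; their missing fields are handled by
#'    mean-substitution at scoring time.
#' 4. `spectra` — drop referrals flagged as co-enrolled in the concurrent
#'    imaging study, whose early imaging could bias booking priority.
#'
#' The cascade is idempotent and its final retained set does not depend on
#' input row order.
#'
#' @param raw a [referral_cohort()].
#' @param era cohort era tag governing step 3; defaults to the cohort's label.
#' @param require_arrival also remove records with missing arrival timestamps
#'   (step 2); use when filtering observed (not simulated) arrival data.
#' @return a filtered [referral_cohort()] whose `filter_log` records the
#'   number removed at each step, in cascade order.
#' @export
#' @examples
#' rc <- referral_cohort(example_referrals(3), "POST_QUEUE")
#' apply_cohort_filters(rc)$filter_log
apply_cohort_filters <- function(raw, era = raw$label, require_arrival = FALSE) {
  stopifnot(inherits(raw, "referral_cohort"))
  if (!era %in% COHORTS) {
    stop(sprintf("unknown era tag '%s'; expected one of %s", era,
                 paste(COHORTS, collapse = ", ")), call. = FALSE)
  }
  df <- raw$referrals
  log <- stats::setNames(integer(length(FILTER_STEPS)), FILTER_STEPS)

  keep <- df$diagnosis %in% c("TIA_MINOR_STROKE", "MIMIC")
  log[["diagnosis"]] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  keep <- !is.na(df$onset_datetime) & !is.na(df$referral_datetime)
  if (require_arrival) keep <- keep & !is.na(df$arrival_datetime)
  log[["dates"]] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  if (era == "PRE_QUEUE") {
    keep <- !is.na(df$abcd_score_recorded)
    log[["abcd"]] <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }

  keep <- df$spectra_flag == 0L
  log[["spectra"]] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  rownames(df) <- NULL
  referral_cohort(df, raw$label, filter_log = log, validate = FALSE)
}
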