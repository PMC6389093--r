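# The weighted triage score and the dynamic ranked referral queue.

#' Compute weighted triage scores
#'
#' The triage weight for a referral is the product of its diagnostic and
#' prognostic components:
#' `w = P(TIA/minor stroke) * remaining_risk(stratum curve, t)`,
#' where `t` is the elapsed time in days since symptom onset. The diagnosis
#' probability discounts mimic referrals; the remaining-risk factor is
#' front-loaded in time, so a patient seen late loses priority as their
#' actionable risk window shrinks.
#'
#' @param p_tia probability of TIA/minor stroke, in `[0, 1]`.
#' @param abcd2 ABCD2 scores (0-7), determining the risk stratum.
#' @param t_days elapsed days since symptom onset (non-negative reals).
#' @param curves named list of per-stratum [fit_risk_curve()] objects
#'   covering every stratum that occurs.
#' @return data frame with `w`, `p_tia`, `remaining_risk`, `abcd2`, `t_days`.
#' @export
#' @examples
#' curves <- fit_risk_curves()
#' weighted_triage_score(0.8, 5, 1.0, curves)
weighted_triage_score <- function(p_tia, abcd2, t_days, curves) {
  stopifnot(all(p_tia >= 0 & p_tia <= 1), all(t_days >= 0))
  strata <- as.character(risk_stratum(abcd2))
  missing_curves <- setdiff(unique(strata), names(curves))
  if (length(missing_curves)) {
    stop(sprintf("no risk curve supplied for stratum(s): %s",
                 paste(missing_curves, collapse = ", ")), call. = FALSE)
  }
  rr <- numeric(length(strata))
  for (s in unique(strata)) {
    idx <- strata == s
    rr[idx] <- remaining_risk(curves[[s]], t_days[idx])
  }
  data.frame(w = p_tia * rr, p_tia = p_tia, remaining_risk = rr,
             abcd2 = as.integer(abcd2), t_days = t_days)
}

#' Construct a queue state
#'
#' A snapshot of the unit's referral queue at a time point: every referral
#' with its current weighted score and booked status.
#'
#' @param now POSIXct timestamp of the snapshot.
#' @param entries data frame with columns `id`, `w`, `onset_datetime`,
#'   `booked` (logical); typically built by [refresh_scores()].
#' @return an object of class `queue_state`.
#' @export
queue_state <- function(now, entries = data.frame(
                          id = character(0), w = numeric(0),
                          onset_datetime = as.POSIXct(character(0), tz = TZ),
                          booked = logical(0))) {
  now <- parse_datetime(now)
  stopifnot(all(c("id", "w", "onset_datetime", "booked") %in% names(entries)),
            !anyDuplicated(entries$id))
  structure(list(now = now, entries = entries), class = "queue_state")
}

#' Rank the unbooked queue
#'
#' Unbooked entries sorted by weighted score descending; ties broken by
#' earlier symptom onset (clinically conservative), then by id for a stable
#' total order. Booked entries are excluded and never re-ranked.
#'
#' @param state a [queue_state()].
#' @return character vector of referral ids, highest priority first.
#' @export
rank_referrals <- function(state) {
  stopifnot(inherits(state, "queue_state"))
  e <- state$entries[!state$entries$booked, , drop = FALSE]
  if (!nrow(e)) return(character(0))
  e$id[order(-e$w, e$onset_datetime, e$id)]
}

#' Refresh queue scores to a new time point
#'
#' Rescores every unbooked entry with the elapsed-time term recomputed at
#' `now`, and inserts any new referrals not yet in the queue. The clock can
#' only move forward; refreshing at the same instant with no new referrals
#' leaves the state unchanged.
#'
#' @param state a [queue_state()].
#' @param referrals scored referral table carrying `id`, `onset_datetime`,
#'   `abcd2`, and `p_tia` columns for every queue entry (and any new ones).
#' @param curves per-stratum risk curves ([fit_risk_curves()]).
#' @param now new snapshot time, `>= state$now`.
#' @return the updated [queue_state()].
#' @export
refresh_scores <- function(state, referrals, curves, now) {
  stopifnot(inherits(state, "queue_state"))
  now <- parse_datetime(now)
  if (now < state$now) {
    stop("queue clock cannot move backwards", call. = FALSE)
  }
  df <- if (inherits(referrals, "referral_cohort")) referrals$referrals else referrals
  needed <- c("id", "onset_datetime", "abcd2", "p_tia")
  stopifnot(all(needed %in% names(df)))
  ids <- union(state$entries$id, df$id)
  booked <- stats::setNames(rep(FALSE, length(ids)), ids)
  booked[state$entries$id] <- state$entries$booked
  df <- df[match(ids, df$id), , drop = FALSE]
  if (anyNA(df$id)) {
    stop("queue entries missing from the referral table", call. = FALSE)
  }
  t_days <- pmax(0, as.numeric(difftime(now, df$onset_datetime, units = "days")))
  scored <- weighted_triage_score(df$p_tia, df$abcd2, t_days, curves)
  entries <- data.frame(id = ids, w = scored$w,
                        onset_datetime = df$onset_datetime,
                        booked = unname(booked[ids]),
                        stringsAsFactors = FALSE)
  # booked entries keep their frozen score
  old <- match(entries$id, state$entries$id)
  frozen <- entries$booked & !is.na(old)
  entries$w[frozen] <- state$entries$w[old[frozen]]
  queue_state(now, entries)
}

#' Mark queue entries as booked
#'
#' @param state a [queue_state()].
#' @param ids referral ids to mark booked.
#' @return the updated state.
#' @export
mark_booked <- function(state, ids) {
  stopifnot(inherits(state, "queue_state"))
  unknown <- setdiff(ids, state$entries$id)
  if (length(unknown)) {
    stop(sprintf("cannot book unknown referral id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  state$entries$booked[state$entries$id %in% ids] <- TRUE
  state
}

#' @export
print.queue_state <- function(x, ...) {
  cat(sprintf("<queue_state> at %s: %d entries (%d unbooked)\n",
              format(x$now), nrow(x$entries), sum(!x$entries$booked)))
  invisible(x)
}
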