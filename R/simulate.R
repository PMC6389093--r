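# Discrete-event simulator of unit booking. Each business-day triage session,
# newly faxed referrals enter the queue (weekend faxes enter Monday morning),
# the queue is ranked under the active policy, and the top entries are booked
# into the earliest free future appointment slots.

#' Unit operating configuration
#'
#' @param daily_capacity appointment slots per business day (>= 1); also the
#'   maximum number of bookings made at one triage session.
#' @param business_days weekdays on which the unit triages and sees patients
#'   (ISO numbering, Monday = 1; default Monday-Friday).
#' @param triage_hour hour of day at which the daily triage session runs.
#' @param appointment_hour hour of day of the first appointment slot.
#' @return an object of class `unit_config`.
#' @export
unit_config <- function(daily_capacity = 5L, business_days = 1:5,
                        triage_hour = 9L, appointment_hour = 10L) {
  daily_capacity <- as.integer(daily_capacity)
  stopifnot(daily_capacity >= 1L, all(business_days %in% 1:7))
  structure(list(daily_capacity = daily_capacity,
                 business_days = as.integer(business_days),
                 triage_hour = as.integer(triage_hour),
                 appointment_hour = as.integer(appointment_hour)),
            class = "unit_config")
}

POLICIES <- c("WEIGHTED_QUEUE", "ABCD_DESC", "FIFO")

#' Simulate unit booking under a triage policy
#'
#' Runs the unit's booking process over a referral stream:
#'
#' * Referrals enter the queue at the first triage session at or after their
#'   referral timestamp; sessions run each business-day morning, so weekend
#'   faxes are first triaged Monday.
#' * At each session the unbooked queue is ordered by the policy —
#'   `WEIGHTED_QUEUE` (weighted triage score, recomputed at session time),
#'   `ABCD_DESC` (the historical practice: staff-recorded ABCD score
#'   descending, falling back to the ABCD2 score when none was recorded), or
#'   `FIFO` (referral time) — with ties broken by earlier onset, then id.
#' * The top `daily_capacity` entries are booked into the earliest free
#'   appointment slots on business days strictly after the session day
#'   (patients are phoned, so same-day booking is not modelled); each
#'   business day holds `daily_capacity` slots.
#'
#' The simulation is deterministic given its inputs and `seed` (the seed only
#' matters when `dropout_prob > 0`).
#'
#' @param stream a [referral_cohort()] (filtered); for `WEIGHTED_QUEUE` it
#'   must carry `abcd2` and `p_tia` columns (see [derive_abcd2()] and
#'   [predict_tia_probability()]) unless `model` and `curves` are given, in
#'   which case they are computed here.
#' @param unit a [unit_config()].
#' @param policy one of `"WEIGHTED_QUEUE"`, `"ABCD_DESC"`, `"FIFO"`.
#' @param seed integer seed for the optional dropout draws.
#' @param model,curves classifier model and risk curves, used to score the
#'   stream when needed.
#' @param constants imputation constants used if scoring here.
#' @param sim_end last triage session date; defaults to 90 days after the
#'   latest referral so the queue can drain. Referrals dated after `sim_end`
#'   are excluded with a warning.
#' @param dropout_prob per-referral probability that a booked patient never
#'   attends (sensitivity analyses only; default 0).
#' @return data frame with one row per referral: `id`, `entry_date` (first
#'   triage session at which it was visible), `booked_date` (session at which
#'   it was booked), `appointment_datetime`, `arrival_datetime` (equal to the
#'   appointment unless the patient dropped out), `arrived` (0/1).
#' @export
simulate_unit <- function(stream, unit = unit_config(),
                          policy = c("WEIGHTED_QUEUE", "ABCD_DESC", "FIFO"),
                          seed = 1L, model = NULL, curves = NULL,
                          constants = imputation_constants(),
                          sim_end = NULL, dropout_prob = 0) {
  stopifnot(inherits(stream, "referral_cohort"), inherits(unit, "unit_config"))
  policy <- match.arg(policy)
  df <- stream$referrals
  if (!nrow(df)) {
    return(data.frame(id = character(0), entry_date = as.Date(character(0)),
                      booked_date = as.Date(character(0)),
                      appointment_datetime = as.POSIXct(character(0), tz = TZ),
                      arrival_datetime = as.POSIXct(character(0), tz = TZ),
                      arrived = integer(0)))
  }
  if (anyNA(df$onset_datetime) || anyNA(df$referral_datetime)) {
    stop("stream has missing onset/referral timestamps; ",
         "run apply_cohort_filters() first", call. = FALSE)
  }
  if (policy == "WEIGHTED_QUEUE") {
    if (!all(c("abcd2", "p_tia") %in% names(df))) {
      if (is.null(model) || is.null(curves)) {
        stop("WEIGHTED_QUEUE needs scored referrals (abcd2, p_tia columns) ",
             "or `model` and `curves` to score them", call. = FALSE)
      }
      cohort <- derive_abcd2(stream, constants)
      cohort$referrals$p_tia <-
        predict_tia_probability(model, cohort)$p_tia
      df <- cohort$referrals
    }
    if (is.null(curves)) {
      stop("WEIGHTED_QUEUE requires risk `curves`", call. = FALSE)
    }
  }
  if (policy == "ABCD_DESC" && !"abcd2" %in% names(df)) {
    if (all(is.na(df$abcd_score_recorded))) {
      stop("ABCD_DESC needs recorded ABCD scores or an abcd2 column",
           call. = FALSE)
    }
  }

  last_referral <- max(as.Date(df$referral_datetime))
  sim_end <- as.Date(sim_end %||% (last_referral + 90L))
  late <- as.Date(df$referral_datetime) > sim_end
  if (any(late)) {
    warning(sprintf("%d referral(s) dated after simulation end excluded",
                    sum(late)), call. = FALSE)
    df <- df[!late, , drop = FALSE]
  }

  # session calendar: business days from the first referral through sim_end
  first_day <- as.Date(min(df$referral_datetime))
  days <- seq(first_day, sim_end, by = "day")
  sessions <- days[is_business_day(days, unit$business_days)]
  session_dt <- as.POSIXct(paste0(format(sessions), " ",
                                  sprintf("%02d:00:00", unit$triage_hour)),
                           tz = TZ)
  # entry session of each referral: first session whose time >= referral time
  entry_idx <- findInterval(as.numeric(df$referral_datetime) - 1e-6,
                            as.numeric(session_dt)) + 1L
  in_scope <- entry_idx <= length(sessions)
  if (any(!in_scope)) {
    warning(sprintf("%d referral(s) arrive after the last triage session",
                    sum(!in_scope)), call. = FALSE)
  }

  n <- nrow(df)
  booked <- rep(FALSE, n)
  booked_date <- as.Date(rep(NA, n))
  appt <- as.POSIXct(rep(NA_real_, n), tz = TZ)
  slots_used <- new.env(parent = emptyenv())
  slot_cursor <- sessions[1]  # earliest day possibly having a free slot

  dropout <- if (dropout_prob > 0) {
    with_seed(seed, stats::runif(n) < dropout_prob)
  } else {
    rep(FALSE, n)
  }

  abcd_key <- if ("abcd2" %in% names(df)) {
    ifelse(is.na(df$abcd_score_recorded), df$abcd2, df$abcd_score_recorded)
  } else {
    df$abcd_score_recorded
  }

  for (s in seq_along(sessions)) {
    active <- which(!booked & in_scope & entry_idx <= s)
    if (!length(active)) next
    ord <- switch(policy,
      WEIGHTED_QUEUE = {
        t_days <- pmax(0, as.numeric(difftime(session_dt[s],
                                              df$onset_datetime[active],
                                              units = "days")))
        w <- weighted_triage_score(df$p_tia[active], df$abcd2[active],
                                   t_days, curves)$w
        active[order(-w, df$onset_datetime[active], df$id[active])]
      },
      ABCD_DESC = active[order(-abcd_key[active], df$onset_datetime[active],
                               df$id[active])],
      FIFO = active[order(df$referral_datetime[active], df$id[active])]
    )
    take <- utils::head(ord, unit$daily_capacity)
    day <- max(slot_cursor, next_business_day(sessions[s], unit$business_days))
    for (i in take) {
      repeat {
        key <- format(day)
        used <- slots_used[[key]] %||% 0L
        if (used < unit$daily_capacity && day > sessions[s]) break
        day <- next_business_day(day, unit$business_days)
      }
      slots_used[[key]] <- (slots_used[[key]] %||% 0L) + 1L
      booked[i] <- TRUE
      booked_date[i] <- sessions[s]
      appt[i] <- as.POSIXct(paste0(format(day), " ",
                                   sprintf("%02d:%02d:00",
                                           unit$appointment_hour,
                                           (slots_used[[key]] - 1L) * 5L)),
                            tz = TZ)
    }
    slot_cursor <- day
  }

  arrived <- booked & !dropout
  data.frame(
    id = df$id,
    entry_date = as.Date(ifelse(in_scope, sessions[pmin(entry_idx,
                                                        length(sessions))],
                                NA), origin = "1970-01-01"),
    booked_date = booked_date,
    appointment_datetime = appt,
    arrival_datetime = as.POSIXct(ifelse(arrived, appt, NA), tz = TZ,
                                  origin = "1970-01-01"),
    arrived = as.integer(arrived),
    stringsAsFactors = FALSE
  )
}

#' Attach simulated arrivals to a cohort
#'
#' @param cohort a [referral_cohort()].
#' @param arrivals output of [simulate_unit()] for the same stream.
#' @return the cohort with `arrival_datetime` filled in from the simulation.
#' @export
attach_arrivals <- function(cohort, arrivals) {
  stopifnot(inherits(cohort, "referral_cohort"))
  idx <- match(cohort$referrals$id, arrivals$id)
  cohort$referrals$arrival_datetime <- arrivals$arrival_datetime[idx]
  cohort
}
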