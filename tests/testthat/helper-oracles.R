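# Independent brute-force oracles and small fixture builders used across the
# suite. Each oracle is a from-scratch implementation kept deliberately
# different in structure from the package code it checks.

# --- fixtures ---------------------------------------------------------------

toy_referral_row <- function(id, age = 70, sbp = 150, dbp = 80, dur = 70,
                             diabetes = 1L, weakness = 1L, speech = 0L,
                             onset = "2015-03-02 08:00:00",
                             referral = "2015-03-02 14:00:00",
                             arrival = NA, abcd = NA_integer_,
                             diagnosis = "TIA_MINOR_STROKE",
                             cohort = "POST_QUEUE", spectra = 0L) {
  data.frame(id = id, age_years = age, systolic_mmHg = sbp,
             diastolic_mmHg = dbp, duration_minutes = dur,
             diabetes = diabetes,
             onset_datetime = if (is.na(onset)) NA_character_ else onset,
             referral_datetime = referral,
             arrival_datetime = if (length(arrival) == 1 && is.na(arrival))
               NA_character_ else arrival,
             abcd_score_recorded = abcd, diagnosis = diagnosis,
             cohort = cohort, spectra_flag = spectra,
             sym_unilateral_weakness = weakness,
             sym_speech_disturbance = speech, stringsAsFactors = FALSE)
}

toy_cohort <- function(rows, label = "POST_QUEUE") {
  referral_cohort(do.call(rbind, rows), label)
}

# --- ABCD2 oracle: literal scalar transcription of the clinical rule --------

oracle_abcd2 <- function(age, sbp, dbp, weakness, speech, duration, diabetes) {
  pts <- 0L
  if (age >= 60) pts <- pts + 1L
  if (sbp >= 140 || dbp >= 90) pts <- pts + 1L
  if (weakness == 1L) {
    pts <- pts + 2L
  } else if (speech == 1L) {
    pts <- pts + 1L
  }
  if (duration >= 60) {
    pts <- pts + 2L
  } else if (duration >= 10) {
    pts <- pts + 1L
  }
  if (diabetes == 1L) pts <- pts + 1L
  pts
}

# --- logistic classifier oracle: term-by-term accumulation ------------------

oracle_predict <- function(model, feature_values) {
  lp <- model$intercept
  for (f in names(model$main_effects)) {
    lp <- lp + model$main_effects[[f]] * (feature_values[[f]] %||% 0)
  }
  for (it in model$interactions) {
    lp <- lp + it$coef * (feature_values[[it$features[1]]] %||% 0) *
      (feature_values[[it$features[2]]] %||% 0)
  }
  1 / (1 + exp(-lp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- Kaplan-Meier oracle: stepwise product over sorted records --------------

oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    n_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  median <- if (any(surv <= 0.5)) ut[min(which(surv <= 0.5))] else NA_real_
  list(time = ut, surv = surv, median = median)
}

# --- event-time sampler from a piecewise-constant hazard (inversion) --------

oracle_sample_events <- function(breaks, hazard, n) {
  # cumulative hazard at the breaks
  ch <- c(0, cumsum(hazard * diff(breaks)))
  u <- -log(runif(n))  # target cumulative hazards
  out <- rep(Inf, n)
  for (i in seq_len(n)) {
    k <- findInterval(u[i], ch)
    if (k < length(ch)) {
      out[i] <- breaks[k] + (u[i] - ch[k]) / hazard[k]
    }
  }
  out
}
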