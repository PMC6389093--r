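# Evaluation pipeline: calendar-day time-to-unit outcomes, right censoring,
# Kaplan-Meier estimation, the Peto-Peto modified Gehan-Wilcoxon test, and
# the six-stratum cohort-comparison report.

#' Calendar days from symptom onset to unit arrival
#'
#' Counts calendar-date boundaries between the two timestamps; time of day is
#' ignored, so an onset at 23:50 and arrival at 00:10 the next day is 1 day.
#'
#' @param onset,arrival POSIXct vectors; `arrival` may contain `NA`
#'   (never arrived). `arrival < onset` is rejected.
#' @return integer days (`NA` where arrival is missing).
#' @export
days_to_unit <- function(onset, arrival) {
  onset <- parse_datetime(onset)
  arrival <- parse_datetime(arrival)
  both <- !is.na(onset) & !is.na(arrival)
  if (any(both & arrival < onset)) {
    stop("arrival precedes symptom onset", call. = FALSE)
  }
  as.integer(as.Date(arrival, tz = TZ) - as.Date(onset, tz = TZ))
}

#' Right-censor days-to-unit at a horizon
#'
#' Arrivals within the horizon are events at their day; later arrivals and
#' never-arrived patients are censored at the horizon. By default the
#' boundary is inclusive — an arrival on day `horizon` exactly counts as an
#' event ("within H days" read inclusively); set `inclusive = FALSE` for the
#' exclusive convention.
#'
#' @param days integer days-to-unit, `NA` for never arrived.
#' @param horizon censoring horizon in days (default 28).
#' @param inclusive whether a day-`horizon` arrival is an event.
#' @return data frame with columns `time` and `event` (1 = arrived).
#' @export
#' @examples
#' censor_at(c(5, 28, 30, NA))
censor_at <- function(days, horizon = 28L, inclusive = TRUE) {
  stopifnot(horizon > 0)
  if (is.data.frame(days)) days <- days$days
  event <- !is.na(days) & (if (inclusive) days <= horizon else days < horizon)
  data.frame(time = as.integer(ifelse(event, days, horizon)),
             event = as.integer(event))
}

#' Kaplan-Meier estimate of days to unit arrival
#'
#' Product-limit estimator with the median defined as the smallest time at
#' which the survival (still-not-arrived) probability is `<= 0.5`; if the
#' curve never reaches 0.5 the median is not reached (`NA`).
#'
#' @param data data frame with `time` and `event` columns ([censor_at()]).
#' @return an object of class `km_curve` with elements `time`, `n_risk`,
#'   `n_event`, `surv`, `median_days`, and the underlying
#'   [survival::survfit()] fit.
#' @export
#' @examples
#' km_estimate(data.frame(time = 1:4, event = 1L))$surv
km_estimate <- function(data) {
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  if (!nrow(data)) stop("empty survival dataset", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  below <- which(fit$surv <= 0.5 & fit$n.event > 0)
  median_days <- if (length(below)) fit$time[min(below)] else NA_real_
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv, median_days = median_days, fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time points, median %s days\n", length(x$time),
              if (is.na(x$median_days)) "not reached" else x$median_days))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$fit, xlab = "Days from symptom onset", ylab = "Not yet arrived", ...)
  invisible(x)
}

#' Peto-Peto modified Gehan-Wilcoxon test
#'
#' Weighted log-rank test in the G-rho family with `rho = 1`: at each distinct
#' event time the observed-minus-expected contribution of group A is weighted
#' by the left-continuous Kaplan-Meier estimate of the combined sample, which
#' up-weights early event-time differences — appropriate when arrivals are
#' front-loaded and the question is whether they got *earlier*. The statistic
#' `(sum w (O - E))^2 / sum w^2 V` is referred to chi-squared on 1 df.
#'
#' @param group_a,group_b data frames with `time` and `event` columns.
#' @return list of class `triage_survtest` with `chi_squared`, `p_value`,
#'   `df`, and the weighted `observed_minus_expected` and `variance` sums.
#' @export
peto_peto_test <- function(group_a, group_b) {
  for (g in list(group_a, group_b)) {
    stopifnot(is.data.frame(g), all(c("time", "event") %in% names(g)))
    if (!nrow(g)) stop("both groups must be non-empty", call. = FALSE)
  }
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  grp <- rep(c(1L, 2L), c(nrow(group_a), nrow(group_b)))
  if (!any(event == 1L)) {
    stop("no events in either group; test statistic undefined", call. = FALSE)
  }
  ut <- sort(unique(time[event == 1L]))
  oe <- 0
  v <- 0
  s <- 1  # left-continuous combined-sample KM weight
  for (t in ut) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    dj <- sum(event == 1L & time == t)
    n1 <- sum(at_risk & grp == 1L)
    d1 <- sum(event == 1L & time == t & grp == 1L)
    oe <- oe + s * (d1 - dj * n1 / nj)
    if (nj > 1L) {
      v <- v + s^2 * dj * (nj - dj) * n1 * (nj - n1) / (nj^2 * (nj - 1L))
    }
    s <- s * (1 - dj / nj)
  }
  if (v <= 0) {
    stop("degenerate test: zero variance (all events tied in one pattern)",
         call. = FALSE)
  }
  chi <- oe^2 / v
  structure(list(chi_squared = chi,
                 p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
                 df = 1L, observed_minus_expected = oe, variance = v),
            class = "triage_survtest")
}

#' @export
print.triage_survtest <- function(x, ...) {
  cat(sprintf("Peto-Peto Gehan-Wilcoxon: chi-squared = %.3f on %d df, p = %.4g\n",
              x$chi_squared, x$df, x$p_value))
  invisible(x)
}

#' Six-stratum cohort comparison report
#'
#' For each of the six strata (LOW/MODERATE/HIGH ABCD2 risk group crossed
#' with TIA/minor stroke vs mimic diagnosis), reports per-cohort N and median
#' days to unit arrival (Kaplan-Meier, right-censored at `horizon`), and the
#' Peto-Peto Gehan-Wilcoxon chi-squared and p value comparing the cohorts.
#'
#' @param pre,post [referral_cohort()]s that have been filtered, scored
#'   (`abcd2`/`stratum` columns via [derive_abcd2()]), and carry arrival
#'   timestamps (observed or from [simulate_unit()]/[attach_arrivals()]).
#' @param horizon censoring horizon in days.
#' @param inclusive boundary convention passed to [censor_at()].
#' @return data frame with one row per stratum: `stratum`, `diagnosis`,
#'   `n_pre`, `median_pre`, `n_post`, `median_post`, `chi_squared`, `p_value`,
#'   `note` (flags empty or untestable strata; medians not reached are `NA`).
#' @export
stratified_report <- function(pre, post, horizon = 28L, inclusive = TRUE) {
  surv_frame <- function(cohort) {
    df <- cohort$referrals
    if (!"stratum" %in% names(df)) {
      stop("cohorts must be scored with derive_abcd2() first", call. = FALSE)
    }
    days <- days_to_unit(df$onset_datetime, df$arrival_datetime)
    cbind(censor_at(days, horizon, inclusive),
          data.frame(stratum = as.character(df$stratum),
                     diagnosis = df$diagnosis, stringsAsFactors = FALSE))
  }
  a <- surv_frame(pre)
  b <- surv_frame(post)
  grid <- expand.grid(stratum = STRATA,
                      diagnosis = c("MIMIC", "TIA_MINOR_STROKE"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$stratum, STRATA), grid$diagnosis), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sa <- a[a$stratum == grid$stratum[i] & a$diagnosis == grid$diagnosis[i],
            c("time", "event")]
    sb <- b[b$stratum == grid$stratum[i] & b$diagnosis == grid$diagnosis[i],
            c("time", "event")]
    med <- function(s) if (nrow(s)) km_estimate(s)$median_days else NA_real_
    test <- tryCatch(peto_peto_test(sa, sb), error = function(e) NULL)
    data.frame(
      stratum = grid$stratum[i], diagnosis = grid$diagnosis[i],
      n_pre = nrow(sa), median_pre = med(sa),
      n_post = nrow(sb), median_post = med(sb),
      chi_squared = if (is.null(test)) NA_real_ else test$chi_squared,
      p_value = if (is.null(test)) NA_real_ else test$p_value,
      note = if (is.null(test)) "untestable (empty or event-free stratum)" else "",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export Kaplan-Meier curve coordinates per stratum and cohort
#'
#' @param pre,post scored cohorts with arrivals, as in [stratified_report()].
#' @param horizon,inclusive censoring settings.
#' @return data frame of step-function coordinates: `cohort`, `stratum`,
#'   `diagnosis`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_coordinates <- function(pre, post, horizon = 28L, inclusive = TRUE) {
  one <- function(cohort, tag) {
    df <- cohort$referrals
    days <- days_to_unit(df$onset_datetime, df$arrival_datetime)
    cens <- censor_at(days, horizon, inclusive)
    cens$stratum <- as.character(df$stratum)
    cens$diagnosis <- df$diagnosis
    parts <- split(cens, list(cens$stratum, cens$diagnosis), drop = TRUE)
    do.call(rbind, lapply(names(parts), function(k) {
      km <- km_estimate(parts[[k]])
      data.frame(cohort = tag, stratum = parts[[k]]$stratum[1],
                 diagnosis = parts[[k]]$diagnosis[1], time = km$time,
                 surv = km$surv, n_risk = km$n_risk, n_event = km$n_event,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one(pre, "PRE_QUEUE"), one(post, "POST_QUEUE"))
  rownames(out) <- NULL
  out
}
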