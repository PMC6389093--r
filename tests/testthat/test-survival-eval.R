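# Calendar-day outcomes, censoring, Kaplan-Meier, Peto-Peto, and the report.

test_that("days to unit counts calendar-date boundaries, not 24h periods", {
  expect_equal(days_to_unit(as.POSIXct("2015-03-01 23:50:00", tz = "UTC"),
                            as.POSIXct("2015-03-02 00:10:00", tz = "UTC")), 1L)
  expect_equal(days_to_unit(as.POSIXct("2015-03-01 08:00:00", tz = "UTC"),
                            as.POSIXct("2015-03-01 19:00:00", tz = "UTC")), 0L)
  expect_equal(days_to_unit(as.POSIXct("2015-03-01 12:00:00", tz = "UTC"),
                            as.POSIXct("2015-03-08 09:00:00", tz = "UTC")), 7L)
  expect_error(days_to_unit(as.POSIXct("2015-03-02", tz = "UTC"),
                            as.POSIXct("2015-03-01", tz = "UTC")),
               "precedes")
})

test_that("censoring keeps in-horizon arrivals as events and censors the rest", {
  out <- censor_at(c(5, 28, 30, NA), horizon = 28)
  expect_equal(out$time, c(5L, 28L, 28L, 28L))
  expect_equal(out$event, c(1L, 1L, 0L, 0L))  # day-28 arrival is inclusive
  excl <- censor_at(28, horizon = 28, inclusive = FALSE)
  expect_equal(excl$event, 0L)
})

test_that("censoring at the same horizon twice changes nothing", {
  once <- censor_at(c(1, 10, 27, 28, 40, NA), 28)
  twice <- censor_at(ifelse(once$event == 1L, once$time, NA), 28)
  expect_equal(twice, once)
})

test_that("km matches hand examples including the exact-0.5 median convention", {
  km <- km_estimate(data.frame(time = 1:4, event = 1L))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median_days, 2)

  km2 <- km_estimate(data.frame(time = c(5, 5, 5), event = 1L))
  expect_equal(km2$surv[km2$time == 5], 0)
  expect_equal(km2$median_days, 5)

  km3 <- km_estimate(data.frame(time = c(1, 28), event = c(1L, 0L)))
  expect_equal(km3$surv[km3$time == 1], 0.5)
  expect_equal(km3$median_days, 1)

  km4 <- km_estimate(data.frame(time = c(5, 28, 28), event = c(1L, 0L, 0L)))
  expect_true(is.na(km4$median_days))  # never reaches 0.5: not reached

  expect_error(km_estimate(data.frame(time = integer(0), event = integer(0))),
               "empty")
})

test_that("km equals the brute-force product-limit on every small dataset", {
  # every multiset of <= 5 records over (time in 1..3) x (event in 0/1)
  pool <- expand.grid(time = 1:3, event = 0:1)
  combos <- unlist(lapply(1:5, function(m) {
    utils::combn(nrow(pool) + m - 1, m, simplify = FALSE)
  }), recursive = FALSE)
  checked <- 0L
  for (cmb in combos) {
    idx <- cmb - seq_along(cmb) + 1L  # multiset from combination
    ds <- pool[idx, , drop = FALSE]
    if (!any(ds$event == 1L)) next
    km <- km_estimate(ds)
    orc <- oracle_km(ds$time, ds$event)
    got_surv <- km$surv[km$n_event > 0]
    expect_equal(unname(got_surv), orc$surv, tolerance = 1e-12)
    expect_equal(km$median_days, orc$median,
                 ignore_attr = TRUE)
    checked <- checked + 1L
  }
  expect_gt(checked, 400L)  # 461 multisets minus the event-free ones
})

test_that("identical groups give a null Peto-Peto result", {
  g <- data.frame(time = c(1, 3, 5, 28), event = c(1L, 1L, 1L, 0L))
  res <- peto_peto_test(g, g)
  expect_lt(res$chi_squared, 1e-20)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
  expect_equal(res$df, 1L)
})

test_that("the 6-record toy reproduces the hand-computed weighted log-rank value", {
  a <- data.frame(time = c(1, 3, 28), event = c(1L, 1L, 0L))
  b <- data.frame(time = c(2, 5, 28), event = c(1L, 1L, 0L))
  res <- peto_peto_test(a, b)
  # hand computation with left-continuous KM weights:
  # O-E = 1/2 - 1/3 + 1/3 - 1/6 = 1/3; V = 1/4 + 1/6 + 1/9 + 1/18 = 7/12
  expect_equal(res$observed_minus_expected, 1 / 3, tolerance = 1e-12)
  expect_equal(res$variance, 7 / 12, tolerance = 1e-12)
  expect_equal(res$chi_squared, (1 / 3)^2 / (7 / 12), tolerance = 1e-12)
})

test_that("the statistic agrees with the survival package's G-rho(1) test", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    time <- pmin(rpois(n, 8) + 1L, 28L)
    event <- rbinom(n, 1, 0.8)
    grp <- rbinom(n, 1, 0.5)
    if (length(unique(grp)) < 2 || sum(event) == 0) next
    a <- data.frame(time = time[grp == 0], event = event[grp == 0])
    b <- data.frame(time = time[grp == 1], event = event[grp == 1])
    if (!nrow(a) || !nrow(b)) next
    got <- tryCatch(peto_peto_test(a, b), error = function(e) NULL)
    if (is.null(got)) next
    ref <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 1)
    expect_equal(got$chi_squared, unname(ref$chisq), tolerance = 1e-10)
  }
})

test_that("the test is label-symmetric and order-invariant", {
  a <- data.frame(time = c(1, 2, 9, 28), event = c(1L, 1L, 1L, 0L))
  b <- data.frame(time = c(4, 6, 11, 28), event = c(1L, 1L, 0L, 1L))
  ab <- peto_peto_test(a, b)
  ba <- peto_peto_test(b, a)
  expect_equal(ab$chi_squared, ba$chi_squared, tolerance = 1e-12)
  perm <- peto_peto_test(a[c(3, 1, 4, 2), ], b[c(2, 4, 1, 3), ])
  expect_equal(perm$chi_squared, ab$chi_squared, tolerance = 1e-12)
})

test_that("a strong early-arrival shift is detected", {
  set.seed(11)
  early <- censor_at(rpois(120, 3), 28)
  late <- censor_at(rpois(120, 9), 28)
  expect_lt(peto_peto_test(early, late)$p_value, 0.05)
})

test_that("event-free groups are an undefined-statistic error", {
  g0 <- data.frame(time = c(28, 28), event = c(0L, 0L))
  expect_error(peto_peto_test(g0, g0), "no events")
})

report_fixture <- function(label, offsets) {
  # three strata x two diagnoses, arrivals `offsets` days after onset;
  # form fields chosen so post-era scoring lands in the intended stratum
  fields <- list(
    `2` = list(weakness = 0L, speech = 0L, dur = 5),
    `4` = list(weakness = 0L, speech = 1L, dur = 30),
    `6` = list(weakness = 1L, speech = 0L, dur = 90)
  )
  rows <- list()
  k <- 0
  for (abcd2 in c(2L, 4L, 6L)) {
    for (diag in c("TIA_MINOR_STROKE", "MIMIC")) {
      for (j in seq_along(offsets)) {
        k <- k + 1
        onset <- sprintf("2015-03-%02d 08:00:00", 1 + (k %% 10))
        arrival <- format(as.POSIXct(onset, tz = "UTC") +
                            offsets[j] * 86400, "%Y-%m-%d %H:%M:%S")
        f <- fields[[as.character(abcd2)]]
        rows[[k]] <- toy_referral_row(
          sprintf("%s-%d-%s-%d", label, abcd2, substr(diag, 1, 1), j),
          age = 70, sbp = 150, dbp = 80, dur = f$dur, diabetes = 0L,
          weakness = f$weakness, speech = f$speech,
          abcd = abcd2, diagnosis = diag, cohort = label,
          onset = onset, referral = onset, arrival = arrival)
      }
    }
  }
  derive_abcd2(toy_cohort(rows, label))
}

test_that("the six-stratum report has the full shape and hand-checkable medians", {
  pre <- report_fixture("PRE_QUEUE", c(2, 4, 6, 9))
  post <- report_fixture("POST_QUEUE", c(1, 2, 3, 8))
  rep <- stratified_report(pre, post)
  expect_equal(nrow(rep), 6L)
  expect_setequal(unique(rep$stratum), c("LOW", "MODERATE", "HIGH"))
  expect_true(all(rep$n_pre == 4L) && all(rep$n_post == 4L))
  # per-stratum KM on 4 uncensored records: median = 2nd smallest time
  expect_true(all(rep$median_pre == 4))
  expect_true(all(rep$median_post == 2))
  expect_true(all(rep$note == ""))
})

test_that("comparing a cohort with itself yields null statistics everywhere", {
  pre <- report_fixture("PRE_QUEUE", c(1, 3, 5, 7))
  post <- pre
  post$label <- "POST_QUEUE"
  rep <- stratified_report(pre, post)
  expect_true(all(rep$chi_squared < 1e-20))
})

test_that("empty strata are flagged, not fatal", {
  pre <- report_fixture("PRE_QUEUE", c(2, 4))
  post <- report_fixture("POST_QUEUE", c(1, 3))
  # drop every HIGH record from post
  post$referrals <- post$referrals[post$referrals$stratum != "HIGH", ]
  rep <- stratified_report(pre, post)
  high <- rep[rep$stratum == "HIGH", ]
  expect_true(all(grepl("untestable", high$note)))
  expect_true(all(is.na(high$chi_squared)))
  expect_equal(nrow(rep), 6L)
})
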