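# Weighted score, queue ranking/refresh, and the booking simulator.

single_curve <- function() {
  list(LOW = fit_risk_curve(data.frame(days = 7, risk = 0.10), "LOW"),
       MODERATE = fit_risk_curve(data.frame(days = 7, risk = 0.10),
                                 "MODERATE"),
       HIGH = fit_risk_curve(data.frame(days = 7, risk = 0.10), "HIGH"))
}

test_that("the weighted score is the product of diagnosis and remaining risk", {
  curves <- single_curve()
  expect_equal(weighted_triage_score(0, 6, 1, curves)$w, 0)
  expect_equal(weighted_triage_score(1, 2, 0, curves)$w, 0.10,
               tolerance = 1e-12)
  expect_equal(weighted_triage_score(0.6, 4, 0, curves)$w, 0.06,
               tolerance = 1e-12)
  expect_error(weighted_triage_score(0.5, 4, 0, curves["LOW"]), "MODERATE")
})

test_that("ranking sorts by weight with onset then id tie-breaks, excluding booked", {
  onset <- parse_dt <- function(x) as.POSIXct(x, tz = "UTC")
  entries <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    w = c(0.1, 0.3, 0.2, 0.2, 0.2),
    onset_datetime = parse_dt(c("2015-01-05", "2015-01-05", "2015-01-03",
                                "2015-01-01", "2015-01-03")),
    booked = c(FALSE, FALSE, FALSE, FALSE, FALSE))
  st <- queue_state("2015-01-06 09:00:00", entries)
  # 0.3 first; the 0.2 group ordered by onset (d, then c/e by id); 0.1 last
  expect_equal(rank_referrals(st), c("b", "d", "c", "e", "a"))
  st2 <- mark_booked(st, c("b", "d"))
  expect_equal(rank_referrals(st2), c("c", "e", "a"))
  st3 <- mark_booked(st2, c("c", "e", "a"))
  expect_equal(rank_referrals(st3), character(0))
})

test_that("refreshing at the same instant is a no-op and the clock cannot regress", {
  curves <- single_curve()
  df <- data.frame(id = c("a", "b"),
                   onset_datetime = as.POSIXct(c("2015-01-05 08:00:00",
                                                 "2015-01-05 12:00:00"),
                                               tz = "UTC"),
                   abcd2 = c(5L, 2L), p_tia = c(0.8, 0.4))
  st <- refresh_scores(queue_state("2015-01-06 09:00:00"), df, curves,
                       "2015-01-06 09:00:00")
  st_again <- refresh_scores(st, df, curves, "2015-01-06 09:00:00")
  expect_equal(st_again$entries, st$entries)
  expect_error(refresh_scores(st, df, curves, "2015-01-05 09:00:00"),
               "backwards")
})

test_that("advancing the clock never raises any unbooked weight", {
  curves <- fit_risk_curves()
  df <- data.frame(id = sprintf("r%02d", 1:8),
                   onset_datetime = as.POSIXct("2015-01-04", tz = "UTC") +
                     3600 * (1:8),
                   abcd2 = c(1L, 3L, 4L, 5L, 6L, 7L, 2L, 4L),
                   p_tia = seq(0.2, 0.9, by = 0.1))
  st <- refresh_scores(queue_state("2015-01-05 09:00:00"), df, curves,
                       "2015-01-05 09:00:00")
  for (h in c(6, 24, 72)) {
    st2 <- refresh_scores(st, df, curves,
                          st$now + h * 3600)
    expect_true(all(st2$entries$w <= st$entries$w + 1e-12))
    st <- st2
  }
})

test_that("new referrals insert exactly one unbooked entry", {
  curves <- single_curve()
  df <- data.frame(id = "a",
                   onset_datetime = as.POSIXct("2015-01-05", tz = "UTC"),
                   abcd2 = 4L, p_tia = 0.5)
  st <- refresh_scores(queue_state("2015-01-06 09:00:00"), df, curves,
                       "2015-01-06 09:00:00")
  df2 <- rbind(df, data.frame(id = "b",
                              onset_datetime = as.POSIXct("2015-01-06",
                                                          tz = "UTC"),
                              abcd2 = 6L, p_tia = 0.9))
  st2 <- refresh_scores(st, df2, curves, "2015-01-06 10:00:00")
  expect_equal(nrow(st2$entries), 2L)
  expect_equal(sum(!st2$entries$booked), 2L)
})

# --- simulator --------------------------------------------------------------

sim_stream <- function(n = 20, start = "2015-03-02", spread_hours = 6,
                       label = "POST_QUEUE") {
  # referrals land on consecutive calendar days at 08:00 + jitter
  onset <- as.POSIXct(start, tz = "UTC") + 86400 * ((seq_len(n) - 1) %% 14) +
    3600 * 2
  referral <- onset + spread_hours * 3600
  rows <- lapply(seq_len(n), function(i) {
    toy_referral_row(sprintf("s%03d", i),
                     age = c(55, 75)[1 + i %% 2],
                     weakness = i %% 2L, dur = c(5, 90)[1 + i %% 2],
                     onset = format(onset[i], "%Y-%m-%d %H:%M:%S"),
                     referral = format(referral[i], "%Y-%m-%d %H:%M:%S"),
                     diagnosis = c("MIMIC", "TIA_MINOR_STROKE")[1 + i %% 2],
                     cohort = label)
  })
  rc <- toy_cohort(rows, label)
  rc <- derive_abcd2(rc)
  rc$referrals$p_tia <- ifelse(rc$referrals$diagnosis == "TIA_MINOR_STROKE",
                               0.8, 0.3)
  rc
}

test_that("uncongested FIFO books every referral on its first post-triage business day", {
  rc <- sim_stream(10)
  arr <- simulate_unit(rc, unit_config(daily_capacity = 50L), "FIFO")
  expect_true(all(arr$arrived == 1L))
  # appointment is the next business day after the entry session
  for (i in seq_len(nrow(arr))) {
    expected <- arr$entry_date[i] + 1
    while (format(expected, "%u") %in% c("6", "7")) expected <- expected + 1
    expect_equal(as.Date(arr$appointment_datetime[i]), expected)
  }
})

test_that("weekend faxes are first triaged on Monday", {
  rows <- list(
    toy_referral_row("sat", onset = "2015-03-07 08:00:00",   # Saturday
                     referral = "2015-03-07 10:00:00"),
    toy_referral_row("sun", onset = "2015-03-08 08:00:00",
                     referral = "2015-03-08 10:00:00"))
  rc <- derive_abcd2(toy_cohort(rows))
  rc$referrals$p_tia <- 0.5
  arr <- simulate_unit(rc, unit_config(daily_capacity = 5L), "FIFO")
  expect_true(all(arr$entry_date == as.Date("2015-03-09")))  # Monday
  expect_true(all(as.Date(arr$appointment_datetime) >= as.Date("2015-03-10")))
})

test_that("capacity is conserved: no day over capacity, nobody booked twice", {
  curves <- fit_risk_curves()
  rc <- sim_stream(40)
  for (policy in c("FIFO", "ABCD_DESC", "WEIGHTED_QUEUE")) {
    arr <- simulate_unit(rc, unit_config(daily_capacity = 2L), policy,
                         curves = curves)
    booked <- arr[!is.na(arr$appointment_datetime), ]
    expect_equal(anyDuplicated(booked$id), 0L)
    per_day <- table(as.Date(booked$appointment_datetime))
    expect_true(all(per_day <= 2L))
    sessions <- table(booked$booked_date)
    expect_true(all(sessions <= 2L))
    # appointments only on business days
    expect_true(all(!format(as.Date(booked$appointment_datetime),
                            "%u") %in% c("6", "7")))
  }
})

test_that("total throughput is policy-invariant; policies permute the same slots", {
  curves <- fit_risk_curves()
  rc <- sim_stream(30)
  end <- as.Date("2015-03-20")  # cut the horizon so congestion persists
  slots <- lapply(c("ABCD_DESC", "WEIGHTED_QUEUE", "FIFO"), function(p) {
    arr <- simulate_unit(rc, unit_config(daily_capacity = 2L), p,
                         curves = curves, sim_end = end)
    sort(arr$appointment_datetime[!is.na(arr$appointment_datetime)])
  })
  expect_equal(slots[[1]], slots[[2]])
  expect_equal(slots[[1]], slots[[3]])
})

test_that("under congestion the weighted queue serves high-weight referrals sooner", {
  curves <- fit_risk_curves()
  delays <- vapply(1:5, function(s) {
    rc <- sim_stream(36 + s)
    arr <- simulate_unit(rc, unit_config(daily_capacity = 2L),
                         "WEIGHTED_QUEUE", curves = curves)
    df <- merge(rc$referrals, arr, by = "id")
    wait <- as.numeric(difftime(df$appointment_datetime, df$referral_datetime,
                                units = "days"))
    mean(wait[df$p_tia > 0.5], na.rm = TRUE) -
      mean(wait[df$p_tia < 0.5], na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(delays), 0)
})

test_that("referrals dated after the simulation end are excluded with a warning", {
  rc <- sim_stream(6)
  expect_warning(
    arr <- simulate_unit(rc, unit_config(5L), "FIFO",
                         sim_end = as.Date("2015-03-04")),
    "excluded")
})

test_that("the simulator is deterministic given seed and inputs", {
  curves <- fit_risk_curves()
  rc <- sim_stream(25)
  a <- simulate_unit(rc, unit_config(2L), "WEIGHTED_QUEUE", seed = 9,
                     curves = curves, dropout_prob = 0.2)
  b <- simulate_unit(rc, unit_config(2L), "WEIGHTED_QUEUE", seed = 9,
                     curves = curves, dropout_prob = 0.2)
  expect_identical(a, b)
})
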