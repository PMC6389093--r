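# Imputation, ABCD2 component scoring, legacy conversion, strata.

test_that("mean substitution fills only missing age/BP and records what it did", {
  rows <- list(toy_referral_row("A", age = NA),
               toy_referral_row("B"),
               toy_referral_row("C", sbp = NA, dbp = NA))
  rc <- impute_missing(toy_cohort(rows))
  df <- rc$referrals
  expect_equal(df$age_years[1], 68.277)
  expect_equal(df$imputed_fields[1], "age_years")
  expect_equal(df$age_years[2], 70)
  expect_equal(df$imputed_fields[2], "")
  expect_equal(df$systolic_mmHg[3], 141.606)
  expect_equal(df$diastolic_mmHg[3], 78.042)
  expect_equal(df$imputed_fields[3], "systolic_mmHg,diastolic_mmHg")
  # everything else untouched
  expect_equal(df$duration_minutes, rep(70, 3))
})

test_that("worked component examples score as expected", {
  rows <- list(
    toy_referral_row("max", age = 70, sbp = 150, dbp = 80, weakness = 1L,
                     dur = 70, diabetes = 1L),
    toy_referral_row("min", age = 50, sbp = 120, dbp = 70, weakness = 0L,
                     speech = 0L, dur = 5, diabetes = 0L),
    toy_referral_row("imputed-age", age = 68.277, sbp = 120, dbp = 70,
                     weakness = 0L, dur = 5, diabetes = 0L)
  )
  sc <- compute_abcd2(toy_cohort(rows))
  expect_equal(unlist(sc[1, c("age_pts", "bp_pts", "clinical_pts",
                              "duration_pts", "diabetes_pts")]),
               c(age_pts = 1L, bp_pts = 1L, clinical_pts = 2L,
                 duration_pts = 2L, diabetes_pts = 1L))
  expect_equal(sc$abcd2, c(7L, 0L, 1L))  # imputed 68.277 >= 60 scores the age point
})

test_that("scoring matches the brute-force rule oracle over a threshold-spanning grid", {
  grid <- expand.grid(age = c(50, 59, 59.999, 60, 61, 75),
                      sbp = c(120, 139, 140, 141),
                      dbp = c(70, 89, 90, 95),
                      weakness = 0:1, speech = 0:1,
                      dur = c(0, 9, 9.5, 10, 59, 60, 61),
                      diabetes = 0:1)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    toy_referral_row(sprintf("g%05d", i), age = grid$age[i],
                     sbp = grid$sbp[i], dbp = grid$dbp[i],
                     weakness = grid$weakness[i], speech = grid$speech[i],
                     dur = grid$dur[i], diabetes = grid$diabetes[i])
  })
  sc <- compute_abcd2(toy_cohort(rows))
  expected <- mapply(oracle_abcd2, grid$age, grid$sbp, grid$dbp,
                     grid$weakness, grid$speech, grid$dur, grid$diabetes)
  expect_equal(sc$abcd2, as.integer(expected))
  expect_true(all(sc$abcd2 >= 0L & sc$abcd2 <= 7L))
  expect_equal(sc$abcd2,
               sc$age_pts + sc$bp_pts + sc$clinical_pts + sc$duration_pts +
                 sc$diabetes_pts)
})

test_that("raising any single input across its threshold never lowers the score", {
  base <- list(age = 50, sbp = 120, dbp = 70, weakness = 0L, speech = 0L,
               dur = 5, diabetes = 0L)
  bumps <- list(age = 65, sbp = 145, dbp = 95, weakness = 1L, speech = 1L,
                dur = 65, diabetes = 1L)
  score_of <- function(v) {
    compute_abcd2(toy_cohort(list(do.call(
      toy_referral_row, c(list("x"), v)))))$abcd2
  }
  for (field in names(bumps)) {
    bumped <- base
    bumped[[field]] <- bumps[[field]]
    expect_gte(score_of(bumped), score_of(base))
  }
})

test_that("missing duration blocks scoring with an informative error", {
  rc <- toy_cohort(list(toy_referral_row("A", dur = NA)))
  expect_error(compute_abcd2(rc), "duration_minutes.*id A")
  expect_error(compute_abcd2(toy_cohort(list(toy_referral_row("B", age = NA)))),
               "age_years")
})

test_that("legacy ABCD converts by adding diabetes status, within range", {
  expect_equal(abcd_to_abcd2(3L, 1L), 4L)
  expect_equal(abcd_to_abcd2(3L, 0L), 3L)
  expect_equal(abcd_to_abcd2(6L, 1L), 7L)
  expect_error(abcd_to_abcd2(7L, 0L), "\\[0, 6\\]")
  expect_error(abcd_to_abcd2(-1L, 0L), "\\[0, 6\\]")
})

test_that("conversion and direct scoring are mutually consistent", {
  grid <- expand.grid(age = c(55, 65), sbp = c(120, 150), weakness = 0:1,
                      dur = c(5, 30, 90), diabetes = 0:1)
  for (i in seq_len(nrow(grid))) {
    sc <- compute_abcd2(toy_cohort(list(toy_referral_row(
      "x", age = grid$age[i], sbp = grid$sbp[i], dbp = 70,
      weakness = grid$weakness[i], dur = grid$dur[i],
      diabetes = grid$diabetes[i]))))
    expect_equal(abcd_to_abcd2(sc$abcd2 - sc$diabetes_pts, grid$diabetes[i]),
                 sc$abcd2)
  }
})

test_that("risk strata partition 0-7 as LOW 0-3 / MODERATE 4-5 / HIGH 6-7", {
  expect_equal(as.character(risk_stratum(0:7)),
               c(rep("LOW", 4), rep("MODERATE", 2), rep("HIGH", 2)))
  expect_error(risk_stratum(8L), "\\[0, 7\\]")
})

test_that("era-appropriate derivation uses recorded ABCD pre and form fields post", {
  pre <- toy_cohort(list(toy_referral_row("A", abcd = 4L, diabetes = 1L,
                                          cohort = "PRE_QUEUE")),
                    "PRE_QUEUE")
  expect_equal(derive_abcd2(pre)$referrals$abcd2, 5L)

  post <- toy_cohort(list(toy_referral_row("B", age = NA, sbp = 150, dbp = 80,
                                           weakness = 1L, dur = 70,
                                           diabetes = 1L)))
  # imputed age 68.277 -> 1 + 1 + 2 + 2 + 1 = 7
  expect_equal(derive_abcd2(post)$referrals$abcd2, 7L)
})
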