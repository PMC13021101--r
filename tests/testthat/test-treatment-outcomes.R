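cfg <- hlh_config()
t0 <- as.POSIXct("2020-06-01 08:00", tz = "UTC")

therapy_extract <- function() {
  ehr_extract(
    patients = tibble::tibble(
      patient_id = c("p1", "p2", "p3"), sex = "male",
      birth_date = as.Date("2012-01-01"), death_date = as.Date(NA)),
    encounters = tibble::tibble(
      encounter_id = c("idx1", "idx2", "idx3", "later3"),
      patient_id = c("p1", "p2", "p3", "p3"),
      encounter_class = "inpatient",
      start = c(t0, t0, t0, t0 + 60 * 86400),
      end = c(t0 + 10 * 86400, t0 + 10 * 86400, t0 + 10 * 86400,
              t0 + 62 * 86400),
      admission_diagnosis = NA_character_, discharged_alive = TRUE),
    medications = tibble::tibble(
      patient_id = c("p1", "p2", "p2", "p3"),
      encounter_id = c("idx1", "idx2", "idx2", "later3"),
      generic_name = c("Dexamethasone", "methylprednisolone", "anakinra",
                       "etoposide"),
      administered_at = c(t0 + 86400, t0 + 86400, t0 + 2 * 86400,
                          t0 + 61 * 86400),
      is_chemotherapy = c(FALSE, FALSE, FALSE, TRUE)))
}

test_that("therapy exposure is scoped to the index episode window", {
  idx <- tibble::tibble(patient_id = c("p1", "p2", "p3"),
                        index_encounter = c("idx1", "idx2", "idx3"))
  expo <- classify_therapy(therapy_extract(), idx, cfg)
  e1 <- expo[expo$patient_id == "p1", ]
  expect_true(e1$hlh_directed_index_encounter)  # case-insensitive match
  expect_equal(e1$therapy_pattern, "steroid_only")
  e2 <- expo[expo$patient_id == "p2", ]
  expect_equal(e2$therapy_pattern, "steroid_plus_other")
  # etoposide given outside the index episode: any yes, index no
  e3 <- expo[expo$patient_id == "p3", ]
  expect_false(e3$hlh_directed_index_encounter)
  expect_true(e3$hlh_directed_any_encounter)
  expect_true(e3$chemo_any_encounter)
  expect_equal(e3$therapy_pattern, "none")
  # *_index implies *_any; the OR columns reconcile
  expect_true(all(!expo$chemo_index_encounter | expo$chemo_any_encounter))
  expect_equal(expo$chemo_or_hlh_any,
               expo$chemo_any_encounter | expo$hlh_directed_any_encounter)
})

test_that("outcome derivation applies the stated boundary conventions", {
  start <- as.POSIXct("2020-06-01 08:00", tz = "UTC")
  mk <- function(death, end_days = 10, dx_at = NULL) {
    args <- list(
      patients = tibble::tibble(patient_id = "p", sex = "female",
                                birth_date = as.Date("2019-12-15"),
                                death_date = death),
      encounters = tibble::tibble(
        encounter_id = "e", patient_id = "p", encounter_class = "inpatient",
        start = start, end = start + end_days * 86400,
        admission_diagnosis = "fever", discharged_alive = TRUE),
      sct = tibble::tibble(patient_id = "p",
                           date = as.Date(start) + 100))
    if (!is.null(dx_at)) {
      args$diagnoses <- tibble::tibble(
        patient_id = "p", icd10_code = "D76.1", noted_at = dx_at,
        encounter_id = NA_character_)
    }
    ex <- do.call(ehr_extract, args)
    asg <- tibble::tibble(patient_id = "p", in_criteria_cohort = TRUE,
                          index_encounter_criteria = "e")
    derive_outcomes(ex, asg, cfg)
  }
  # death exactly on day 30 counts (inclusive anchor at episode start)
  o30 <- mk(as.Date(start) + 30)
  expect_true(o30$death_within_30d)
  expect_false(o30$in_hospital_death)
  # death on day 40, after discharge: neither outcome
  o40 <- mk(as.Date(start) + 40)
  expect_false(o40$death_within_30d)
  expect_false(o40$in_hospital_death)
  # death during the stay counts for both
  o5 <- mk(as.Date(start) + 5)
  expect_true(o5$in_hospital_death && o5$death_within_30d)
  expect_equal(o5$los_days, 10)
  expect_true(o5$sct_after)
  expect_equal(o5$age_group, "0-<1")
  # ICD timing relative to the index episode
  expect_equal(mk(as.Date(NA), dx_at = start - 30 * 86400)$icd_timing,
               "before")
  expect_equal(mk(as.Date(NA), dx_at = start + 86400)$icd_timing, "during")
  expect_equal(mk(as.Date(NA), dx_at = start + 20 * 86400)$icd_timing,
               "after")
  expect_equal(mk(as.Date(NA))$icd_timing, "never")
})

test_that("risk differences use round-first arithmetic with a Wald interval", {
  rd <- risk_difference(29, 193, 7, 52)
  expect_equal(rd$rate1, 15.0)
  expect_equal(rd$rate2, 13.5)
  expect_equal(rd$diff, 1.5)
  expect_equal(rd$diff_unrounded, 100 * (29 / 193 - 7 / 52))
  z <- risk_difference(0, 10, 0, 10)
  expect_equal(z$diff, 0)
  expect_equal(c(z$conf_low, z$conf_high), c(0, 0))
  expect_error(risk_difference(1, 0, 1, 5))
  # unrounded difference equals direct proportion subtraction
  set.seed(5)
  for (rep in 1:25) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    rd <- risk_difference(x1, n1, x2, n2)
    expect_equal(rd$diff_unrounded, 100 * (x1 / n1 - x2 / n2))
    expect_equal(rd$diff, round(100 * x1 / n1, 1) - round(100 * x2 / n2, 1))
    expect_lte(rd$conf_low, rd$diff_unrounded)
    expect_gte(rd$conf_high, rd$diff_unrounded)
  }
})

test_that("median difference is seeded and brackets its point estimate", {
  md <- median_difference(c(30, 33.4, 40), c(18, 20.8, 25), n_boot = 500,
                          seed = 3)
  expect_equal(md$diff, 33.4 - 20.8)
  md2 <- median_difference(c(30, 33.4, 40), c(18, 20.8, 25), n_boot = 500,
                           seed = 3)
  expect_equal(md, md2)
  same <- median_difference(1:9, 1:9, n_boot = 200, seed = 1)
  expect_equal(same$diff, 0)
  expect_error(median_difference(numeric(), 1:3), "empty")
  set.seed(8)
  for (rep in 1:20) {
    x <- rlnorm(sample(5:40, 1), 3, 1)
    y <- rlnorm(sample(5:40, 1), 2.5, 1)
    md <- median_difference(x, y, n_boot = 300, seed = rep)
    expect_true(md$conf_low <= md$diff + 1e-9 &&
                  md$conf_high >= md$diff - 1e-9)
  }
})

test_that("the test dispatcher picks Wilcoxon, chi-square or Fisher", {
  sym <- two_group_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$p_value, 1.0, tolerance = 1e-12)
  f <- two_group_test(matrix(c(1, 9, 8, 2), 2))
  expect_equal(f$method, "Fisher exact")
  expect_equal(f$p_value, oracle_fisher_p(1, 8, 9, 2), tolerance = 1e-10)
  big <- two_group_test(matrix(c(30, 40, 50, 35), 2))
  expect_equal(big$method, "chi-square")
  w <- two_group_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(w$method, "Wilcoxon rank-sum")
  expect_gt(w$p_value, 0.9)
  dg <- two_group_test(matrix(c(0, 0, 3, 4), 2))
  expect_equal(dg$method, "not applicable")
  expect_true(is.na(dg$p_value))
  kx2 <- two_group_test(matrix(c(10, 20, 30, 12, 18, 33), ncol = 2))
  expect_equal(kx2$method, "chi-square")
})

test_that("screening summary handles edge cases and partitions cleanly", {
  prof <- get_table3_profiles()
  scr <- build_screening_cohort(prof, cfg)
  ss <- screening_summary(scr)
  tb <- tibble::as_tibble(ss)
  # strata partition the total for every criterion row
  for (cr in unique(tb$criterion)) {
    expect_equal(tb$n[tb$stratum == "all" & tb$criterion == cr],
                 tb$n[tb$stratum == "meets_threshold" & tb$criterion == cr] +
                   tb$n[tb$stratum == "below_threshold" & tb$criterion == cr])
  }
  all_meet <- screening_summary(scr[scr$meets_threshold, ])
  expect_equal(attr(all_meet, "nns"), 1)
  none <- screening_summary(scr[0, ])
  expect_true(is.na(attr(none, "nns")))
  expect_equal(attr(none, "total"), 0)
})

test_that("group comparison reproduces fixture counts and is antisymmetric", {
  fx <- get_table2_fixture()
  prof <- get_table2_profiles()
  asg <- assign_phenotypes(fx, prof, cfg)
  cmp <- compare_groups(fx, asg, prof, config = cfg, n_boot = 200, seed = 1)
  expect_equal(unname(cmp$groups), c(193, 52))
  s <- cmp$summary
  crit <- s[s$variable == "criterion", ]
  expect_equal(crit$n_treated[crit$level == "ferritin"], 190)
  expect_equal(crit$n_untreated[crit$level == "scd25"], 26)
  expect_equal(crit$measured_treated[crit$level == "scd25"], 135)
  expect_equal(crit$measured_untreated[crit$level == "low_nk"], 7)
  # top-5 admission diagnoses by cohort frequency, ties lexical
  adx <- s[s$variable == "admission_diagnosis", ]
  expect_setequal(adx$level, c("fever", "sepsis", "leukemia",
                               "acute lymphoblastic leukemia", "neutropenia"))
  expect_equal(adx$n_treated[adx$level == "sepsis"], 9)
  expect_equal(adx$pct_treated[adx$level == "sepsis"], 4.7)
  expect_equal(adx$n_untreated[adx$level == "sepsis"], 7)
  tim <- s[s$variable == "icd_timing", ]
  expect_equal(tim$n_treated, c(8, 55, 9, 121))
  expect_equal(tim$n_untreated, c(0, 3, 2, 47))
  svc <- s[s$variable == "service", ]
  expect_equal(svc$n_treated[svc$level == "oncology"], 109)
  # exchanging the group roles negates the risk differences
  expect_equal(cmp$effects$estimate[1],
               -risk_difference(7, 52, 29, 193)$diff)
  expect_equal(cmp$effects$estimate[2],
               -risk_difference(8, 52, 32, 193)$diff)
})
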