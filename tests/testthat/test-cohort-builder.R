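cfg <- hlh_config()
t0 <- as.POSIXct("2020-06-01 08:00", tz = "UTC")

cohort_extract <- function() {
  ehr_extract(
    patients = tibble::tibble(
      patient_id = c("p1", "p2", "p3"), sex = "female",
      birth_date = as.Date("2015-01-01"), death_date = as.Date(NA)),
    encounters = tibble::tibble(
      encounter_id = c("e1a", "e1b", "e2", "e3"),
      patient_id = c("p1", "p1", "p2", "p3"),
      encounter_class = "inpatient",
      start = c(t0, t0 + 30 * 86400, t0, t0),
      end = c(t0 + 5 * 86400, t0 + 35 * 86400, t0 + 5 * 86400,
              t0 + 5 * 86400),
      admission_diagnosis = NA_character_, discharged_alive = TRUE),
    diagnoses = tibble::tibble(
      patient_id = c("p1", "p1", "p2", "p3", "p3"),
      icd10_code = c("D76.1", "D76.1", "D76.3", "d76.2 ", "D76.1"),
      noted_at = c(t0 + 31 * 86400, t0 + 2 * 86400, t0 + 86400,
                   t0 + 86400, as.POSIXct("2017-05-01", tz = "UTC")),
      encounter_id = c("e1b", "e1a", "e2", NA, NA)),
    treatment_plans = tibble::tibble(
      patient_id = c("p2", "p3", "p1"),
      display_name = c("HLH-94 salvage", "Hodgkin ABVD", ""),
      protocol_name = c("", "", "Haemophagocytosis protocol"),
      applied_at = c(t0 + 86400, t0 + 86400,
                     as.POSIXct("2016-01-01", tz = "UTC")),
      encounter_id = c("e2", "e3", NA)))
}

test_that("ICD cohort takes exact in-window codes, indexed at the first", {
  icd <- build_icd_cohort(cohort_extract(), cfg)
  expect_setequal(icd$patient_id, c("p1", "p3"))  # p2's D76.3 excluded
  # p1 has two codes: the earlier one (day 2, on e1a) wins
  expect_equal(icd$index_encounter_icd[icd$patient_id == "p1"], "e1a")
  # p3's 2017 code predates the window; the in-window lower-case code counts
  expect_equal(as.Date(icd$first_code_at[icd$patient_id == "p3"]),
               as.Date(t0 + 86400))
  # unlinked code resolves to the encounter containing its timestamp
  expect_equal(icd$index_encounter_icd[icd$patient_id == "p3"], "e3")
})

test_that("plan cohort matches name substrings case-insensitively, in window", {
  plan <- build_plan_cohort(cohort_extract(), cfg)
  # p2 via display 'HLH-94', p1's plan predates the window, p3 no match
  expect_equal(plan$patient_id, "p2")
  expect_equal(plan$index_encounter_plan, "e2")
  ex2 <- cohort_extract()
  ex2$treatment_plans$applied_at[3] <- t0 + 86400
  plan2 <- build_plan_cohort(ex2, cfg)
  expect_setequal(plan2$patient_id, c("p1", "p2"))  # spelling variant matches
})

test_that("criteria cohort picks the max-count encounter, earliest on ties", {
  prof <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p2", "p3"),
    encounter_id = c("A", "B", "C", "D", "E"),
    episode_start = as.POSIXct(c("2020-01-01", "2020-02-01", "2020-03-01",
                                 "2020-01-15", "2020-01-01"), tz = "UTC"),
    episode_end = episode_start + 86400,
    n_criteria = c(4L, 6L, 5L, 5L, 4L))
  crit <- build_criteria_cohort(prof, cfg)
  expect_equal(crit$index_encounter_criteria[crit$patient_id == "p1"], "B")
  expect_true(crit$in_criteria_cohort[crit$patient_id == "p1"])
  # tie at 5: earlier start (D) wins
  expect_equal(crit$index_encounter_criteria[crit$patient_id == "p2"], "D")
  # below threshold: non-member, but max count recorded
  expect_false(crit$in_criteria_cohort[crit$patient_id == "p3"])
  expect_equal(crit$max_criteria_count[crit$patient_id == "p3"], 4L)
  # invariance to row enumeration order
  crit2 <- build_criteria_cohort(prof[sample(nrow(prof)), ], cfg)
  expect_equal(crit, crit2)
})

test_that("overlap regions partition the union and match the oracle", {
  mk <- function(a, b, c_) tibble::tibble(
    patient_id = sprintf("x%03d", seq_along(a)),
    in_icd_cohort = a, in_plan_cohort = b, in_criteria_cohort = c_)
  disjoint <- mk(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                 c(FALSE, FALSE, TRUE))
  ov <- compute_overlap(disjoint)
  expect_equal(ov$n[ov$region == "any"], 3)
  expect_equal(sum(ov$n[ov$region != "any"]), 3)
  all3 <- mk(TRUE, TRUE, TRUE)
  expect_equal(compute_overlap(all3)$n[1:8], c(0, 0, 0, 0, 0, 0, 1, 1))

  set.seed(99)
  rnd <- mk(runif(50) < .4, runif(50) < .2, runif(50) < .5)
  ov2 <- compute_overlap(rnd)
  oracle <- oracle_overlap(rnd)
  expect_equal(setNames(ov2$n, ov2$region), oracle)
  # regions sum to the union; pairwise cohort sizes recoverable
  expect_equal(sum(ov2$n[ov2$region != "any"]), oracle[["any"]])
  expect_equal(ov2$n[ov2$region == "icd_only"] +
                 ov2$n[ov2$region == "icd_plan"] +
                 ov2$n[ov2$region == "icd_criteria"] +
                 ov2$n[ov2$region == "all_three"],
               sum(rnd$in_icd_cohort))
})

test_that("screening rows always carry both entry criteria", {
  prof <- get_table3_profiles()
  scr <- build_screening_cohort(prof, cfg)
  expect_true(all(scr$ferritin))
  expect_true(all(scr$fever))
  expect_equal(scr$meets_threshold, scr$n_criteria >= 5)
  # encounter-level: patients with two qualifying encounters give two rows
  expect_gt(max(table(scr$patient_id)), 1)
})
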