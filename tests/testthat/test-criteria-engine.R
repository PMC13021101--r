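cfg <- hlh_config()
t0 <- as.POSIXct("2021-01-01 08:00", tz = "UTC")

mk_temps <- function(mins, temps, route = "oral") {
  tibble::tibble(patient_id = "p", encounter_id = "e",
                 taken_at = t0 + mins * 60, temperature_c = temps,
                 route = route)
}
mk_labs <- function(analyte, value, at = t0) {
  tibble::tibble(patient_id = "p", encounter_id = "e", analyte = analyte,
                 value = value, collected_at = at)
}

test_that("fever rule: single spike or sustained 60-minute run", {
  expect_true(fever_met(mk_temps(0, 38.3), cfg))           # clause (a), inclusive
  expect_false(fever_met(mk_temps(0, 38.2), cfg))          # single sub-38.3
  expect_true(fever_met(mk_temps(c(0, 65), c(38.1, 38.1)), cfg))   # clause (b)
  expect_false(fever_met(mk_temps(c(0, 30, 65), c(38.1, 37.5, 38.1)), cfg),
               info = "run broken by an intervening sub-38.0 reading")
  expect_false(fever_met(mk_temps(c(0, 59), c(38.2, 38.0)), cfg),
               info = "59-minute span is too short")
  expect_true(fever_met(mk_temps(c(0, 30, 65), c(38.0, 38.2, 38.1)), cfg))
  expect_false(fever_met(mk_temps(0, 39, route = "other"), cfg),
               info = "non-oral routes are ignored")
  expect_false(fever_met(mk_temps(numeric(), numeric()), cfg))
})

test_that("cytopenia needs two lineages, with the infant hemoglobin cutoff", {
  birth <- as.Date("2010-01-01")
  expect_true(cytopenia_met(mk_labs(c("hemoglobin", "platelets"), c(85, 90)),
                            birth, cfg))
  expect_false(cytopenia_met(mk_labs("platelets", 90), birth, cfg))
  # 95 g/L counts as low only under the infant (<28 d) threshold
  infant_birth <- as.Date(t0) - 10
  expect_true(cytopenia_met(
    dplyr::bind_rows(mk_labs("hemoglobin", 95), mk_labs("platelets", 90)),
    infant_birth, cfg))
  expect_false(cytopenia_met(
    dplyr::bind_rows(mk_labs("hemoglobin", 95), mk_labs("platelets", 90)),
    as.Date(t0) - 40, cfg))
  # thresholds are strict '<'
  expect_false(cytopenia_met(
    dplyr::bind_rows(mk_labs("hemoglobin", 90), mk_labs("platelets", 100)),
    birth, cfg))
  # same-day toggle: lows on different days stop counting together
  spread <- dplyr::bind_rows(mk_labs("hemoglobin", 80, t0),
                             mk_labs("platelets", 50, t0 + 3 * 86400))
  expect_true(cytopenia_met(spread, birth, cfg))
  strict <- hlh_config(strict_cytopenia_same_day = TRUE)
  expect_false(cytopenia_met(spread, birth, strict))
  expect_true(cytopenia_met(
    dplyr::bind_rows(mk_labs("hemoglobin", 80, t0),
                     mk_labs("platelets", 50, t0 + 3600)), birth, strict))
})

test_that("threshold criteria use the stated inclusivity; missing test is not abnormal", {
  expect_true(ferritin_met(mk_labs("ferritin", 500), cfg))    # inclusive >=
  expect_false(ferritin_met(mk_labs("ferritin", 499.9), cfg))
  expect_true(tg_fib_met(mk_labs("fibrinogen", 1.5), cfg))    # inclusive <=
  expect_true(tg_fib_met(mk_labs("triglycerides", 3.0), cfg)) # inclusive >=
  expect_false(tg_fib_met(mk_labs("triglycerides", 2.9), cfg))
  expect_true(scd25_met(mk_labs("scd25", 2400), cfg))
  expect_true(nk_met(mk_labs("nk_activity", 1), cfg))
  expect_false(nk_met(mk_labs("nk_activity", 0), cfg))
  none <- mk_labs("ferritin", 1)[0, ]
  expect_false(ferritin_met(none, cfg))
  expect_false(scd25_met(none, cfg))
  expect_false(tg_fib_met(none, cfg))
})

test_that("episode windows truncate open stays and same-day outpatients", {
  enc <- tibble::tibble(
    encounter_id = c("a", "b", "c"), patient_id = "p",
    encounter_class = c("inpatient", "inpatient", "outpatient"),
    start = rep(t0, 3),
    end = c(t0 + 9 * 86400, NA, NA),
    admission_diagnosis = NA_character_, discharged_alive = NA)
  w <- episode_window(enc, cfg)
  expect_equal(w$episode_end[1], t0 + 9 * 86400)
  expect_equal(as.Date(w$episode_end[2]), cfg$window_end)
  expect_equal(w$episode_end[3],
               as.POSIXct("2021-01-01 23:59", tz = "UTC"))
})

test_that("evaluate_encounter assembles counts and rejects out-of-window episodes", {
  start <- as.POSIXct("2021-05-01 08:00", tz = "UTC")
  ex <- ehr_extract(
    patients = tibble::tibble(patient_id = "p", sex = "female",
                              birth_date = as.Date("2015-01-01"),
                              death_date = as.Date(NA)),
    encounters = tibble::tibble(
      encounter_id = c("e", "old"), patient_id = "p",
      encounter_class = "inpatient",
      start = c(!!start, as.POSIXct("2017-01-01 08:00", tz = "UTC")),
      end = c(!!start + 10 * 86400, as.POSIXct("2017-01-05", tz = "UTC")),
      admission_diagnosis = NA_character_, discharged_alive = TRUE),
    labs = tibble::tibble(
      patient_id = "p", encounter_id = "e",
      analyte = c("ferritin", "hemoglobin", "platelets", "triglycerides"),
      value = c(1200, 80, 40, 3.5), collected_at = start + 3600),
    temperatures = tibble::tibble(patient_id = "p", encounter_id = "e",
                                  taken_at = start + 3600,
                                  temperature_c = 39, route = "oral"),
    notes = tibble::tibble(patient_id = "p", encounter_id = "e",
                           authored_at = start + 7200,
                           text = "splenomegaly on exam"))
  prof <- evaluate_encounter(ex, "e")
  expect_equal(prof$n_criteria, 5L)
  expect_true(all(prof$fever, prof$cytopenia, prof$ferritin,
                  prof$tg_or_fibrinogen, prof$splenomegaly))
  expect_false(any(prof$scd25, prof$low_nk, prof$hemophagocytosis))
  expect_false(prof$measured_scd25)
  expect_error(evaluate_encounter(ex, "old"), "outside the study window")
  expect_error(evaluate_encounter(ex, "nope"), "unknown encounter")

  # empty episode scores zero; a maximal one scores eight
  empty <- ex
  for (nm in c("labs", "temperatures", "notes")) empty[[nm]] <- empty[[nm]][0, ]
  expect_equal(evaluate_encounter(empty, "e")$n_criteria, 0L)
  full <- ex
  full$labs <- dplyr::bind_rows(full$labs, tibble::tibble(
    patient_id = "p", encounter_id = "e",
    analyte = c("scd25", "nk_activity"), value = c(3000, 1),
    collected_at = start + 3600))
  full$pathology <- tibble::tibble(
    patient_id = "p", encounter_id = "e", authored_at = start + 3600,
    text = "hemophagocytosis present", adjudicated_positive = NA)
  p8 <- evaluate_encounter(full, "e")
  expect_equal(p8$n_criteria, 8L)
  expect_equal(sum(dplyr::select(p8, dplyr::starts_with("measured_")) |>
                     unlist()), 8L)
})

test_that("profiles are invariant to row order and monotone under added rows", {
  set.seed(11)
  ex <- random_small_extract(10)
  prof <- evaluate_criteria(ex, cfg)
  shuf <- ex
  for (nm in c("labs", "temperatures", "notes", "pathology")) {
    tbl <- shuf[[nm]]
    if (nrow(tbl) > 1) shuf[[nm]] <- tbl[sample(nrow(tbl)), ]
  }
  prof2 <- evaluate_criteria(shuf, cfg)
  expect_equal(prof, prof2)

  # adding an abnormal lab row never decreases any count
  add <- ex
  target <- ex$encounters$encounter_id[1]
  add$labs <- dplyr::bind_rows(add$labs, tibble::tibble(
    patient_id = ex$encounters$patient_id[1], encounter_id = target,
    analyte = "ferritin", value = 10000,
    collected_at = ex$encounters$start[1] + 3600))
  prof3 <- evaluate_criteria(add, cfg)
  merged <- dplyr::left_join(prof, prof3, by = "encounter_id",
                             suffix = c("_old", "_new"))
  expect_true(all(merged$n_criteria_new >= merged$n_criteria_old))
})

test_that("engine agrees with the plain-loop evaluator on random extracts", {
  set.seed(23)
  for (rep in 1:20) {
    ex <- random_small_extract(8)
    prof <- evaluate_criteria(ex, cfg)
    for (i in seq_len(nrow(prof))) {
      o <- oracle_profile(ex, prof$encounter_id[i], cfg)
      got <- unlist(prof[i, names(o)[names(o) != "n_criteria"]])
      expect_equal(as.logical(got), as.logical(o[names(o) != "n_criteria"]),
                   info = prof$encounter_id[i])
      expect_equal(prof$n_criteria[i], unname(o[["n_criteria"]]))
    }
  }
})
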