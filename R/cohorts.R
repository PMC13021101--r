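# Resolve an event (timestamp + optional encounter link) to an encounter:
# explicit link wins; else the in-window encounter containing the timestamp
# (earliest start on overlap); else the nearest subsequent encounter; else NA.
resolve_event_encounter <- function(events, extract, config) {
  enc <- episode_window(extract$encounters, config) |>
    filter(in_study_window(.data$start, config))
  purrr::map_chr(seq_len(nrow(events)), function(i) {
    eid <- events$encounter_id[i]
    if (!is.na(eid) && eid %in% enc$encounter_id) return(eid)
    t <- events$at[i]
    mine <- enc |> filter(.data$patient_id == events$patient_id[i])
    if (!nrow(mine)) return(NA_character_)
    contain <- mine |> filter(.data$episode_start <= t, t <= .data$episode_end)
    if (nrow(contain)) {
      return(contain |> arrange(.data$episode_start, .data$encounter_id) |>
               pull(.data$encounter_id) |> first())
    }
    later <- mine |> filter(.data$episode_start >= t)
    if (nrow(later)) {
      return(later |> arrange(.data$episode_start, .data$encounter_id) |>
               pull(.data$encounter_id) |> first())
    }
    NA_character_
  })
}

#' ICD-10 coding phenotype
#'
#' Patients with at least one in-window D76.1 or D76.2 diagnosis
#' (exact code match after upper-casing and trimming; child codes do not
#' match). The index encounter is the one associated with the first
#' qualifying code: its explicit encounter link if present, else the
#' encounter containing the code's timestamp, else the nearest subsequent
#' encounter.
#'
#' @param extract An `ehr_extract`.
#' @param config An [hlh_config()].
#' @return Tibble: `patient_id`, `first_code_at`, `index_encounter_icd`.
#' @export
build_icd_cohort <- function(extract, config = hlh_config()) {
  dg <- extract$diagnoses |>
    mutate(code = stringr::str_to_upper(stringr::str_trim(.data$icd10_code))) |>
    filter(.data$code %in% config$hlh_icd_codes,
           in_study_window(.data$noted_at, config))
  firsts <- dg |>
    group_by(.data$patient_id) |>
    arrange(.data$noted_at, .data$icd10_code, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    rename(first_code_at = "noted_at")
  if (!nrow(firsts)) {
    return(tibble(patient_id = character(),
                  first_code_at = as.POSIXct(character(), tz = "UTC"),
                  index_encounter_icd = character()))
  }
  firsts$index_encounter_icd <- resolve_event_encounter(
    firsts |> mutate(at = .data$first_code_at), extract, config)
  firsts |> select("patient_id", "first_code_at", "index_encounter_icd") |>
    arrange(.data$patient_id)
}

#' Treatment-plan phenotype
#'
#' Patients with an in-window treatment plan whose display or protocol
#' name contains "hlh" or "h(a)emophagocytosis" (case-insensitive
#' substring). Index = first application, linked to an encounter as for
#' the ICD cohort.
#'
#' @param extract An `ehr_extract`.
#' @param config An [hlh_config()].
#' @return Tibble: `patient_id`, `first_plan_at`, `index_encounter_plan`.
#' @export
build_plan_cohort <- function(extract, config = hlh_config()) {
  pat <- stringr::str_to_lower(config$plan_name_patterns)
  matches_any <- function(x) {
    x <- stringr::str_to_lower(dplyr::coalesce(x, ""))
    purrr::reduce(pat, function(acc, p)
      acc | stringr::str_detect(x, stringr::fixed(p)), .init = rep(FALSE, length(x)))
  }
  tp <- extract$treatment_plans |>
    filter(matches_any(.data$display_name) | matches_any(.data$protocol_name),
           in_study_window(.data$applied_at, config))
  firsts <- tp |>
    group_by(.data$patient_id) |>
    arrange(.data$applied_at, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    rename(first_plan_at = "applied_at")
  if (!nrow(firsts)) {
    return(tibble(patient_id = character(),
                  first_plan_at = as.POSIXct(character(), tz = "UTC"),
                  index_encounter_plan = character()))
  }
  firsts$index_encounter_plan <- resolve_event_encounter(
    firsts |> mutate(at = .data$first_plan_at), extract, config)
  firsts |> select("patient_id", "first_plan_at", "index_encounter_plan") |>
    arrange(.data$patient_id)
}

#' Clinical-criteria phenotype
#'
#' Per patient, the HLH-specific (index) encounter is the encounter with
#' the maximum criteria count; ties are broken by earliest episode start,
#' then encounter_id. Membership requires the maximum count to reach
#' `criteria_required` (default 5 of 8) within that single encounter.
#'
#' @param profiles Output of [evaluate_criteria()].
#' @param config An [hlh_config()].
#' @return Tibble: `patient_id`, `index_encounter_criteria`,
#'   `max_criteria_count`, `in_criteria_cohort`.
#' @export
build_criteria_cohort <- function(profiles, config = hlh_config()) {
  if (!nrow(profiles)) {
    return(tibble(patient_id = character(),
                  index_encounter_criteria = character(),
                  max_criteria_count = integer(),
                  in_criteria_cohort = logical()))
  }
  profiles |>
    group_by(.data$patient_id) |>
    arrange(dplyr::desc(.data$n_criteria), .data$episode_start,
            .data$encounter_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(in_criteria_cohort = .data$n_criteria >= config$criteria_required) |>
    select("patient_id", index_encounter_criteria = "encounter_id",
           max_criteria_count = "n_criteria", "in_criteria_cohort") |>
    arrange(.data$patient_id)
}

#' Assign the three HLH phenotypes to every patient
#'
#' Combines the ICD-10, treatment-plan and clinical-criteria cohorts into
#' one per-patient assignment table with each cohort's index encounter.
#'
#' @param extract An `ehr_extract`.
#' @param profiles Optional precomputed [evaluate_criteria()] output.
#' @param config An [hlh_config()].
#' @return Tibble with one row per patient: the three membership flags,
#'   the three index encounters, and `max_criteria_count`.
#' @examples
#' ex <- simulate_ehr(n_patients = 50, seed = 2)
#' assign_phenotypes(ex) |> dplyr::count(in_icd_cohort, in_criteria_cohort)
#' @export
assign_phenotypes <- function(extract, profiles = NULL,
                              config = hlh_config()) {
  profiles <- profiles %||% evaluate_criteria(extract, config)
  icd <- build_icd_cohort(extract, config)
  plan <- build_plan_cohort(extract, config)
  crit <- build_criteria_cohort(profiles, config)
  extract$patients |>
    select("patient_id") |>
    left_join(icd |> mutate(in_icd_cohort = TRUE), by = "patient_id") |>
    left_join(plan |> mutate(in_plan_cohort = TRUE), by = "patient_id") |>
    left_join(crit, by = "patient_id") |>
    mutate(
      in_icd_cohort = dplyr::coalesce(.data$in_icd_cohort, FALSE),
      in_plan_cohort = dplyr::coalesce(.data$in_plan_cohort, FALSE),
      in_criteria_cohort = dplyr::coalesce(.data$in_criteria_cohort, FALSE),
      max_criteria_count = dplyr::coalesce(.data$max_criteria_count, 0L),
      index_encounter_criteria = if_else(.data$in_criteria_cohort,
                                         .data$index_encounter_criteria,
                                         NA_character_)
    ) |>
    select("patient_id", "in_icd_cohort", "in_plan_cohort",
           "in_criteria_cohort", "index_encounter_icd",
           "index_encounter_plan", "index_encounter_criteria",
           "max_criteria_count") |>
    arrange(.data$patient_id)
}

#' Three-set cohort overlap
#'
#' Counts the seven non-empty regions of the three-set Venn diagram over
#' the ICD, plan and criteria cohorts, plus the union total.
#'
#' @param assignments Output of [assign_phenotypes()].
#' @return A tibble of class `hlh_overlap` with `region` and `n`; the
#'   union is the `"any"` row.
#' @export
compute_overlap <- function(assignments) {
  a <- assignments$in_icd_cohort
  b <- assignments$in_plan_cohort
  c_ <- assignments$in_criteria_cohort
  out <- tibble(
    region = c("icd_only", "plan_only", "criteria_only", "icd_plan",
               "icd_criteria", "plan_criteria", "all_three", "any"),
    n = c(sum(a & !b & !c_), sum(!a & b & !c_), sum(!a & !b & c_),
          sum(a & b & !c_), sum(a & !b & c_), sum(!a & b & c_),
          sum(a & b & c_), sum(a | b | c_))
  )
  structure(out, class = c("hlh_overlap", class(out)))
}

#' Ferritin-plus-fever screening encounters
#'
#' Encounter-level (not patient-level) rows for every in-window encounter
#' whose episode met both the ferritin and the fever criteria; a patient
#' can contribute multiple encounters. `meets_threshold` marks episodes
#' with at least `criteria_required` total criteria.
#'
#' @param profiles Output of [evaluate_criteria()].
#' @param config An [hlh_config()].
#' @return Tibble of screening encounters carrying all criterion flags,
#'   `measured_*` columns, `n_criteria` and `meets_threshold`.
#' @export
build_screening_cohort <- function(profiles, config = hlh_config()) {
  profiles |>
    filter(.data$ferritin, .data$fever) |>
    mutate(meets_threshold = .data$n_criteria >= config$criteria_required) |>
    arrange(.data$encounter_id)
}
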