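#' Classify HLH therapy exposure per patient
#'
#' HLH-directed therapy is receipt of any dose of dexamethasone,
#' methylprednisolone, anakinra, ruxolitinib, cyclosporine, etoposide or
#' emapalumab (case-insensitive generic-name match); chemotherapy is the
#' per-administration flag in the extract. "Index-encounter" exposure
#' means administered within the index episode's time window;
#' "any-encounter" means at any time in the study window. The therapy
#' pattern is `steroid_only` when every HLH-directed drug received during
#' the index episode is dexamethasone or methylprednisolone,
#' `steroid_plus_other` when steroids were combined with another listed
#' drug, `other_only`, or `none`.
#'
#' @param extract An `ehr_extract`.
#' @param index_encounters Tibble with `patient_id` and `index_encounter`
#'   (e.g. a renamed column of [assign_phenotypes()] output). Patients
#'   with `NA` index have all index-scoped flags `FALSE`.
#' @param config An [hlh_config()].
#' @return Tibble: patient_id, `chemo_index_encounter`,
#'   `chemo_any_encounter`, `hlh_directed_index_encounter`,
#'   `hlh_directed_any_encounter`, `chemo_or_hlh_index`,
#'   `chemo_or_hlh_any`, `therapy_pattern`.
#' @export
classify_therapy <- function(extract, index_encounters,
                             config = hlh_config()) {
  stopifnot(all(c("patient_id", "index_encounter") %in%
                  names(index_encounters)))
  win <- episode_window(extract$encounters, config) |>
    select("encounter_id", "episode_start", "episode_end")
  idx <- index_encounters |>
    left_join(win, by = c(index_encounter = "encounter_id"))
  meds <- extract$medications |>
    mutate(generic = stringr::str_to_lower(.data$generic_name),
           is_hlh_drug = .data$generic %in% config$hlh_directed_drugs,
           is_steroid = .data$generic %in% config$steroid_drugs,
           in_window = in_study_window(.data$administered_at, config))
  per <- purrr::map(seq_len(nrow(idx)), function(i) {
    pid <- idx$patient_id[i]
    m <- meds |> filter(.data$patient_id == pid, .data$in_window)
    in_index <- if (is.na(idx$index_encounter[i])) {
      rep(FALSE, nrow(m))
    } else {
      m$administered_at >= idx$episode_start[i] &
        m$administered_at <= idx$episode_end[i]
    }
    hlh_idx_drugs <- unique(m$generic[m$is_hlh_drug & in_index])
    pattern <- if (!length(hlh_idx_drugs)) {
      "none"
    } else if (all(hlh_idx_drugs %in% config$steroid_drugs)) {
      "steroid_only"
    } else if (any(hlh_idx_drugs %in% config$steroid_drugs)) {
      "steroid_plus_other"
    } else {
      "other_only"
    }
    tibble(
      patient_id = pid,
      chemo_index_encounter = any(m$is_chemotherapy & in_index),
      chemo_any_encounter = any(m$is_chemotherapy),
      hlh_directed_index_encounter = any(m$is_hlh_drug & in_index),
      hlh_directed_any_encounter = any(m$is_hlh_drug),
      therapy_pattern = pattern
    )
  })
  bind_rows(per) |>
    mutate(
      chemo_or_hlh_index = .data$chemo_index_encounter |
        .data$hlh_directed_index_encounter,
      chemo_or_hlh_any = .data$chemo_any_encounter |
        .data$hlh_directed_any_encounter
    ) |>
    arrange(.data$patient_id)
}

age_group_at <- function(birth_date, at) {
  yrs <- as.numeric(as.Date(at) - birth_date) / 365.25
  dplyr::case_when(
    yrs < 1 ~ "0-<1",
    yrs < 5 ~ "1-4",
    yrs < 15 ~ "5-14",
    TRUE ~ ">=15"
  )
}

#' Derive clinical outcomes for the criteria cohort
#'
#' For each patient with a criteria-phenotype index encounter: length of
#' stay (episode end minus start, days), ICU admission during the index
#' encounter, in-hospital death (death date within the episode or
#' `discharged_alive == FALSE`), death within 30 days of the index
#' episode start (inclusive boundary), stem-cell transplant after the
#' index start, services involved, age group at index start, admission
#' diagnosis, and the timing of the first HLH ICD-10 code relative to
#' the index episode (`before` / `during` / `after` / `never`).
#'
#' @param extract An `ehr_extract`.
#' @param assignments Output of [assign_phenotypes()]; rows without
#'   `index_encounter_criteria` are dropped.
#' @param config An [hlh_config()].
#' @return Tibble with one row per criteria-cohort patient.
#' @export
derive_outcomes <- function(extract, assignments, config = hlh_config()) {
  idx <- assignments |>
    filter(!is.na(.data$index_encounter_criteria))
  if (!nrow(idx)) abort("no patients with a criteria index encounter")
  win <- episode_window(extract$encounters, config)
  enc <- idx |>
    left_join(win, by = c(index_encounter_criteria = "encounter_id",
                          patient_id = "patient_id")) |>
    left_join(extract$patients, by = "patient_id")
  first_codes <- build_icd_cohort(extract, config) |>
    select("patient_id", "first_code_at")
  enc <- enc |> left_join(first_codes, by = "patient_id")

  icu_ids <- unique(extract$icu$encounter_id)
  svc <- extract$services |> distinct(.data$encounter_id, .data$service)
  sct <- extract$sct
  mort_days <- config$mortality_window_days

  purrr::map(seq_len(nrow(enc)), function(i) {
    e <- enc[i, ]
    start_d <- as.Date(e$episode_start)
    end_d <- as.Date(e$episode_end)
    death <- e$death_date
    in_hosp <- (!is.na(death) && death >= start_d && death <= end_d) ||
      isFALSE(e$discharged_alive)
    d30 <- !is.na(death) && death >= start_d &&
      as.numeric(death - start_d) <= mort_days
    services <- svc$service[svc$encounter_id == e$index_encounter_criteria]
    timing <- if (is.na(e$first_code_at)) {
      "never"
    } else if (as.Date(e$first_code_at) < start_d) {
      "before"
    } else if (as.Date(e$first_code_at) <= end_d) {
      "during"
    } else {
      "after"
    }
    tibble(
      patient_id = e$patient_id,
      index_encounter = e$index_encounter_criteria,
      los_days = as.numeric(difftime(e$episode_end, e$episode_start,
                                     units = "days")),
      icu = e$index_encounter_criteria %in% icu_ids,
      in_hospital_death = in_hosp,
      death_within_30d = d30,
      sct_after = any(sct$patient_id == e$patient_id &
                        sct$date > start_d),
      services = list(sort(unique(services))),
      age_group = age_group_at(e$birth_date, e$episode_start),
      sex = e$sex,
      admission_dx = e$admission_diagnosis,
      icd_timing = timing
    )
  }) |>
    bind_rows() |>
    arrange(.data$patient_id)
}
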