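CRITERIA <- c("fever", "splenomegaly", "cytopenia", "tg_or_fibrinogen",
              "hemophagocytosis", "low_nk", "ferritin", "scd25")

#' Episode time window for an encounter
#'
#' Criteria are evaluated over an episode: the admission-to-discharge
#' interval for inpatient encounters. An inpatient encounter with no
#' recorded end (still admitted) truncates at the study `window_end`;
#' an outpatient encounter with no end is a same-day interval ending at
#' 23:59 of the start date.
#'
#' @param encounters One-or-more-row encounters tibble.
#' @param config An [hlh_config()].
#' @return The encounters tibble with `episode_start`/`episode_end`
#'   POSIXct columns appended.
#' @export
episode_window <- function(encounters, config = hlh_config()) {
  day_end <- function(t) as.POSIXct(paste(format(t, "%Y-%m-%d"), "23:59"),
                                    tz = "UTC")
  win_end <- as.POSIXct(paste(format(config$window_end), "23:59"), tz = "UTC")
  encounters |>
    mutate(
      episode_start = .data$start,
      episode_end = dplyr::case_when(
        !is.na(.data$end) ~ .data$end,
        .data$encounter_class == "outpatient" ~ day_end(.data$start),
        TRUE ~ win_end
      )
    )
}

#' Two-clause oral fever rule
#'
#' Fever is met if (a) any oral temperature is at least 38.3 C once, or
#' (b) a maximal consecutive run of oral readings all >= 38.0 C spans at
#' least 60 minutes from first to last reading, with no intervening oral
#' reading below 38.0 C. Non-oral routes are ignored. A lone reading can
#' never satisfy clause (b): a span needs two timepoints.
#'
#' @param temps Tibble with `taken_at`, `temperature_c`, `route` for one
#'   episode.
#' @param config An [hlh_config()].
#' @return Logical scalar (`FALSE` when there are no oral observations).
#' @export
fever_met <- function(temps, config = hlh_config()) {
  th <- config$thresholds
  t <- temps |> filter(.data$route == "oral") |> arrange(.data$taken_at)
  if (!nrow(t)) return(FALSE)
  if (any(t$temperature_c >= th$fever_single)) return(TRUE)
  hot <- t$temperature_c >= th$fever_sustained_low
  if (!any(hot)) return(FALSE)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    span <- as.numeric(difftime(t$taken_at[ends[k]], t$taken_at[starts[k]],
                                units = "mins"))
    if (span >= th$fever_sustained_minutes) return(TRUE)
  }
  FALSE
}

# age in whole days at a timestamp
age_days_at <- function(at, birth_date) {
  as.numeric(as.Date(at) - birth_date)
}

#' Cytopenia of at least two lineages
#'
#' Each lineage (hemoglobin, platelets, neutrophils) is low iff any
#' in-episode value breaches its threshold; the hemoglobin threshold is
#' 100 g/L when the patient is under 28 days old at collection, else
#' 90 g/L (all three strict `<`). The criterion is met when at least two
#' lineages are low at any time in the episode — not necessarily
#' simultaneously — unless `strict_cytopenia_same_day` is set, in which
#' case two lineages must be low on the same calendar day.
#'
#' @param labs Tibble of in-episode lab rows.
#' @param birth_date Patient date of birth.
#' @param config An [hlh_config()].
#' @return Logical scalar.
#' @export
cytopenia_met <- function(labs, birth_date, config = hlh_config()) {
  th <- config$thresholds
  l <- labs |>
    filter(.data$analyte %in% c("hemoglobin", "platelets", "neutrophils")) |>
    mutate(
      low = dplyr::case_when(
        .data$analyte == "hemoglobin" &
          age_days_at(.data$collected_at, birth_date) < th$infant_age_days ~
          .data$value < th$hgb_max_infant,
        .data$analyte == "hemoglobin" ~ .data$value < th$hgb_max,
        .data$analyte == "platelets" ~ .data$value < th$plt_max,
        TRUE ~ .data$value < th$anc_max
      )
    )
  if (!nrow(l)) return(FALSE)
  if (isTRUE(config$strict_cytopenia_same_day)) {
    by_day <- l |>
      filter(.data$low) |>
      mutate(day = as.Date(.data$collected_at)) |>
      distinct(.data$day, .data$analyte) |>
      count(.data$day)
    return(any(by_day$n >= 2))
  }
  sum(tapply(l$low, l$analyte, any)) >= 2
}

# single-analyte threshold criteria; missing test => FALSE ("not abnormal")
lab_flag <- function(labs, analyte, fn) {
  v <- labs$value[labs$analyte == analyte]
  length(v) > 0 && any(fn(v))
}

#' Single-analyte laboratory criteria
#'
#' Threshold rules with the stated inclusivity: triglycerides >= 3.0
#' mmol/L, fibrinogen <= 1.5 g/L, ferritin >= 500 ug/L, sCD25 >= 2400
#' U/mL, and NK activity flagged abnormal-low per the local reference.
#' A test never performed in the episode is "not abnormal": `FALSE`.
#'
#' @param labs Tibble of in-episode lab rows.
#' @param config An [hlh_config()].
#' @return Logical scalar.
#' @name lab_criteria
NULL

#' @rdname lab_criteria
#' @export
tg_fib_met <- function(labs, config = hlh_config()) {
  th <- config$thresholds
  lab_flag(labs, "triglycerides", function(v) v >= th$tg_min) ||
    lab_flag(labs, "fibrinogen", function(v) v <= th$fib_max)
}

#' @rdname lab_criteria
#' @export
ferritin_met <- function(labs, config = hlh_config()) {
  lab_flag(labs, "ferritin", function(v) v >= config$thresholds$ferritin_min)
}

#' @rdname lab_criteria
#' @export
scd25_met <- function(labs, config = hlh_config()) {
  lab_flag(labs, "scd25", function(v) v >= config$thresholds$scd25_min)
}

#' @rdname lab_criteria
#' @export
nk_met <- function(labs, config = hlh_config()) {
  lab_flag(labs, "nk_activity", function(v) v == 1)
}

#' Text-based criteria over in-episode documents
#'
#' Splenomegaly is met iff any in-episode clinical note is positive under
#' the term-plus-negation rule; hemophagocytosis iff any in-episode
#' pathology report is positive (adjudication overrides the text rule).
#'
#' @param notes,pathology In-episode document tibbles.
#' @param config An [hlh_config()].
#' @return Logical scalar.
#' @name text_criteria
NULL

#' @rdname text_criteria
#' @export
splenomegaly_met <- function(notes, config = hlh_config()) {
  nrow(notes) > 0 &&
    any(purrr::map_lgl(notes$text, note_positive_for_splenomegaly,
                       config = config))
}

#' @rdname text_criteria
#' @export
hemophagocytosis_met <- function(pathology, config = hlh_config()) {
  nrow(pathology) > 0 &&
    any(purrr::map2_lgl(pathology$text, pathology$adjudicated_positive,
                        pathology_positive_for_hemophagocytosis,
                        config = config))
}

in_study_window <- function(start, config) {
  d <- as.Date(start)
  d >= config$window_start & d <= config$window_end
}

#' Evaluate the eight HLH-2004 criteria for every in-window encounter
#'
#' A criterion is met if it occurs at any point during the episode.
#' Laboratory, temperature, note and pathology rows are scoped to the
#' episode by `encounter_id`. Alongside each flag, a `measured_*` column
#' records whether the underlying test or document existed in the
#' episode, so "not abnormal" (absent test) is distinguishable from a
#' normal result.
#'
#' @param extract An `ehr_extract`.
#' @param config An [hlh_config()].
#' @return A tibble (one row per encounter whose start falls in the study
#'   window) with `patient_id`, `encounter_id`, `episode_start`,
#'   `episode_end`, the 8 criterion flags, the 8 `measured_*` booleans and
#'   `n_criteria`.
#' @examples
#' ex <- simulate_ehr(n_patients = 20, seed = 1)
#' evaluate_criteria(ex) |> dplyr::count(n_criteria)
#' @export
evaluate_criteria <- function(extract, config = hlh_config()) {
  enc <- episode_window(extract$encounters, config) |>
    filter(in_study_window(.data$start, config)) |>
    arrange(.data$encounter_id)
  birth <- setNames(extract$patients$birth_date, extract$patients$patient_id)

  split_by_enc <- function(tbl) split(tbl, tbl$encounter_id)
  labs_by <- split_by_enc(extract$labs)
  temps_by <- split_by_enc(extract$temperatures)
  notes_by <- split_by_enc(extract$notes)
  path_by <- split_by_enc(extract$pathology)
  empty <- function(proto) proto[0, , drop = FALSE]

  rows <- purrr::map(seq_len(nrow(enc)), function(i) {
    eid <- enc$encounter_id[i]
    labs <- labs_by[[eid]] %||% empty(extract$labs)
    temps <- temps_by[[eid]] %||% empty(extract$temperatures)
    notes <- notes_by[[eid]] %||% empty(extract$notes)
    path <- path_by[[eid]] %||% empty(extract$pathology)
    has <- function(a) any(labs$analyte %in% a)
    flags <- c(
      fever = fever_met(temps, config),
      splenomegaly = splenomegaly_met(notes, config),
      cytopenia = cytopenia_met(labs, birth[[enc$patient_id[i]]], config),
      tg_or_fibrinogen = tg_fib_met(labs, config),
      hemophagocytosis = hemophagocytosis_met(path, config),
      low_nk = nk_met(labs, config),
      ferritin = ferritin_met(labs, config),
      scd25 = scd25_met(labs, config)
    )
    measured <- c(
      fever = any(temps$route == "oral"),
      splenomegaly = nrow(notes) > 0,
      cytopenia = has(c("hemoglobin", "platelets", "neutrophils")),
      tg_or_fibrinogen = has(c("triglycerides", "fibrinogen")),
      hemophagocytosis = nrow(path) > 0,
      low_nk = has("nk_activity"),
      ferritin = has("ferritin"),
      scd25 = has("scd25")
    )
    tibble(
      patient_id = enc$patient_id[i], encounter_id = eid,
      episode_start = enc$episode_start[i], episode_end = enc$episode_end[i],
      !!!as.list(flags),
      !!!setNames(as.list(measured), paste0("measured_", names(measured))),
      n_criteria = as.integer(sum(flags))
    )
  })
  if (!length(rows)) {
    out <- tibble(patient_id = character(), encounter_id = character(),
                  episode_start = as.POSIXct(character(), tz = "UTC"),
                  episode_end = as.POSIXct(character(), tz = "UTC"))
    for (cr in CRITERIA) out[[cr]] <- logical()
    for (cr in CRITERIA) out[[paste0("measured_", cr)]] <- logical()
    out$n_criteria <- integer()
    return(out)
  }
  bind_rows(rows)
}

#' Evaluate one encounter
#'
#' @param extract An `ehr_extract`.
#' @param encounter_id Encounter key; must start within the study window.
#' @param config An [hlh_config()].
#' @return A one-row criteria profile (see [evaluate_criteria()]).
#' @export
evaluate_encounter <- function(extract, encounter_id, config = hlh_config()) {
  enc <- extract$encounters |> filter(.data$encounter_id == !!encounter_id)
  if (!nrow(enc)) abort(paste0("unknown encounter: ", encounter_id))
  if (!in_study_window(enc$start, config)) {
    abort(paste0("encounter ", encounter_id, " starts outside the study window"))
  }
  sub <- extract
  for (nm in c("labs", "temperatures", "notes", "pathology", "medications",
               "icu", "services")) {
    sub[[nm]] <- sub[[nm]] |> filter(.data$encounter_id == !!encounter_id)
  }
  sub$encounters <- enc
  evaluate_criteria(sub, config)
}
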