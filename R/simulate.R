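#' Parameters of the synthetic EHR generator
#'
#' The generator is a stylized latent-state Bernoulli mixture, not a
#' mechanistic disease model: each patient carries a latent
#' hyperinflammatory state with probability `p_latent`; the latent state
#' drives correlated criterion exceedances, test ordering, ICD coding,
#' treatment-plan application, therapy, length of stay and death in one
#' designated "flare" encounter. Per criterion, `p_test` is the
#' probability the underlying test is ordered (governs "measured") and
#' `p_abn` the probability an ordered test breaches its threshold, each
#' as `c(latent_positive, latent_negative)`.
#'
#' @param p_latent Probability a patient carries the latent state.
#' @param p_test,p_abn Named lists of 2-vectors per criterion.
#' @param p_note_negated Probability a spleen-term note realizes a
#'   negated (rather than affirmed) template when splenomegaly is absent.
#' @param p_icd Probability of a D76.1 code `c(latent, non_latent)`.
#' @param p_plan_given_treated Probability a treated latent patient has
#'   an HLH-named plan applied.
#' @param p_treat_by_count Monotone non-decreasing vector of length 9:
#'   probability of HLH-directed therapy given criteria count 0..8.
#' @param steroid_only_share Among treated, share receiving steroids only.
#' @param p_death HLH-flare 30-day death probability
#'   `c(treated, untreated)`.
#' @param p_death_in_hospital Share of deaths occurring before discharge.
#' @param los_meanlog,los_sdlog Log-normal length-of-stay parameters
#'   `c(treated, untreated)` for flare encounters, days.
#' @param encounters_lambda Poisson mean of extra (background) encounters.
#' @param date_range Study window the encounters are drawn from.
#' @return A list of class `hlh_sim_params`.
#' @export
sim_params <- function(p_latent = 0.05,
                       p_test = list(
                         ferritin = c(0.95, 0.30), cytopenia = c(0.98, 0.80),
                         tg_or_fibrinogen = c(0.85, 0.20),
                         scd25 = c(0.70, 0.02), low_nk = c(0.25, 0.005),
                         fever = c(1.0, 0.9), splenomegaly = c(1.0, 0.8),
                         hemophagocytosis = c(0.40, 0.03)),
                       p_abn = list(
                         ferritin = c(0.95, 0.10), cytopenia = c(0.90, 0.12),
                         tg_or_fibrinogen = c(0.92, 0.12),
                         scd25 = c(0.70, 0.10), low_nk = c(0.50, 0.08),
                         fever = c(0.92, 0.25), splenomegaly = c(0.90, 0.08),
                         hemophagocytosis = c(0.50, 0.02)),
                       p_note_negated = 0.35,
                       p_icd = c(0.70, 0.004),
                       p_plan_given_treated = 0.20,
                       p_treat_by_count = c(0.02, 0.02, 0.05, 0.10, 0.30,
                                            0.70, 0.85, 0.90, 0.95),
                       steroid_only_share = 0.68,
                       p_death = c(0.15, 0.14),
                       p_death_in_hospital = 0.9,
                       los_meanlog = c(log(30), log(18)),
                       los_sdlog = c(0.8, 0.8),
                       encounters_lambda = 0.7,
                       date_range = c(as.Date("2018-06-02"),
                                      as.Date("2025-04-30"))) {
  p <- as.list(environment())
  probs <- c(p$p_latent, unlist(p$p_test), unlist(p$p_abn), p$p_note_negated,
             p$p_icd, p$p_plan_given_treated, p$p_treat_by_count,
             p$steroid_only_share, p$p_death, p$p_death_in_hospital)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (is.unsorted(p$p_treat_by_count)) {
    abort("p_treat_by_count must be monotone non-decreasing")
  }
  structure(p, class = "hlh_sim_params")
}

# independent substream per stage so adding a stage leaves others untouched
stage_seed <- function(seed, k) ((as.integer(seed) %% 100000L) * 131L + k) %% 2147483647L

AFFIRMED_TEMPLATES <- c(
  "exam shows enlarged spleen today",
  "abdominal ultrasound demonstrates splenomegaly measuring above normal",
  "palpable organomegaly on examination",
  "persistent splenomegaly noted on rounds")
NEGATED_TEMPLATES <- c(
  "no splenomegaly on examination",
  "abdomen soft without organomegaly",
  "ultrasound negative for splenomegaly",
  "there is absence of splenomegaly on imaging")
NEUTRAL_TEMPLATES <- c(
  "afebrile overnight tolerating feeds well",
  "spleen not palpable abdomen benign",
  "continues on supportive care plan reviewed")

#' Generate a synthetic EHR extract
#'
#' Deterministic under a fixed seed: an identical seed reproduces a
#' bit-identical extract. Ground truth (latent state, flare encounter,
#' treatment, and the per-note NLP label) is attached for use in tests:
#' `attr(x, "patient_truth")` and `attr(x, "note_truth")`.
#'
#' @param n_patients Number of patients.
#' @param seed Master seed; each generated table uses its own substream.
#' @param params An [sim_params()] list.
#' @param config An [hlh_config()] (study window for episode truncation).
#' @return A validated `ehr_extract` with ground-truth attributes.
#' @examples
#' ex <- simulate_ehr(n_patients = 30, seed = 7)
#' attr(ex, "patient_truth")
#' @export
simulate_ehr <- function(n_patients = 500, seed = 1, params = sim_params(),
                         config = hlh_config()) {
  p <- params
  d0 <- p$date_range[1]
  d1 <- p$date_range[2]
  span <- as.numeric(d1 - d0)

  # -- patients ---------------------------------------------------------
  withr_seed(stage_seed(seed, 1L), {
    pid <- sprintf("P%05d", seq_len(n_patients))
    sex <- sample(c("male", "female"), n_patients, replace = TRUE)
    age_y <- runif(n_patients, 0, 18)
    latent <- runif(n_patients) < p$p_latent
  })

  # -- encounters -------------------------------------------------------
  withr_seed(stage_seed(seed, 2L), {
    n_extra <- rpois(n_patients, p$encounters_lambda)
    flare_start <- d0 + floor(runif(n_patients, 0, span - 40))
  })

  # per-encounter criterion realization -------------------------------
  crit_names <- c("ferritin", "cytopenia", "tg_or_fibrinogen", "scd25",
                  "low_nk", "fever", "splenomegaly", "hemophagocytosis")
  enc_rows <- list(); lab_rows <- list(); temp_rows <- list()
  note_rows <- list(); path_rows <- list(); truth_note <- list()
  med_rows <- list(); icu_rows <- list(); svc_rows <- list()
  dx_rows <- list(); plan_rows <- list(); sct_rows <- list()
  death_date <- rep(as.Date(NA), n_patients)
  treated <- logical(n_patients)
  flare_count <- integer(n_patients)
  flare_eid <- character(n_patients)

  withr_seed(stage_seed(seed, 3L), {
    ek <- 0L
    for (i in seq_len(n_patients)) {
      lat <- latent[i]
      s <- as.integer(lat) * 1L + as.integer(!lat) * 2L  # 1 latent, 2 not
      # flare (first) encounter + background encounters
      starts <- c(flare_start[i],
                  d0 + floor(runif(n_extra[i], 0, span)))
      for (j in seq_along(starts)) {
        ek <- ek + 1L
        eid <- sprintf("E%06d", ek)
        is_flare <- j == 1L
        if (is_flare) flare_eid[i] <- eid
        use <- if (is_flare) s else 2L  # background encounters look healthy
        tested <- vapply(crit_names, function(cr)
          runif(1) < p$p_test[[cr]][use], logical(1))
        abn <- tested & vapply(crit_names, function(cr)
          runif(1) < p$p_abn[[cr]][use], logical(1))
        start_t <- as.POSIXct(paste(starts[j], "08:00"), tz = "UTC")
        los <- if (is_flare) {
          rlnorm(1, p$los_meanlog[1 + !lat], p$los_sdlog[1 + !lat])
        } else {
          rlnorm(1, log(3), 0.5)
        }
        end_t <- start_t + round(los * 86400 / 60) * 60
        enc_rows[[ek]] <- tibble(
          encounter_id = eid, patient_id = pid[i],
          encounter_class = "inpatient", start = start_t, end = end_t,
          admission_diagnosis = if (is_flare && lat) "fever" else
            sample(c("fever", "viral infection", "pneumonia", "dehydration",
                     "seizure"), 1),
          discharged_alive = TRUE)

        mk_lab <- function(analyte, value, hrs) {
          tibble(patient_id = pid[i], encounter_id = eid, analyte = analyte,
                 value = value, collected_at = start_t + round(hrs * 3600))
        }
        labs <- list()
        if (tested["ferritin"]) {
          labs <- c(labs, list(mk_lab("ferritin",
                                      if (abn["ferritin"]) runif(1, 600, 20000)
                                      else runif(1, 20, 450), 4)))
        }
        if (tested["cytopenia"]) {
          two_low <- abn["cytopenia"]
          labs <- c(labs, list(
            mk_lab("hemoglobin", if (two_low) runif(1, 55, 88)
                   else runif(1, 100, 140), 4),
            mk_lab("platelets", if (two_low) runif(1, 10, 95)
                   else runif(1, 150, 400), 4),
            mk_lab("neutrophils", runif(1, 1.5, 8), 4)))
        }
        if (tested["tg_or_fibrinogen"]) {
          labs <- c(labs, list(
            mk_lab("triglycerides", if (abn["tg_or_fibrinogen"])
              runif(1, 3.1, 8) else runif(1, 0.5, 2.5), 6),
            mk_lab("fibrinogen", runif(1, 1.8, 4), 6)))
        }
        if (tested["scd25"]) {
          labs <- c(labs, list(mk_lab("scd25", if (abn["scd25"])
            runif(1, 2500, 30000) else runif(1, 300, 2200), 24)))
        }
        if (tested["low_nk"]) {
          labs <- c(labs, list(mk_lab("nk_activity",
                                      as.numeric(abn["low_nk"]), 48)))
        }
        lab_rows[[ek]] <- bind_rows(labs)

        # temperatures: a short oral series; febrile via either clause
        n_t <- 3L + sample.int(4L, 1L)
        tt <- start_t + sort(sample.int(72, n_t)) * 3600
        tv <- runif(n_t, 36.2, 37.6)
        if (abn["fever"]) {
          if (runif(1) < 0.5) {
            tv[1] <- runif(1, 38.3, 40.5)       # clause (a)
          } else {                              # clause (b): 70-min run
            tt[1:2] <- c(start_t + 3600, start_t + 3600 + 70 * 60)
            tv[1:2] <- runif(2, 38.0, 38.2)
            tt <- c(tt[1:2], tt[-(1:2)] + 2 * 86400)
            tt <- sort(tt)
          }
        }
        temp_rows[[ek]] <- tibble(patient_id = pid[i], encounter_id = eid,
                                  taken_at = tt, temperature_c = tv,
                                  route = "oral")

        # notes with ground-truth NLP labels
        n_notes <- 1L + sample.int(2L, 1L)
        labels <- if (abn["splenomegaly"]) {
          c("affirmed", sample(c("neutral", "negated"), n_notes - 1,
                               replace = TRUE,
                               prob = c(1 - p$p_note_negated,
                                        p$p_note_negated)))
        } else {
          sample(c("neutral", "negated"), n_notes, replace = TRUE,
                 prob = c(1 - p$p_note_negated, p$p_note_negated))
        }
        texts <- vapply(labels, function(lb) switch(lb,
          affirmed = sample(AFFIRMED_TEMPLATES, 1),
          negated = sample(NEGATED_TEMPLATES, 1),
          neutral = sample(NEUTRAL_TEMPLATES, 1)), character(1))
        if (tested["splenomegaly"]) {
          note_rows[[ek]] <- tibble(patient_id = pid[i], encounter_id = eid,
                                    authored_at = start_t + seq_len(n_notes) *
                                      86400, text = unname(texts))
          truth_note[[ek]] <- tibble(patient_id = pid[i], encounter_id = eid,
                                     authored_at = start_t + seq_len(n_notes) *
                                       86400, label = unname(labels))
        }
        if (tested["hemophagocytosis"]) {
          ptxt <- if (abn["hemophagocytosis"]) {
            "bone marrow aspirate with hemophagocytosis identified"
          } else {
            "bone marrow aspirate no hemophagocytosis identified"
          }
          path_rows[[ek]] <- tibble(patient_id = pid[i], encounter_id = eid,
                                    authored_at = start_t + 3 * 86400,
                                    text = ptxt, adjudicated_positive = NA)
        }

        if (is_flare) {
          realized <- sum(abn[c("ferritin", "cytopenia", "tg_or_fibrinogen",
                                "scd25", "low_nk", "fever")]) +
            abn[["splenomegaly"]] + abn[["hemophagocytosis"]]
          flare_count[i] <- as.integer(realized)
        }
      }
    }
  })
  enc <- bind_rows(enc_rows)

  # -- treatment, coding, outcomes (flare-scoped) -----------------------
  withr_seed(stage_seed(seed, 4L), {
    for (i in seq_len(n_patients)) {
      treated[i] <- runif(1) < p$p_treat_by_count[flare_count[i] + 1L]
      eid <- flare_eid[i]
      e <- enc[enc$encounter_id == eid, ]
      if (treated[i]) {
        drugs <- if (runif(1) < p$steroid_only_share) {
          "dexamethasone"
        } else if (runif(1) < 0.9) {
          c("dexamethasone", "anakinra")
        } else {
          "etoposide"
        }
        med_rows[[i]] <- tibble(patient_id = pid[i], encounter_id = eid,
                                generic_name = drugs,
                                administered_at = e$start + 86400,
                                is_chemotherapy = drugs == "etoposide")
        if (latent[i] && runif(1) < p$p_plan_given_treated) {
          plan_rows[[i]] <- tibble(patient_id = pid[i],
                                   display_name = "HLH-94 protocol",
                                   protocol_name = "HLH 94",
                                   applied_at = e$start + 86400,
                                   encounter_id = eid)
        }
      }
      if (runif(1) < p$p_icd[1 + !latent[i]]) {
        dx_rows[[i]] <- tibble(patient_id = pid[i], icd10_code = "D76.1",
                               noted_at = e$start + 2 * 86400,
                               encounter_id = eid)
      }
      if (latent[i]) {
        if (runif(1) < 0.5) {
          icu_rows[[i]] <- tibble(patient_id = pid[i], encounter_id = eid,
                                  start = e$start + 86400,
                                  end = e$start + 3 * 86400)
        }
        svcs <- sample(SERVICE_LEVELS, sample.int(3L, 1L))
        svc_rows[[i]] <- tibble(patient_id = pid[i], encounter_id = eid,
                                service = svcs)
        if (runif(1) < p$p_death[1 + !treated[i]]) {
          dd <- as.Date(e$start) + sample.int(30L, 1L)
          if (runif(1) < p$p_death_in_hospital) {
            dd <- min(dd, as.Date(e$end))
            enc$discharged_alive[enc$encounter_id == eid] <- FALSE
            enc$end[enc$encounter_id == eid] <-
              min(e$end, as.POSIXct(paste(dd, "12:00"), tz = "UTC"))
          }
          death_date[i] <- dd
        } else if (runif(1) < 0.08) {
          sct_rows[[i]] <- tibble(patient_id = pid[i],
                                  date = as.Date(e$end) + 60)
        }
      }
    }
  })

  patients <- tibble(patient_id = pid, sex = sex,
                     birth_date = flare_start - round(age_y * 365.25),
                     death_date = death_date)
  ex <- ehr_extract(
    patients = patients, encounters = enc,
    labs = bind_rows(lab_rows), temperatures = bind_rows(temp_rows),
    diagnoses = bind_rows(dx_rows), treatment_plans = bind_rows(plan_rows),
    medications = bind_rows(med_rows), notes = bind_rows(note_rows),
    pathology = bind_rows(path_rows), icu = bind_rows(icu_rows),
    services = bind_rows(svc_rows), sct = bind_rows(sct_rows))
  ex <- sort_extract(ex)
  attr(ex, "patient_truth") <- tibble(
    patient_id = pid, latent = latent, flare_encounter_id = flare_eid,
    flare_criteria_count = flare_count, treated = treated)
  attr(ex, "note_truth") <- bind_rows(truth_note) |>
    arrange(.data$patient_id, .data$encounter_id, .data$authored_at)
  ex
}
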