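# Independent oracles used by the property suites. These re-derive each
# rule with plain loops, deliberately avoiding the package's vectorized /
# rle / dplyr implementations.

# two-sided Fisher p by direct hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# all non-overlapping left-to-right longest matches, by plain scanning
oracle_mentions <- function(tokens, lexicon) {
  phrases <- lapply(lexicon, function(p) hlhphenotype::hlh_tokenize(p))
  res <- list()
  i <- 1
  while (i <= length(tokens)) {
    best <- NULL
    best_len <- 0
    for (j in seq_along(phrases)) {
      ph <- phrases[[j]]
      if (length(ph) > best_len && i + length(ph) - 1 <= length(tokens)) {
        if (identical(tokens[i:(i + length(ph) - 1)], ph)) {
          best <- j
          best_len <- length(ph)
        }
      }
    }
    if (!is.null(best)) {
      res[[length(res) + 1]] <- list(term = lexicon[best], start = i - 1)
      i <- i + best_len
    } else {
      i <- i + 1
    }
  }
  res
}

oracle_negated <- function(tokens, start0, neg_terms, window) {
  if (window == 0) return(FALSE)
  hit <- FALSE
  for (k in seq_len(window)) {
    pos <- start0 - k + 1  # 1-based index of the k-th preceding token
    if (pos >= 1 && tolower(tokens[pos]) %in% neg_terms) hit <- TRUE
  }
  hit
}

oracle_note_positive <- function(text, config) {
  toks <- hlhphenotype::hlh_tokenize(text)
  ms <- oracle_mentions(toks, config$splenomegaly_terms)
  for (m in ms) {
    if (!oracle_negated(toks, m$start, config$negation_terms,
                        config$negation_window_words)) {
      return(TRUE)
    }
  }
  FALSE
}

# plain-loop criteria evaluator for one encounter
oracle_profile <- function(extract, eid, config) {
  e <- extract$encounters[extract$encounters$encounter_id == eid, ]
  labs <- extract$labs[extract$labs$encounter_id == eid, ]
  temps <- extract$temperatures[extract$temperatures$encounter_id == eid, ]
  notes <- extract$notes[extract$notes$encounter_id == eid, ]
  path <- extract$pathology[extract$pathology$encounter_id == eid, ]
  birth <- extract$patients$birth_date[
    extract$patients$patient_id == e$patient_id]
  th <- config$thresholds

  # fever: pairwise enumeration of run endpoints
  ot <- temps[temps$route == "oral", ]
  ot <- ot[order(ot$taken_at), ]
  fever <- FALSE
  if (nrow(ot) > 0) {
    if (any(ot$temperature_c >= th$fever_single)) fever <- TRUE
    if (!fever) {
      for (i in seq_len(nrow(ot))) {
        for (j in seq_len(nrow(ot))) {
          if (j > i && all(ot$temperature_c[i:j] >= th$fever_sustained_low)) {
            span <- as.numeric(difftime(ot$taken_at[j], ot$taken_at[i],
                                        units = "mins"))
            if (span >= th$fever_sustained_minutes) fever <- TRUE
          }
        }
      }
    }
  }

  low_lineages <- character()
  for (r in seq_len(nrow(labs))) {
    an <- labs$analyte[r]
    v <- labs$value[r]
    if (an == "hemoglobin") {
      cutoff <- if (as.numeric(as.Date(labs$collected_at[r]) - birth) <
                    th$infant_age_days) th$hgb_max_infant else th$hgb_max
      if (v < cutoff) low_lineages <- union(low_lineages, "h")
    }
    if (an == "platelets" && v < th$plt_max)
      low_lineages <- union(low_lineages, "p")
    if (an == "neutrophils" && v < th$anc_max)
      low_lineages <- union(low_lineages, "n")
  }
  cytopenia <- length(low_lineages) >= 2

  anyv <- function(an, f) {
    v <- labs$value[labs$analyte == an]
    length(v) > 0 && any(f(v))
  }
  tg_fib <- anyv("triglycerides", function(v) v >= th$tg_min) ||
    anyv("fibrinogen", function(v) v <= th$fib_max)
  ferritin <- anyv("ferritin", function(v) v >= th$ferritin_min)
  scd25 <- anyv("scd25", function(v) v >= th$scd25_min)
  nk <- anyv("nk_activity", function(v) v == 1)

  spleno <- FALSE
  for (r in seq_len(nrow(notes))) {
    if (oracle_note_positive(notes$text[r], config)) spleno <- TRUE
  }
  hemo <- FALSE
  for (r in seq_len(nrow(path))) {
    adj <- path$adjudicated_positive[r]
    if (!is.na(adj)) {
      if (isTRUE(adj)) hemo <- TRUE
    } else {
      toks <- hlhphenotype::hlh_tokenize(path$text[r])
      for (i in seq_along(toks)) {
        if (any(vapply(config$hemophagocytosis_patterns, function(p)
          grepl(p, toks[i], fixed = TRUE), logical(1)))) {
          if (!oracle_negated(toks, i - 1, config$negation_terms,
                              config$negation_window_words)) {
            hemo <- TRUE
          }
        }
      }
    }
  }
  flags <- c(fever = fever, splenomegaly = spleno, cytopenia = cytopenia,
             tg_or_fibrinogen = tg_fib, hemophagocytosis = hemo,
             low_nk = nk, ferritin = ferritin, scd25 = scd25)
  c(flags, n_criteria = sum(flags))
}

# small random extract for property tests (independent of simulate_ehr)
random_small_extract <- function(n_patients = 20) {
  start0 <- as.POSIXct("2020-01-01 08:00", tz = "UTC")
  vocab <- c("no", "none", "without", "negative", "exam", "shows",
             "splenomegaly", "enlarged", "spleen", "organomegaly", "big",
             "normal", "today", "liver")
  pts <- tibble::tibble(
    patient_id = sprintf("R%03d", seq_len(n_patients)),
    sex = sample(c("male", "female"), n_patients, TRUE),
    birth_date = as.Date("2020-01-01") -
      sample(c(5, 40, 2000, 6000), n_patients, TRUE),
    death_date = as.Date(NA))
  enc <- list(); labs <- list(); temps <- list(); notes <- list()
  path <- list()
  k <- 0
  for (i in seq_len(n_patients)) {
    for (j in seq_len(sample(1:2, 1))) {
      k <- k + 1
      eid <- sprintf("RE%03d", k)
      st <- start0 + sample(0:300, 1) * 86400
      enc[[k]] <- tibble::tibble(
        encounter_id = eid, patient_id = pts$patient_id[i],
        encounter_class = sample(c("inpatient", "outpatient"), 1),
        start = st, end = st + sample(2:10, 1) * 86400,
        admission_diagnosis = NA_character_, discharged_alive = TRUE)
      n_lab <- sample(0:6, 1)
      if (n_lab > 0) {
        an <- sample(c("ferritin", "hemoglobin", "platelets", "neutrophils",
                       "triglycerides", "fibrinogen", "scd25"), n_lab, TRUE)
        val <- vapply(an, function(a) switch(a,
          ferritin = runif(1, 100, 2000), hemoglobin = runif(1, 60, 130),
          platelets = runif(1, 20, 300), neutrophils = runif(1, 0.2, 5),
          triglycerides = runif(1, 1, 5), fibrinogen = runif(1, 0.5, 3),
          scd25 = runif(1, 500, 5000)), numeric(1))
        labs[[k]] <- tibble::tibble(
          patient_id = pts$patient_id[i], encounter_id = eid,
          analyte = an, value = unname(val),
          collected_at = st + sample(1:72, n_lab, TRUE) * 3600)
      }
      n_t <- sample(0:5, 1)
      if (n_t > 0) {
        temps[[k]] <- tibble::tibble(
          patient_id = pts$patient_id[i], encounter_id = eid,
          taken_at = st + sort(sample(1:120, n_t)) * 35 * 60,
          temperature_c = round(runif(n_t, 36.5, 39.5), 1),
          route = sample(c("oral", "other"), n_t, TRUE, prob = c(.8, .2)))
      }
      n_n <- sample(0:2, 1)
      if (n_n > 0) {
        notes[[k]] <- tibble::tibble(
          patient_id = pts$patient_id[i], encounter_id = eid,
          authored_at = st + seq_len(n_n) * 86400,
          text = vapply(seq_len(n_n), function(z)
            paste(sample(vocab, sample(3:12, 1), TRUE), collapse = " "),
            character(1)))
      }
      if (runif(1) < 0.2) {
        path[[k]] <- tibble::tibble(
          patient_id = pts$patient_id[i], encounter_id = eid,
          authored_at = st + 86400,
          text = sample(c("hemophagocytosis seen in marrow",
                          "no hemophagocytosis seen",
                          "normocellular marrow"), 1),
          adjudicated_positive = sample(c(NA, TRUE, FALSE), 1,
                                        prob = c(.8, .1, .1)))
      }
    }
  }
  hlhphenotype::ehr_extract(
    patients = pts, encounters = dplyr::bind_rows(enc),
    labs = dplyr::bind_rows(labs), temperatures = dplyr::bind_rows(temps),
    notes = dplyr::bind_rows(notes), pathology = dplyr::bind_rows(path))
}

# set-algebra overlap oracle: per-patient region classification
oracle_overlap <- function(assignments) {
  regions <- c("icd_only", "plan_only", "criteria_only", "icd_plan",
               "icd_criteria", "plan_criteria", "all_three", "any")
  counts <- stats::setNames(integer(8), regions)
  for (i in seq_len(nrow(assignments))) {
    a <- assignments$in_icd_cohort[i]
    b <- assignments$in_plan_cohort[i]
    c_ <- assignments$in_criteria_cohort[i]
    if (!(a || b || c_)) next
    counts["any"] <- counts["any"] + 1L
    key <- paste0(as.integer(a), as.integer(b), as.integer(c_))
    reg <- switch(key, "100" = "icd_only", "010" = "plan_only",
                  "001" = "criteria_only", "110" = "icd_plan",
                  "101" = "icd_criteria", "011" = "plan_criteria",
                  "111" = "all_three")
    counts[reg] <- counts[reg] + 1L
  }
  counts
}
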