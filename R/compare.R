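pct1 <- function(x, n) ifelse(n > 0, round(100 * x / n, 1), NA_real_)

cat_row <- function(variable, level, x1, n1, x2, n2, test = TRUE) {
  tt <- if (test) {
    two_group_test(matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = FALSE))
  } else {
    tibble(statistic = NA_real_, p_value = NA_real_, method = "suppressed")
  }
  tibble(variable = variable, level = level,
         n_treated = x1, pct_treated = pct1(x1, n1),
         n_untreated = x2, pct_untreated = pct1(x2, n2),
         method = tt$method, p_value = tt$p_value)
}

#' Compare treated and untreated patients in the criteria cohort
#'
#' Stratifies the >= `criteria_required` cohort by receipt of
#' HLH-directed therapy during the index encounter and reproduces the
#' standard report rows: sex, age group, the five most frequent admission
#' diagnoses (ties broken lexically), ICD-10 HLH diagnosis and its timing,
#' the eight criteria (with measured denominators for sCD25 and NK
#' activity), the six consulting services, median length of stay, ICU,
#' in-hospital mortality, 30-day mortality and stem-cell transplant.
#' Continuous rows use the Wilcoxon rank-sum test; categorical rows use
#' chi-square or Fisher's exact test. Risk differences (round-first, with
#' Wald intervals) are attached for the two mortality outcomes and a
#' seeded percentile-bootstrap interval for the median length-of-stay
#' difference. If either group is empty the rows are still emitted with
#' tests suppressed.
#'
#' @param extract An `ehr_extract`.
#' @param assignments Output of [assign_phenotypes()].
#' @param profiles Output of [evaluate_criteria()].
#' @param exposures Optional [classify_therapy()] output for the criteria
#'   cohort (computed if `NULL`).
#' @param outcomes Optional [derive_outcomes()] output (computed if `NULL`).
#' @param config An [hlh_config()].
#' @param n_boot,seed Bootstrap settings for the median difference.
#' @return An `hlh_comparison`: list with `summary` (per-row tibble),
#'   `effects` (risk/median differences), `continuous` (LOS row) and
#'   `groups`.
#' @export
compare_groups <- function(extract, assignments, profiles,
                           exposures = NULL, outcomes = NULL,
                           config = hlh_config(), n_boot = 2000, seed = 1) {
  cohort <- assignments |> filter(.data$in_criteria_cohort)
  if (!nrow(cohort)) abort("criteria cohort is empty")
  exposures <- exposures %||% classify_therapy(
    extract, cohort |> select("patient_id",
                              index_encounter = "index_encounter_criteria"),
    config)
  outcomes <- outcomes %||% derive_outcomes(extract, cohort, config)
  dat <- cohort |>
    left_join(exposures, by = "patient_id") |>
    left_join(outcomes, by = "patient_id") |>
    left_join(profiles |> select(-"patient_id"),
              by = c(index_encounter_criteria = "encounter_id")) |>
    mutate(treated = .data$hlh_directed_index_encounter)
  n1 <- sum(dat$treated)
  n2 <- sum(!dat$treated)
  do_test <- n1 > 0 && n2 > 0
  tr <- dat |> filter(.data$treated)
  un <- dat |> filter(!.data$treated)

  rows <- list()
  rows$sex <- cat_row("sex", "male", sum(tr$sex == "male"), n1,
                      sum(un$sex == "male"), n2, do_test)

  age_levels <- c("0-<1", "1-4", "5-14", ">=15")
  age_tab <- vapply(age_levels, function(a)
    c(sum(tr$age_group == a), sum(un$age_group == a)), numeric(2))
  age_test <- if (do_test) two_group_test(t(age_tab)) else
    tibble(statistic = NA_real_, p_value = NA_real_, method = "suppressed")
  rows$age <- purrr::map(age_levels, function(a) {
    tibble(variable = "age_group", level = a,
           n_treated = sum(tr$age_group == a),
           pct_treated = pct1(sum(tr$age_group == a), n1),
           n_untreated = sum(un$age_group == a),
           pct_untreated = pct1(sum(un$age_group == a), n2),
           method = age_test$method, p_value = age_test$p_value)
  }) |> bind_rows()

  top5 <- dat |>
    filter(!is.na(.data$admission_dx)) |>
    count(.data$admission_dx) |>
    arrange(dplyr::desc(.data$n), .data$admission_dx) |>
    dplyr::slice(seq_len(min(5, dplyr::n()))) |>
    pull(.data$admission_dx)
  rows$adx <- purrr::map(top5, function(a)
    cat_row("admission_diagnosis", a,
            sum(tr$admission_dx == a, na.rm = TRUE), n1,
            sum(un$admission_dx == a, na.rm = TRUE), n2, do_test)) |>
    bind_rows()

  rows$icd <- cat_row("icd_hlh_diagnosis", "ever",
                      sum(tr$icd_timing != "never"), n1,
                      sum(un$icd_timing != "never"), n2, do_test)
  timing_levels <- c("before", "during", "after", "never")
  tim_tab <- vapply(timing_levels, function(a)
    c(sum(tr$icd_timing == a), sum(un$icd_timing == a)), numeric(2))
  keep <- colSums(tim_tab) > 0
  tim_test <- if (do_test && sum(keep) >= 2) two_group_test(t(tim_tab[, keep]))
  else tibble(statistic = NA_real_, p_value = NA_real_, method = "suppressed")
  rows$timing <- purrr::map(timing_levels, function(a) {
    tibble(variable = "icd_timing", level = a,
           n_treated = sum(tr$icd_timing == a),
           pct_treated = pct1(sum(tr$icd_timing == a), n1),
           n_untreated = sum(un$icd_timing == a),
           pct_untreated = pct1(sum(un$icd_timing == a), n2),
           method = tim_test$method, p_value = tim_test$p_value)
  }) |> bind_rows()

  crit_order <- c("ferritin", "fever", "cytopenia", "tg_or_fibrinogen",
                  "splenomegaly", "scd25", "hemophagocytosis", "low_nk")
  rows$criteria <- purrr::map(crit_order, function(cr) {
    m1 <- sum(tr[[paste0("measured_", cr)]])
    m2 <- sum(un[[paste0("measured_", cr)]])
    cat_row("criterion", cr, sum(tr[[cr]]), n1, sum(un[[cr]]), n2, do_test) |>
      mutate(measured_treated = m1, measured_untreated = m2,
             pct_of_measured_treated = pct1(sum(tr[[cr]]), m1),
             pct_of_measured_untreated = pct1(sum(un[[cr]]), m2))
  }) |> bind_rows()

  has_svc <- function(d, s) purrr::map_lgl(d$services, function(v) s %in% v)
  rows$services <- purrr::map(SERVICE_LEVELS, function(s)
    cat_row("service", s, sum(has_svc(tr, s)), n1,
            sum(has_svc(un, s)), n2, do_test)) |> bind_rows()

  for (out in c("icu", "in_hospital_death", "death_within_30d", "sct_after")) {
    rows[[out]] <- cat_row("outcome", out, sum(tr[[out]]), n1,
                           sum(un[[out]]), n2, do_test)
  }
  summary <- bind_rows(rows)

  los_test <- if (do_test) two_group_test(dat$los_days, !dat$treated) else
    tibble(statistic = NA_real_, p_value = NA_real_, method = "suppressed")
  continuous <- tibble(
    variable = "los_days",
    median_treated = if (n1) median(tr$los_days) else NA_real_,
    iqr_treated = if (n1) paste0(round(quantile(tr$los_days, .75), 1), "-",
                                 round(quantile(tr$los_days, .25), 1)) else NA,
    median_untreated = if (n2) median(un$los_days) else NA_real_,
    iqr_untreated = if (n2) paste0(round(quantile(un$los_days, .75), 1), "-",
                                   round(quantile(un$los_days, .25), 1)) else NA,
    method = los_test$method, p_value = los_test$p_value
  )

  effects <- NULL
  if (do_test) {
    rd_h <- risk_difference(sum(tr$in_hospital_death), n1,
                            sum(un$in_hospital_death), n2)
    rd_30 <- risk_difference(sum(tr$death_within_30d), n1,
                             sum(un$death_within_30d), n2)
    md <- median_difference(tr$los_days, un$los_days, n_boot = n_boot,
                            seed = seed)
    effects <- bind_rows(
      tibble(effect = "in_hospital_mortality_diff", estimate = rd_h$diff,
             estimate_unrounded = rd_h$diff_unrounded,
             conf_low = rd_h$conf_low, conf_high = rd_h$conf_high,
             unit = "percentage points"),
      tibble(effect = "mortality_30d_diff", estimate = rd_30$diff,
             estimate_unrounded = rd_30$diff_unrounded,
             conf_low = rd_30$conf_low, conf_high = rd_30$conf_high,
             unit = "percentage points"),
      tibble(effect = "median_los_diff", estimate = md$diff,
             estimate_unrounded = md$diff,
             conf_low = md$conf_low, conf_high = md$conf_high,
             unit = "days")
    )
  }
  structure(list(summary = summary, continuous = continuous,
                 effects = effects,
                 groups = c(treated = n1, untreated = n2)),
            class = "hlh_comparison")
}

#' @export
print.hlh_comparison <- function(x, ...) {
  cat("<hlh_comparison> HLH-directed therapy: treated n=", x$groups[["treated"]],
      ", untreated n=", x$groups[["untreated"]], "\n", sep = "")
  print(x$summary, n = 15)
  if (!is.null(x$effects)) print(x$effects)
  invisible(x)
}

#' @rdname compare_groups
#' @param x An `hlh_comparison`.
#' @param ... Unused.
#' @export
tidy.hlh_comparison <- function(x, ...) x$summary

#' @rdname compare_groups
#' @export
glance.hlh_comparison <- function(x, ...) {
  tibble(n_treated = unname(x$groups["treated"]),
         n_untreated = unname(x$groups["untreated"]),
         n_rows = nrow(x$summary),
         median_los_diff = if (!is.null(x$effects))
           x$effects$estimate[x$effects$effect == "median_los_diff"]
         else NA_real_)
}

#' Summarise the ferritin-plus-fever screening cohort
#'
#' For all screening encounters, those meeting the full criteria
#' threshold, and those below it, tabulates the prevalence of the six
#' remaining criteria (cytopenia, hypertriglyceridemia/
#' hypofibrinogenemia, splenomegaly, sCD25, hemophagocytosis, low NK
#' activity), the threshold stratum's share of all screening encounters,
#' and the number needed to screen `round(total / n_meeting)`.
#'
#' @param screening Output of [build_screening_cohort()].
#' @return An `hlh_screening_summary`: tibble of criterion-by-stratum
#'   rows with attributes `total`, `n_meet`, `share_pct`, `nns`.
#' @export
screening_summary <- function(screening) {
  other <- c("cytopenia", "tg_or_fibrinogen", "splenomegaly", "scd25",
             "hemophagocytosis", "low_nk")
  total <- nrow(screening)
  meets <- screening |> filter(.data$meets_threshold)
  below <- screening |> filter(!.data$meets_threshold)
  stratum_rows <- function(d, name) {
    purrr::map(other, function(cr) {
      tibble(stratum = name, criterion = cr, n_encounters = nrow(d),
             n = sum(d[[cr]]), pct = pct1(sum(d[[cr]]), nrow(d)),
             n_measured = sum(d[[paste0("measured_", cr)]]),
             pct_of_measured = pct1(sum(d[[cr]]),
                                    sum(d[[paste0("measured_", cr)]])))
    }) |> bind_rows()
  }
  out <- bind_rows(stratum_rows(screening, "all"),
                   stratum_rows(meets, "meets_threshold"),
                   stratum_rows(below, "below_threshold"))
  structure(out,
            class = c("hlh_screening_summary", class(out)),
            total = total, n_meet = nrow(meets),
            share_pct = pct1(nrow(meets), total),
            nns = if (nrow(meets) > 0) round(total / nrow(meets)) else NA_real_)
}

#' @export
print.hlh_screening_summary <- function(x, ...) {
  cat("<hlh_screening_summary> ", attr(x, "total"),
      " ferritin+fever encounters; ", attr(x, "n_meet"),
      " (", attr(x, "share_pct"), "%) meet the criteria threshold; ",
      "number needed to screen = ", attr(x, "nns"), "\n", sep = "")
  NextMethod()
}

#' @rdname screening_summary
#' @param x An `hlh_screening_summary`.
#' @param ... Unused.
#' @export
glance.hlh_screening_summary <- function(x, ...) {
  tibble(total_encounters = attr(x, "total"),
         n_meeting_threshold = attr(x, "n_meet"),
         share_pct = attr(x, "share_pct"),
         number_needed_to_screen = attr(x, "nns"))
}
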