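#' Study configuration for HLH phenotyping
#'
#' Assembles the full set of tunable constants used across the pipeline:
#' the study window, the operationalized HLH-2004 laboratory and fever
#' thresholds, the splenomegaly lexicon and negation rule, the
#' hemophagocytosis pathology patterns, the qualifying ICD-10 codes and
#' treatment-plan name patterns, the HLH-directed drug list, and the
#' 30-day mortality window.
#'
#' Defaults encode the operationalized HLH-2004 rules: ferritin >= 500 ug/L,
#' hemoglobin < 90 g/L (< 100 g/L for infants under 28 days at collection),
#' platelets < 100e9/L, neutrophils < 1.0e9/L, triglycerides >= 3.0 mmol/L,
#' fibrinogen <= 1.5 g/L, sCD25 >= 2400 U/mL, and fever as one oral reading
#' >= 38.3 C or a run of oral readings 38.0 C or above spanning at least 60
#' minutes. Diagnosis requires `criteria_required` (default 5) of the 8
#' criteria within one episode.
#'
#' @param path Optional path to a YAML file whose keys override defaults.
#' @param ... Named overrides applied after the file (e.g.
#'   `criteria_required = 4`).
#'
#' @return A list of class `hlh_config`.
#' @examples
#' cfg <- hlh_config()
#' cfg$thresholds$ferritin_min
#' hlh_config(criteria_required = 4)$criteria_required
#' @export
hlh_config <- function(path = NULL, ...) {
  cfg <- list(
    window_start = as.Date("2018-06-02"),
    window_end   = as.Date("2025-05-31"),
    thresholds = list(
      ferritin_min  = 500,   # ug/L, inclusive
      hgb_max       = 90,    # g/L, strict <
      hgb_max_infant = 100,  # g/L, strict <, age < infant_age_days
      infant_age_days = 28,
      plt_max       = 100,   # 10^9/L, strict <
      anc_max       = 1.0,   # 10^9/L, strict <
      tg_min        = 3.0,   # mmol/L, inclusive
      fib_max       = 1.5,   # g/L, inclusive
      scd25_min     = 2400,  # U/mL, inclusive
      fever_single  = 38.3,  # C
      fever_sustained_low  = 38.0,
      fever_sustained_high = 38.2,
      fever_sustained_minutes = 60
    ),
    criteria_required = 5L,
    strict_cytopenia_same_day = FALSE,
    splenomegaly_terms = c("splenomegaly", "big spleen", "organomegaly",
                           "enlarged spleen"),
    negation_terms = c("no", "none", "absence", "without", "negative"),
    negation_window_words = 3L,
    hemophagocytosis_patterns = c("hemophagocytosis", "haemophagocytosis",
                                  "hemophagocytic", "haemophagocytic"),
    hlh_icd_codes = c("D76.1", "D76.2"),
    plan_name_patterns = c("hlh", "hemophagocytosis", "haemophagocytosis"),
    hlh_directed_drugs = c("dexamethasone", "methylprednisolone", "anakinra",
                           "ruxolitinib", "cyclosporine", "etoposide",
                           "emapalumab"),
    steroid_drugs = c("dexamethasone", "methylprednisolone"),
    mortality_window_days = 30L
  )
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    over <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, over)
  }
  dots <- list(...)
  if (length(dots)) cfg <- merge_config(cfg, dots)
  cfg$window_start <- as.Date(cfg$window_start)
  cfg$window_end <- as.Date(cfg$window_end)
  validate_hlh_config(structure(cfg, class = "hlh_config"))
}

merge_config <- function(cfg, over) {
  stopifnot(is.list(over))
  bad <- setdiff(names(over), c(names(cfg), names(cfg$thresholds)))
  if (length(bad)) abort(paste0("unknown config key(s): ",
                                paste(bad, collapse = ", ")))
  for (k in names(over)) {
    if (k == "thresholds") {
      cfg$thresholds <- modifyList(cfg$thresholds, over$thresholds)
    } else if (k %in% names(cfg$thresholds)) {
      cfg$thresholds[[k]] <- over[[k]]
    } else {
      cfg[[k]] <- over[[k]]
    }
  }
  cfg
}

validate_hlh_config <- function(cfg) {
  th <- cfg$thresholds
  num <- vapply(th, function(x) is.numeric(x) && length(x) == 1 && !is.na(x),
                logical(1))
  if (!all(num)) {
    abort(paste0("non-numeric threshold(s): ",
                 paste(names(th)[!num], collapse = ", ")))
  }
  if (any(unlist(th) <= 0)) abort("all thresholds must be strictly positive")
  cr <- cfg$criteria_required
  if (!is.numeric(cr) || length(cr) != 1 || is.na(cr) || cr < 1 || cr > 8) {
    abort("criteria_required must be a single integer in [1, 8]")
  }
  cfg$criteria_required <- as.integer(cr)
  if (cfg$window_end < cfg$window_start) abort("window_end before window_start")
  if (cfg$negation_window_words < 0) abort("negation_window_words must be >= 0")
  cfg
}

#' @export
print.hlh_config <- function(x, ...) {
  cat("<hlh_config>\n")
  cat("  study window: ", format(x$window_start), " .. ",
      format(x$window_end), "\n", sep = "")
  cat("  criteria required:", x$criteria_required, "of 8\n")
  cat("  ferritin >=", x$thresholds$ferritin_min,
      "ug/L; sCD25 >=", x$thresholds$scd25_min, "U/mL\n")
  cat("  fever: >=", x$thresholds$fever_single, "C once, or >=",
      x$thresholds$fever_sustained_low, "C for >=",
      x$thresholds$fever_sustained_minutes, "min\n")
  invisible(x)
}

#' Write a configuration echo next to pipeline outputs
#' @param cfg An `hlh_config`.
#' @param path File path for the YAML echo.
#' @return `path`, invisibly.
#' @export
write_hlh_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "hlh_config"))
  out <- unclass(cfg)
  out$window_start <- format(out$window_start)
  out$window_end <- format(out$window_end)
  yaml::write_yaml(out, path)
  invisible(path)
}
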