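#' @name ehr_extract
#' @title The EHR extract bundle
#'
#' @description
#' An `ehr_extract` is a named list of 12 tibbles mirroring a
#' single-institution EHR export: `patients`, `encounters`, `labs`,
#' `temperatures`, `diagnoses`, `treatment_plans`, `medications`, `notes`,
#' `pathology`, `icu`, `services`, `sct`. All timestamps are timezone-naive
#' (stored as UTC POSIXct, minute resolution) and all laboratory values are
#' in canonical units: ferritin ug/L, hemoglobin g/L, platelets 10^9/L,
#' neutrophils 10^9/L, triglycerides mmol/L, fibrinogen g/L, sCD25 U/mL;
#' `nk_activity` is a 0/1 abnormal-low flag per the local laboratory
#' reference. Unit conversion is out of scope: extracts must be
#' pre-converted.
#'
#' Missing tables are filled with empty, correctly typed tibbles, so a
#' partial bundle (e.g. labs only) is still a valid extract.
NULL

LAB_ANALYTES <- c("ferritin", "hemoglobin", "platelets", "neutrophils",
                  "triglycerides", "fibrinogen", "scd25", "nk_activity")
SERVICE_LEVELS <- c("oncology", "hematology", "rheumatology",
                    "infectious diseases", "immunology", "neurology")

# column prototypes; order here fixes the on-disk column order
extract_schemas <- function() {
  dt <- as.POSIXct(character(), tz = "UTC")
  d <- as.Date(character())
  list(
    patients = tibble(patient_id = character(), sex = character(),
                      birth_date = d, death_date = d),
    encounters = tibble(encounter_id = character(), patient_id = character(),
                        encounter_class = character(), start = dt, end = dt,
                        admission_diagnosis = character(),
                        discharged_alive = logical()),
    labs = tibble(patient_id = character(), encounter_id = character(),
                  analyte = character(), value = double(), collected_at = dt),
    temperatures = tibble(patient_id = character(), encounter_id = character(),
                          taken_at = dt, temperature_c = double(),
                          route = character()),
    diagnoses = tibble(patient_id = character(), icd10_code = character(),
                       noted_at = dt, encounter_id = character()),
    treatment_plans = tibble(patient_id = character(), display_name = character(),
                             protocol_name = character(), applied_at = dt,
                             encounter_id = character()),
    medications = tibble(patient_id = character(), encounter_id = character(),
                         generic_name = character(), administered_at = dt,
                         is_chemotherapy = logical()),
    notes = tibble(patient_id = character(), encounter_id = character(),
                   authored_at = dt, text = character()),
    pathology = tibble(patient_id = character(), encounter_id = character(),
                       authored_at = dt, text = character(),
                       adjudicated_positive = logical()),
    icu = tibble(patient_id = character(), encounter_id = character(),
                 start = dt, end = dt),
    services = tibble(patient_id = character(), encounter_id = character(),
                      service = character()),
    sct = tibble(patient_id = character(), date = d)
  )
}

extract_files <- function() {
  c(patients = "patients.csv", encounters = "encounters.csv",
    labs = "labs.csv", temperatures = "temperatures.csv",
    diagnoses = "diagnoses.csv", treatment_plans = "treatment_plans.csv",
    medications = "medications.csv", notes = "notes.csv",
    pathology = "pathology.csv", icu = "icu.csv", services = "services.csv",
    sct = "sct.csv")
}

#' Construct and validate an EHR extract
#'
#' @param ... Named tables (any of `patients`, `encounters`, `labs`,
#'   `temperatures`, `diagnoses`, `treatment_plans`, `medications`, `notes`,
#'   `pathology`, `icu`, `services`, `sct`). Omitted tables default to empty.
#' @return A validated `ehr_extract`.
#' @examples
#' ex <- ehr_extract(
#'   patients = tibble::tibble(
#'     patient_id = "p1", sex = "female",
#'     birth_date = as.Date("2015-01-01"), death_date = as.Date(NA)
#'   )
#' )
#' nrow(ex$labs)
#' @export
ehr_extract <- function(...) {
  supplied <- list(...)
  schemas <- extract_schemas()
  bad <- setdiff(names(supplied), names(schemas))
  if (length(bad)) abort(paste0("unknown extract table(s): ",
                                paste(bad, collapse = ", ")))
  out <- schemas
  for (nm in names(supplied)) {
    out[[nm]] <- coerce_table(as_tibble(supplied[[nm]]), schemas[[nm]], nm)
  }
  validate_ehr_extract(structure(out, class = "ehr_extract"))
}

# fill absent optional columns, order columns, check types coercibly
coerce_table <- function(tbl, proto, name) {
  missing_cols <- setdiff(names(proto), names(tbl))
  for (mc in missing_cols) tbl[[mc]] <- proto[[mc]][NA_integer_][rep(1, nrow(tbl))]
  extra <- setdiff(names(tbl), names(proto))
  if (length(extra)) abort(paste0("table '", name, "': unexpected column(s) ",
                                  paste(extra, collapse = ", ")))
  for (cn in names(proto)) {
    tbl[[cn]] <- coerce_col(tbl[[cn]], proto[[cn]], name, cn)
  }
  tbl[names(proto)]
}

coerce_col <- function(x, proto, tbl, col) {
  ok <- tryCatch({
    if (inherits(proto, "POSIXct")) {
      x <- as.POSIXct(x, tz = "UTC")
      attr(x, "tzone") <- "UTC"
      # minute resolution
      x <- as.POSIXct(floor(as.numeric(x) / 60) * 60, tz = "UTC",
                      origin = "1970-01-01")
    } else if (inherits(proto, "Date")) {
      x <- as.Date(x)
    } else if (is.double(proto)) {
      x <- as.double(x)
    } else if (is.logical(proto)) {
      x <- as.logical(x)
    } else {
      x <- as.character(x)
    }
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(paste0("table '", tbl, "', column '", col,
                        "': cannot coerce to ", class(proto)[1]))
  x
}

row_fail <- function(tbl, rows, msg) {
  abort(paste0("table '", tbl, "': ", msg, " (row ",
               paste(head(which(rows), 5), collapse = ", "),
               if (sum(rows) > 5) ", ..." else "", ")"),
        class = "hlh_invariant_error")
}

#' Validate an EHR extract against the schema invariants
#'
#' Checks primary-key uniqueness, foreign keys, enumerated values,
#' non-negative laboratory values, the temperature plausibility range
#' (30-45 C), interval ordering, and death after birth. Fails with
#' row-level diagnostics.
#'
#' @param x An `ehr_extract` (or plain list of tables).
#' @return The validated extract, invisibly classed as `ehr_extract`.
#' @export
validate_ehr_extract <- function(x) {
  p <- x$patients; e <- x$encounters
  req_nonmissing <- function(tbl, name, cols) {
    for (cn in cols) {
      bad <- is.na(tbl[[cn]])
      if (any(bad)) row_fail(name, bad, paste0("missing ", cn))
    }
  }
  req_nonmissing(p, "patients", c("patient_id", "sex", "birth_date"))
  if (anyDuplicated(p$patient_id))
    row_fail(p, duplicated(p$patient_id), "duplicate patient_id")
  bad <- !p$sex %in% c("male", "female", "other")
  if (any(bad)) row_fail("patients", bad, "sex not in {male, female, other}")
  bad <- !is.na(p$death_date) & p$death_date < p$birth_date
  if (any(bad)) row_fail("patients", bad, "death_date before birth_date")

  req_nonmissing(e, "encounters", c("encounter_id", "patient_id",
                                    "encounter_class", "start"))
  if (anyDuplicated(e$encounter_id))
    row_fail(e, duplicated(e$encounter_id), "duplicate encounter_id")
  bad <- !e$encounter_class %in% c("inpatient", "outpatient")
  if (any(bad)) row_fail("encounters", bad, "bad encounter_class")
  bad <- !is.na(e$end) & e$end < e$start
  if (any(bad)) row_fail("encounters", bad, "end before start")
  fk_check(x, "encounters", "patient_id", p$patient_id)

  l <- x$labs
  req_nonmissing(l, "labs", c("patient_id", "encounter_id", "analyte",
                              "value", "collected_at"))
  bad <- !l$analyte %in% LAB_ANALYTES
  if (any(bad)) {
    abort(paste0("table 'labs': unknown analyte code(s): ",
                 paste(unique(l$analyte[bad]), collapse = ", ")),
          class = "hlh_invariant_error")
  }
  bad <- l$value < 0
  if (any(bad)) row_fail("labs", bad, "negative laboratory value")
  bad <- l$analyte == "nk_activity" & !l$value %in% c(0, 1)
  if (any(bad)) row_fail("labs", bad, "nk_activity must be 0/1 flag")
  fk_check(x, "labs", "encounter_id", e$encounter_id)

  tmp <- x$temperatures
  req_nonmissing(tmp, "temperatures", c("patient_id", "encounter_id",
                                        "taken_at", "temperature_c", "route"))
  bad <- tmp$temperature_c < 30 | tmp$temperature_c > 45
  if (any(bad)) row_fail("temperatures", bad, "temperature outside 30-45 C")
  bad <- !tmp$route %in% c("oral", "other")
  if (any(bad)) row_fail("temperatures", bad, "bad route")

  x$diagnoses$icd10_code <- stringr::str_trim(x$diagnoses$icd10_code)
  dg <- x$diagnoses
  req_nonmissing(dg, "diagnoses", c("patient_id", "icd10_code", "noted_at"))
  bad <- !grepl("^[A-Za-z][0-9]+(\\.[0-9]+)?$", dg$icd10_code)
  if (any(bad)) row_fail("diagnoses", bad, "malformed icd10_code")

  tp <- x$treatment_plans
  req_nonmissing(tp, "treatment_plans", c("patient_id", "applied_at"))
  dn <- dplyr::coalesce(tp$display_name, "")
  pn <- dplyr::coalesce(tp$protocol_name, "")
  bad <- dn == "" & pn == ""
  if (any(bad)) row_fail("treatment_plans", bad,
                         "both display_name and protocol_name empty")

  md <- x$medications
  req_nonmissing(md, "medications", c("patient_id", "encounter_id",
                                      "generic_name", "administered_at",
                                      "is_chemotherapy"))
  bad <- md$generic_name == ""
  if (any(bad)) row_fail("medications", bad, "empty generic_name")

  nt <- x$notes
  req_nonmissing(nt, "notes", c("patient_id", "encounter_id", "authored_at"))
  if (any(is.na(nt$text))) nt$text[is.na(nt$text)] <- ""
  x$notes <- nt
  pt <- x$pathology
  req_nonmissing(pt, "pathology", c("patient_id", "encounter_id", "authored_at"))
  if (any(is.na(pt$text))) pt$text[is.na(pt$text)] <- ""
  x$pathology <- pt

  ic <- x$icu
  req_nonmissing(ic, "icu", c("patient_id", "encounter_id", "start", "end"))
  bad <- ic$end < ic$start
  if (any(bad)) row_fail("icu", bad, "interval end before start")

  sv <- x$services
  req_nonmissing(sv, "services", c("patient_id", "encounter_id", "service"))
  bad <- !sv$service %in% SERVICE_LEVELS
  if (any(bad)) row_fail("services", bad, "unknown service label")

  sc <- x$sct
  req_nonmissing(sc, "sct", c("patient_id", "date"))

  invisible(structure(x, class = "ehr_extract"))
}

fk_check <- function(x, tbl, col, keys) {
  v <- x[[tbl]][[col]]
  bad <- !is.na(v) & !v %in% keys
  if (any(bad)) row_fail(tbl, bad, paste0("unknown ", col))
}

#' @export
print.ehr_extract <- function(x, ...) {
  cat("<ehr_extract>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

sort_extract <- function(x) {
  ord <- function(tbl) tbl[do.call(order, unname(as.list(tbl))), , drop = FALSE]
  for (nm in names(x)) x[[nm]] <- as_tibble(ord(x[[nm]]))
  x
}

fmt_dt <- function(x) ifelse(is.na(x), NA_character_,
                             format(x, "%Y-%m-%d %H:%M", tz = "UTC"))

#' Read an EHR extract from a directory of CSV files
#'
#' Expects `patients.csv`, `encounters.csv`, `labs.csv`, `temperatures.csv`,
#' `diagnoses.csv`, `treatment_plans.csv`, `medications.csv`, `notes.csv`,
#' `pathology.csv`, `icu.csv`, `services.csv`, `sct.csv` with fixed headers
#' (UTF-8, RFC-4180). A header-only file yields an empty table; a missing
#' file is fatal. Rows violating schema invariants abort with row-level
#' diagnostics. Tables are returned canonically sorted.
#'
#' @param dir Directory containing the CSV files.
#' @return A validated `ehr_extract`.
#' @seealso [write_ehr_extract()]
#' @export
read_ehr_extract <- function(dir) {
  files <- extract_files()
  paths <- file.path(dir, files)
  miss <- !file.exists(paths)
  if (any(miss)) abort(paste0("missing required file(s): ",
                              paste(files[miss], collapse = ", ")))
  schemas <- extract_schemas()
  tabs <- list()
  for (i in seq_along(files)) {
    nm <- names(files)[i]
    proto <- schemas[[nm]]
    spec <- readr::as.col_spec(purrr::map_chr(proto, function(col) {
      if (inherits(col, "POSIXct")) "c"
      else if (inherits(col, "Date")) "D"
      else if (is.double(col)) "d"
      else if (is.logical(col)) "l"
      else "c"
    }))
    tbl <- readr::read_csv(paths[i], col_types = spec, progress = FALSE,
                           na = c("", "NA"))
    probs <- readr::problems(tbl)
    if (nrow(probs)) {
      abort(paste0("file '", files[i], "': parse failure at row(s) ",
                   paste(head(probs$row, 5), collapse = ", ")))
    }
    tabs[[nm]] <- tbl
  }
  sort_extract(do.call(ehr_extract, tabs))
}

#' Write an EHR extract to a directory of CSV files
#'
#' Deterministic output: fixed column order, rows sorted canonically,
#' RFC-4180 quoting, timestamps as `YYYY-mm-dd HH:MM`. Together with
#' [read_ehr_extract()] this round-trips a validated extract identically.
#'
#' @param x An `ehr_extract`.
#' @param dir Output directory (created if needed).
#' @param config Optional `hlh_config` echoed alongside as `config.yaml`.
#' @return `dir`, invisibly.
#' @export
write_ehr_extract <- function(x, dir, config = NULL) {
  x <- validate_ehr_extract(x)
  x <- sort_extract(x)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- extract_files()
  for (nm in names(files)) {
    tbl <- x[[nm]]
    tbl <- dplyr::mutate(tbl, across(dplyr::where(function(c)
      inherits(c, "POSIXct")), fmt_dt))
    readr::write_csv(tbl, file.path(dir, files[[nm]]), na = "",
                     progress = FALSE)
  }
  if (!is.null(config)) write_hlh_config(config, file.path(dir, "config.yaml"))
  invisible(dir)
}
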