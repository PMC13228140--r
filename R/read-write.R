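#' Readers and writers for the pipeline's file formats
#'
#' All exchange files are comma-separated UTF-8 with a header row (RFC 4180
#' quoting), the portable equivalent of the standardized spreadsheet formats
#' used in chart-review workflows. Dates are ISO-8601 (`YYYY-MM-DD`).
#' Readers validate the stated invariants and fail with an error naming the
#' offending column, row, or value; they never silently drop records.
#'
#' @name ali_io
NULL

read_csv_strict <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, show_col_types = FALSE)
}

#' Read a patient cohort file
#'
#' Expects columns `patient_id`, `age`, `sex`, `engaged` (plus optional
#' `race`, `ethnicity`). `engaged` records whether the patient had at least
#' one emergency department visit or hospitalization during the study
#' period. Sex is normalized to lowercase `male`/`female`; `engaged` to
#' logical.
#'
#' @param path Path to a cohort CSV.
#' @return Tibble with one row per patient.
#' @export
read_cohort <- function(path) {
  raw <- read_csv_strict(path, "cohort")
  require_columns(raw, c("patient_id", "age", "sex", "engaged"), "cohort file")
  dup <- unique(raw$patient_id[duplicated(raw$patient_id)])
  if (length(dup) > 0) {
    stop("duplicate patient_id in cohort: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    patient_id = raw$patient_id,
    age = as.numeric(raw$age),
    sex = normalize_sex(raw$sex),
    race = if ("race" %in% names(raw)) raw$race else NA_character_,
    ethnicity = if ("ethnicity" %in% names(raw)) raw$ethnicity else NA_character_,
    engaged = parse_logical_flag(raw$engaged, "engaged"))
  if (any(is.na(out$age) & !is.na(raw$age))) {
    stop("non-numeric age value(s) in cohort", call. = FALSE)
  }
  out
}

#' @rdname ali_io
#' @param cohort Cohort tibble as returned by [read_cohort()].
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Read an ICD-10 code dictionary
#'
#' Two-column CSV (`code`, `description`) mapping ICD-10 codes to free-text
#' descriptions; the matching substrate. Exact duplicate rows are collapsed
#' with a warning; the same code with conflicting descriptions is an error.
#'
#' @param path Path to the catalog CSV.
#' @return Tibble with columns `code`, `description`, class
#'   `ali_icd10_catalog`.
#' @export
read_icd10_catalog <- function(path) {
  raw <- read_csv_strict(path, "ICD-10 catalog")
  require_columns(raw, c("code", "description"), "ICD-10 catalog file")
  if (any(is.na(raw$code) | raw$code == "")) {
    stop("ICD-10 catalog contains empty code(s)", call. = FALSE)
  }
  dup_rows <- duplicated(raw[, c("code", "description")])
  if (any(dup_rows)) {
    warning("ICD-10 catalog: ", sum(dup_rows),
            " exact duplicate row(s) collapsed", call. = FALSE)
    raw <- raw[!dup_rows, ]
  }
  conflicting <- unique(raw$code[duplicated(raw$code)])
  if (length(conflicting) > 0) {
    stop("ICD-10 catalog has conflicting descriptions for code(s): ",
         paste(conflicting, collapse = ", "), call. = FALSE)
  }
  icd10_catalog(raw)
}

#' Construct an ICD-10 catalog from a data frame
#'
#' @param df Data frame with columns `code`, `description`.
#' @return Tibble of class `ali_icd10_catalog`.
#' @export
icd10_catalog <- function(df) {
  require_columns(df, c("code", "description"), "catalog")
  stopifnot(!anyDuplicated(df$code))
  out <- tibble::as_tibble(df[, c("code", "description")])
  class(out) <- c("ali_icd10_catalog", class(out))
  out
}

#' @rdname ali_io
#' @param catalog Catalog tibble.
#' @export
write_icd10_catalog <- function(catalog, path) {
  readr::write_csv(tibble::as_tibble(catalog)[, c("code", "description")],
                   path, na = "")
  invisible(path)
}

#' Read patient diagnosis records
#'
#' Columns `patient_id`, `code`, `date` (ISO-8601). Codes absent from the
#' supplied catalog are retained but flagged `resolved = FALSE` -- they can
#' never match a roadmap term, but keeping them preserves per-patient code
#' counts. Unparseable dates are a row-level error naming the data row.
#'
#' @param path Path to a diagnoses CSV.
#' @param catalog Optional `ali_icd10_catalog` used to flag resolvability.
#' @return Tibble with columns `patient_id`, `code`, `date`, `resolved`.
#' @export
read_diagnoses <- function(path, catalog = NULL) {
  raw <- read_csv_strict(path, "diagnoses")
  require_columns(raw, c("patient_id", "code", "date"), "diagnoses file")
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(date) & !is.na(raw$date) & raw$date != "")
  if (length(bad) > 0) {
    stop(sprintf("unparseable date %s in diagnoses row %d",
                 raw$date[bad[1]], bad[1]), call. = FALSE)
  }
  out <- tibble::tibble(patient_id = raw$patient_id, code = raw$code, date = date)
  out$resolved <- if (is.null(catalog)) NA else out$code %in% catalog$code
  if (!is.null(catalog) && any(!out$resolved)) {
    message(sum(!out$resolved), " diagnosis record(s) carry codes not in the catalog")
  }
  out
}

#' @rdname ali_io
#' @param diagnoses Diagnoses tibble.
#' @export
write_diagnoses <- function(diagnoses, path) {
  readr::write_csv(diagnoses[, c("patient_id", "code", "date")], path, na = "")
  invisible(path)
}

#' Read a long-format biomarker file
#'
#' Columns `patient_id`, `component`, `value`; a blank value means the
#' biomarker was not measured (missing), the pipeline's central concern.
#'
#' @param path Path to a biomarkers CSV.
#' @return Tibble with columns `patient_id`, `component`, `value` (numeric,
#'   `NA` = missing).
#' @export
read_biomarkers <- function(path) {
  raw <- read_csv_strict(path, "biomarkers")
  require_columns(raw, c("patient_id", "component", "value"), "biomarkers file")
  assert_components(raw$component)
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(value) & !is.na(raw$value) & raw$value != "")
  if (length(bad) > 0) {
    stop(sprintf("non-numeric biomarker value %s in row %d",
                 raw$value[bad[1]], bad[1]), call. = FALSE)
  }
  tibble::tibble(patient_id = raw$patient_id, component = raw$component,
                 value = value)
}

#' @rdname ali_io
#' @param biomarkers Biomarkers tibble.
#' @export
write_biomarkers <- function(biomarkers, path) {
  readr::write_csv(biomarkers[, c("patient_id", "component", "value")],
                   path, na = "")
  invisible(path)
}

#' Read chart-review records
#'
#' Columns `patient_id`, `component`, `reviewed_status` with statuses in the
#' four-way set (`UNHEALTHY`, `HEALTHY`, `MISSING`, `PROTOCOL_ERROR`). At
#' most one record per (patient, component); each reviewed patient carries
#' exactly ten.
#'
#' @param path Path to a chart-review CSV.
#' @return Tibble with columns `patient_id`, `component`, `reviewed_status`.
#' @export
read_chart_review <- function(path) {
  raw <- read_csv_strict(path, "chart review")
  require_columns(raw, c("patient_id", "component", "reviewed_status"),
                  "chart review file")
  assert_components(raw$component)
  assert_statuses(raw$reviewed_status, arg = "reviewed_status")
  key <- paste(raw$patient_id, raw$component)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, component) in chart review: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  per_patient <- table(raw$patient_id)
  if (any(per_patient != 10)) {
    stop("chart review must contain exactly 10 components per reviewed patient; ",
         "offending patient_id: ", names(per_patient)[per_patient != 10][1],
         call. = FALSE)
  }
  tibble::tibble(patient_id = raw$patient_id, component = raw$component,
                 reviewed_status = raw$reviewed_status)
}

#' @rdname ali_io
#' @param chart_review Chart-review tibble.
#' @export
write_chart_review <- function(chart_review, path) {
  readr::write_csv(chart_review[, c("patient_id", "component", "reviewed_status")],
                   path, na = "")
  invisible(path)
}
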