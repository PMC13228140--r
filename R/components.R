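#' The ten allostatic load index components
#'
#' The allostatic load index (ALI) summarizes physiological "wear and tear"
#' as the proportion of ten biomarkers falling in the unhealthy range. The
#' ten components span three body systems: cardiovascular (systolic and
#' diastolic blood pressure), metabolic (body mass index, triglycerides,
#' total cholesterol), and inflammation (C-reactive protein, hemoglobin A1c,
#' serum albumin, creatinine clearance, homocysteine).
#'
#' @return A tibble with one row per component and columns `component`
#'   (short code used throughout the package), `label` (human-readable
#'   biomarker name), `body_system`, and `unhealthy_direction` (`"high"` or
#'   `"low"`, the side of the clinical threshold considered unhealthy).
#' @examples
#' ali_components()
#' @export
ali_components <- function() {
  tibble::tribble(
    ~component, ~label,                      ~body_system,     ~unhealthy_direction,
    "SBP",      "systolic blood pressure",   "cardiovascular", "high",
    "DBP",      "diastolic blood pressure",  "cardiovascular", "high",
    "BMI",      "body mass index",           "metabolic",      "high",
    "TRIG",     "triglycerides",             "metabolic",      "high",
    "CHOL",     "total cholesterol",         "metabolic",      "high",
    "CRP",      "C-reactive protein",        "inflammation",   "high",
    "HBA1C",    "hemoglobin A1c",            "inflammation",   "high",
    "ALB",      "serum albumin",             "inflammation",   "high",
    "CC",       "creatinine clearance",      "inflammation",   "low",
    "HCST",     "homocysteine",              "inflammation",   "high"
  )
}

#' Component identifiers
#'
#' @return Character vector of the ten component codes, in canonical order.
#' @export
component_ids <- function() ali_components()$component

#' The four mutually exclusive data-point statuses
#'
#' Every patient-by-component data point is in exactly one of four states:
#' `UNHEALTHY`, `HEALTHY`, `MISSING`, or (for chart-review records only)
#' `PROTOCOL_ERROR` -- a point that was missing in the extracted EHR data but
#' where the reviewer recorded a value from outside the study period instead
#' of applying the roadmap.
#'
#' @return Character vector of the four status labels.
#' @export
status_levels <- function() c("UNHEALTHY", "HEALTHY", "MISSING", "PROTOCOL_ERROR")

assert_components <- function(x, arg = "component") {
  bad <- setdiff(unique(x), component_ids())
  if (length(bad) > 0) {
    stop(sprintf("unknown %s label(s): %s", arg, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

assert_statuses <- function(x, allowed = status_levels(), arg = "status") {
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0) {
    stop(sprintf("invalid %s value(s): %s (allowed: %s)", arg,
                 paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
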