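#' Load the clinical threshold table
#'
#' Thresholds ship as editable YAML so that alternative ALI definitions can
#' be explored without code changes. Each component has exactly one rule; the
#' creatinine-clearance rule is the only sex-specific one.
#'
#' @param path Path to a thresholds YAML file. Defaults to the table shipped
#'   with the package.
#' @return A tibble with columns `component`, `direction` (one of `greater`,
#'   `greater_equal`, `less`, `less_equal`), `cutoff_male`, `cutoff_female`
#'   (equal except for CC), and `units`.
#' @export
ali_thresholds <- function(path = system.file("extdata", "thresholds.yaml",
                                              package = "alirecover")) {
  raw <- yaml::read_yaml(path)
  assert_components(names(raw))
  missing <- setdiff(component_ids(), names(raw))
  if (length(missing) > 0) {
    stop("thresholds file lacks rule(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- purrr::imap(raw, function(rule, comp) {
    stopifnot(rule$direction %in% c("greater", "greater_equal", "less", "less_equal"))
    cut <- rule$cutoff
    if (is.list(cut)) {
      tibble::tibble(component = comp, direction = rule$direction,
                     cutoff_male = as.numeric(cut$male),
                     cutoff_female = as.numeric(cut$female),
                     units = rule$units %||% NA_character_)
    } else {
      tibble::tibble(component = comp, direction = rule$direction,
                     cutoff_male = as.numeric(cut), cutoff_female = as.numeric(cut),
                     units = rule$units %||% NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows)
  out[match(component_ids(), out$component), ]
}

sex_specific_components <- function(thresholds = ali_thresholds()) {
  thresholds$component[thresholds$cutoff_male != thresholds$cutoff_female]
}

#' Discretize biomarker values at the clinical thresholds
#'
#' Converts numeric biomarker measurements to the three-way status used by
#' the recovery pipeline: `UNHEALTHY` if the value satisfies the component's
#' threshold rule, `HEALTHY` otherwise, and `MISSING` when the value is
#' absent (`NA`). The boundary semantics follow the printed inequality
#' strictness exactly (e.g. SBP > 140 is strict, TRIG >= 150 is inclusive).
#'
#' @param component Character vector of component codes (recycled against
#'   `value`).
#' @param value Numeric vector of measurements; `NA` means unmeasured.
#' @param sex Optional character vector (`"male"`/`"female"`), required
#'   whenever a sex-specific component (creatinine clearance) is discretized
#'   with a non-missing value.
#' @param thresholds Threshold table from [ali_thresholds()].
#' @return Character vector of statuses in
#'   `{UNHEALTHY, HEALTHY, MISSING}`.
#' @examples
#' discretize("SBP", c(150, 140, NA))
#' discretize("CC", 105, sex = c("male", "female"))
#' @export
discretize <- function(component, value, sex = NULL,
                       thresholds = ali_thresholds()) {
  n <- max(length(component), length(value), length(sex %||% character()))
  component <- rep_len(component, n)
  value <- rep_len(value, n)
  assert_components(component)
  needs_sex <- component %in% sex_specific_components(thresholds) & !is.na(value)
  if (any(needs_sex)) {
    if (is.null(sex)) {
      stop("sex is required to discretize sex-specific component(s): ",
           paste(unique(component[needs_sex]), collapse = ", "), call. = FALSE)
    }
    sex <- rep_len(sex, n)
    bad <- needs_sex & (is.na(sex) | !sex %in% c("male", "female"))
    if (any(bad)) {
      stop("sex must be 'male' or 'female' for sex-specific components",
           call. = FALSE)
    }
  }
  sex <- if (is.null(sex)) rep_len("female", n) else rep_len(sex, n)
  idx <- match(component, thresholds$component)
  cutoff <- ifelse(!is.na(sex) & sex == "male",
                   thresholds$cutoff_male[idx], thresholds$cutoff_female[idx])
  direction <- thresholds$direction[idx]
  unhealthy <- dplyr::case_when(
    direction == "greater" ~ value > cutoff,
    direction == "greater_equal" ~ value >= cutoff,
    direction == "less" ~ value < cutoff,
    direction == "less_equal" ~ value <= cutoff
  )
  dplyr::case_when(
    is.na(value) ~ "MISSING",
    unhealthy ~ "UNHEALTHY",
    .default = "HEALTHY"
  )
}

#' Discretize a biomarker table into component records
#'
#' Convenience wrapper turning a long biomarker table (one row per patient
#' and component, `NA` value = unmeasured) into the component-record table
#' the recovery pipeline consumes. Components absent from the table for a
#' patient are filled in as `MISSING`.
#'
#' @param biomarkers Tibble with columns `patient_id`, `component`, `value`.
#' @param cohort Cohort tibble (for `sex`); must contain `patient_id`, `sex`.
#' @param thresholds Threshold table from [ali_thresholds()].
#' @return Tibble with columns `patient_id`, `component`, `value`, `status`,
#'   one row per patient and component (10 per patient).
#' @export
discretize_biomarkers <- function(biomarkers, cohort,
                                  thresholds = ali_thresholds()) {
  require_columns(biomarkers, c("patient_id", "component", "value"), "biomarkers")
  require_columns(cohort, c("patient_id", "sex"), "cohort")
  assert_components(biomarkers$component)
  grid <- tidyr::expand_grid(patient_id = unique(cohort$patient_id),
                             component = component_ids())
  full <- dplyr::left_join(grid, biomarkers, by = c("patient_id", "component"))
  full <- dplyr::left_join(full, cohort[, c("patient_id", "sex")], by = "patient_id")
  full$status <- discretize(full$component, full$value, full$sex, thresholds)
  dplyr::arrange(full[, c("patient_id", "component", "value", "status")],
                 .data$patient_id, match(.data$component, component_ids()))
}

#' Compute per-patient allostatic load index scores
#'
#' The ALI is the proportion of components in the unhealthy range. In
#' `"nonmissing"` mode (the default) the denominator is the number of
#' non-missing components; in `"all10"` mode it is fixed at 10. A patient
#' with all ten components missing has an undefined score in nonmissing mode
#' (`ali = NA`, `ali_defined = FALSE`).
#'
#' @param records Component-record tibble with columns `patient_id`,
#'   `component`, `status` (statuses in `{UNHEALTHY, HEALTHY, MISSING}`);
#'   exactly one row per patient and component.
#' @param mode Denominator mode, `"nonmissing"` or `"all10"`.
#' @return A tibble with columns `patient_id`, `n_unhealthy`,
#'   `n_nonmissing`, `ali`, `ali_defined`.
#' @examples
#' recs <- tibble::tibble(
#'   patient_id = "p1", component = component_ids(),
#'   status = c(rep("UNHEALTHY", 2), rep("HEALTHY", 4), rep("MISSING", 4)))
#' compute_ali(recs) # 2 / 6
#' @export
compute_ali <- function(records, mode = c("nonmissing", "all10")) {
  mode <- match.arg(mode)
  require_columns(records, c("patient_id", "component", "status"), "records")
  assert_statuses(records$status, c("UNHEALTHY", "HEALTHY", "MISSING"))
  counts <- dplyr::count(records, .data$patient_id, .data$component)
  if (any(counts$n > 1)) {
    stop("duplicate (patient, component) records for: ",
         paste(utils::head(unique(counts$patient_id[counts$n > 1]), 5),
               collapse = ", "), call. = FALSE)
  }
  per_patient <- dplyr::summarise(
    dplyr::group_by(records, .data$patient_id),
    n_unhealthy = sum(.data$status == "UNHEALTHY"),
    n_nonmissing = sum(.data$status != "MISSING"),
    n_components = dplyr::n(),
    .groups = "drop")
  if (any(per_patient$n_components != 10)) {
    stop("each patient must have exactly one record per component (10 total)",
         call. = FALSE)
  }
  per_patient$ali <- switch(mode,
    nonmissing = ifelse(per_patient$n_nonmissing == 0, NA_real_,
                        per_patient$n_unhealthy / per_patient$n_nonmissing),
    all10 = per_patient$n_unhealthy / 10)
  per_patient$ali_defined <- !is.na(per_patient$ali)
  per_patient$denominator_mode <- mode
  per_patient[, c("patient_id", "n_unhealthy", "n_nonmissing", "ali",
                  "ali_defined", "denominator_mode")]
}
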