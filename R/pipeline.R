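#' Pipeline run configuration
#'
#' Bundles and validates the resolved settings of a pipeline run: input
#' paths, roadmap selection, matching mode, ALI denominator mode, seed, and
#' output directory. Every command writes a `manifest.json` of these
#' settings (plus the package version) into its output directory so a run
#' can be reproduced.
#'
#' @param out_dir Output directory.
#' @param cohort,biomarkers,diagnoses,catalog,roadmap,chart_review Input
#'   file paths (those required by the command must exist at validation
#'   time; `chart_review` is optional).
#' @param mode Matching mode, `"token"` or `"substring"`.
#' @param denominator ALI denominator mode, `"nonmissing"` or `"all10"`.
#' @param seed Integer seed for any randomness.
#' @return List of class `ali_run_config`.
#' @export
run_config <- function(out_dir, cohort = NULL, biomarkers = NULL,
                       diagnoses = NULL, catalog = NULL, roadmap = NULL,
                       chart_review = NULL,
                       mode = c("token", "substring"),
                       denominator = c("nonmissing", "all10"),
                       seed = 1) {
  cfg <- list(out_dir = out_dir, cohort = cohort, biomarkers = biomarkers,
              diagnoses = diagnoses, catalog = catalog, roadmap = roadmap,
              chart_review = chart_review,
              mode = match.arg(mode), denominator = match.arg(denominator),
              seed = as.integer(seed))
  for (field in c("cohort", "biomarkers", "diagnoses", "catalog", "roadmap",
                  "chart_review")) {
    p <- cfg[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("config field %s refers to a missing file: %s", field, p),
           call. = FALSE)
    }
  }
  class(cfg) <- "ali_run_config"
  cfg
}

write_manifest <- function(cfg, command, extra = list()) {
  manifest <- c(list(command = command,
                     package_version = as.character(utils::packageVersion("alirecover")),
                     timestamp = format(Sys.time(), tz = "UTC")),
                unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))], extra)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a synthetic study to disk
#'
#' Generates a synthetic EHR study under `generator` (defaulting to the
#' package's study conditions) and writes the fixture bundle plus a run
#' manifest into `cfg$out_dir`.
#'
#' @param cfg An `ali_run_config` (only `out_dir` and `seed` are used).
#' @param generator An `ali_generator_config`; its seed is overridden by
#'   `cfg$seed`.
#' @param rm Roadmap used for code carriage (default: the shipped
#'   clinicians' original).
#' @return The synthetic study, invisibly.
#' @export
cmd_simulate <- function(cfg, generator = NULL, rm = original_roadmap()) {
  stopifnot(inherits(cfg, "ali_run_config"))
  if (is.null(generator)) generator <- generator_config(seed = cfg$seed)
  generator$seed <- cfg$seed
  validate_generator_config(generator)
  catalog <- generate_catalog(rm, seed = cfg$seed)
  study <- generate_cohort(generator, rm, catalog)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  write_fixture_bundle(study, cfg$out_dir)
  write_manifest(cfg, "simulate",
                 list(n_patients = generator$n_patients,
                      n_review = generator$n_review))
  invisible(study)
}

#' Run the recovery algorithm over files on disk
#'
#' Reads the configured inputs, discretizes biomarkers, reclassifies
#' chart-review protocol errors when a chart-review file is supplied,
#' expands the roadmap against the catalog, recovers missing components,
#' and writes `recovery_results.csv`, `match_report.json`, and the run
#' manifest.
#'
#' @param cfg An `ali_run_config` with `cohort`, `biomarkers`, `diagnoses`,
#'   `catalog`, and `roadmap` set (plus optionally `chart_review`).
#' @return The `ali_recovery` results, invisibly.
#' @export
cmd_recover <- function(cfg) {
  stopifnot(inherits(cfg, "ali_run_config"))
  for (field in c("cohort", "biomarkers", "diagnoses", "catalog", "roadmap")) {
    if (is.null(cfg[[field]])) stop("config field ", field, " is required",
                                    call. = FALSE)
  }
  cohort <- read_cohort(cfg$cohort)
  catalog <- read_icd10_catalog(cfg$catalog)
  diagnoses <- read_diagnoses(cfg$diagnoses, catalog)
  rm <- parse_roadmap(cfg$roadmap)
  if (nrow(rm) == 0) warning("roadmap is empty: no recoveries are possible",
                             call. = FALSE)
  records <- if (!is.null(cfg$chart_review)) {
    reclassify_protocol_errors(read_chart_review(cfg$chart_review))
  } else {
    discretize_biomarkers(read_biomarkers(cfg$biomarkers), cohort)
  }
  universe <- expand_roadmap(rm, catalog, mode = cfg$mode)
  results <- recover(records, diagnoses, universe)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  write_recovery_results(results, file.path(cfg$out_dir, "recovery_results.csv"))
  write_match_report(universe, diagnoses,
                     file.path(cfg$out_dir, "match_report.json"))
  write_manifest(cfg, "recover",
                 list(roadmap_name = roadmap_name(rm),
                      recovery = recovery_counts(results)))
  invisible(results)
}

#' Evaluate a recovery run and write the report
#'
#' Runs the algorithm as in [cmd_recover()] on the extracted-EHR records,
#' evaluates it (flow accounting, missingness summaries, ALI shift,
#' engagement regressions, and -- when a chart-review file is supplied --
#' the disagreement report on the reviewed subset), and writes
#' `evaluation_report.json`, `scatter_export.csv` (per-patient pre/post ALI
#' pairs), and the manifest.
#'
#' @param cfg An `ali_run_config` as for [cmd_recover()].
#' @return The `ali_evaluation`, invisibly.
#' @export
cmd_evaluate <- function(cfg) {
  stopifnot(inherits(cfg, "ali_run_config"))
  cohort <- read_cohort(cfg$cohort)
  catalog <- read_icd10_catalog(cfg$catalog)
  diagnoses <- read_diagnoses(cfg$diagnoses, catalog)
  rm <- parse_roadmap(cfg$roadmap)
  universe <- expand_roadmap(rm, catalog, mode = cfg$mode)
  ehr <- discretize_biomarkers(read_biomarkers(cfg$biomarkers), cohort)
  algo <- recover(ehr, diagnoses, universe)
  chart_results <- NULL
  if (!is.null(cfg$chart_review)) {
    chart <- reclassify_protocol_errors(read_chart_review(cfg$chart_review))
    reviewed <- unique(chart$patient_id)
    ehr_sub <- ehr[ehr$patient_id %in% reviewed, , drop = FALSE]
    # the chart source "recovers" whatever it marked unhealthy among points
    # missing in the extracted EHR; express it as a recovery result so the
    # disagreement taxonomy applies symmetrically
    chart_results <- chart_as_recovery(ehr_sub, chart)
    algo_sub <- recover(ehr_sub, diagnoses, universe)
    evaluation <- evaluate_recovery(ehr, algo, cohort, chart = NULL,
                                    mode = cfg$denominator)
    evaluation$disagreements <- disagreements(chart_results, algo_sub)
  } else {
    evaluation <- evaluate_recovery(ehr, algo, cohort, mode = cfg$denominator)
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  write_evaluation_report(evaluation,
                          file.path(cfg$out_dir, "evaluation_report.json"))
  readr::write_csv(evaluation$scatter,
                   file.path(cfg$out_dir, "scatter_export.csv"), na = "")
  write_manifest(cfg, "evaluate", list(roadmap_name = roadmap_name(rm)))
  invisible(evaluation)
}

#' Express chart-review findings as a recovery result
#'
#' Restricted to points missing in the extracted EHR data, a chart review
#' acts like a (human) recovery algorithm: a missing point it marked
#' `UNHEALTHY` counts as recovered. Protocol errors must already be
#' reclassified to missing.
#'
#' @param ehr Extracted-EHR component records for the reviewed patients.
#' @param chart Reclassified chart records (`patient_id`, `component`,
#'   `status`).
#' @return An `ali_recovery` with empty evidence lists.
#' @export
chart_as_recovery <- function(ehr, chart) {
  key_e <- paste(ehr$patient_id, ehr$component)
  key_c <- paste(chart$patient_id, chart$component)
  if (!setequal(key_e, key_c)) {
    stop("chart and EHR records must cover the same universe", call. = FALSE)
  }
  chart_status <- chart$status[match(key_e, key_c)]
  post <- ifelse(ehr$status == "MISSING" & chart_status == "UNHEALTHY",
                 "UNHEALTHY", ehr$status)
  out <- tibble::tibble(
    patient_id = ehr$patient_id, component = ehr$component,
    pre_status = ehr$status, post_status = post,
    evidence = rep(list(tibble::tibble(code = character(), term = character())),
                   nrow(ehr)))
  class(out) <- c("ali_recovery", class(out))
  out
}
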