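#' Synthetic EHR study configuration
#'
#' Defines the conditions of a simulated cohort study with known ground
#' truth. Defaults emulate the printed marginals of a 1000-patient primary
#' care EHR sample: blood pressures never missing, BMI almost never,
#' C-reactive protein and homocysteine missing for ~95% and ~98% of
#' patients, a per-patient median of 6 non-missing components, ~30 noise
#' diagnosis codes per patient, ~32% engagement in care driven by the true
#' ALI, a 100-patient chart-review subset balanced 50/50 on engagement,
#' chart reviews recovering ~11% of missing points, and a ~1% protocol
#' error rate among missing points.
#'
#' Per-component parameters accept a scalar (recycled), or a named vector
#' naming any subset of components (unnamed defaults retained).
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; all generator randomness flows from it.
#' @param measurement_prob Per-component probability that the biomarker is
#'   measured (observed) in the extracted EHR data.
#' @param prevalence Per-component probability that the patient is truly
#'   unhealthy on that component.
#' @param carriage_sensitivity Per-component probability that a truly
#'   unhealthy patient carries >= 1 roadmap-matching diagnosis code.
#' @param false_carriage Per-component probability that a truly healthy
#'   patient carries such a code anyway.
#' @param mnar_multiplier Multiplier on `measurement_prob` for truly
#'   unhealthy patients (1 = missingness independent of true status; > 1 =
#'   sicker patients more likely measured, the missing-not-at-random knob).
#' @param noise_code_mean Mean (Poisson) number of background noise
#'   diagnosis codes per patient.
#' @param recovery_prob Per-component probability that the chart reviewer
#'   recovers a missing, truly unhealthy point (independent of code
#'   carriage: reviewers see information beyond coded diagnoses).
#' @param protocol_error_prob Probability that a missing point is instead
#'   recorded as a protocol error by the reviewer.
#' @param engagement_beta0,engagement_beta1 Intercept and slope of the
#'   logistic model for engagement in care on the true ALI.
#' @param n_review Chart-review subset size (balanced on engagement).
#' @param study_start,study_days Study period for diagnosis dates.
#' @return List of class `ali_generator_config`.
#' @export
generator_config <- function(n_patients = 1000,
                             seed = 20180301,
                             measurement_prob = c(SBP = 1, DBP = 1, BMI = 0.998,
                                                  TRIG = 0.60, CHOL = 0.60,
                                                  CRP = 0.045, HBA1C = 0.55,
                                                  ALB = 0.55, CC = 0.55,
                                                  HCST = 0.017),
                             prevalence = 0.35,
                             carriage_sensitivity = 0.5,
                             false_carriage = 0.05,
                             mnar_multiplier = 1,
                             noise_code_mean = 30,
                             recovery_prob = 0.3,
                             protocol_error_prob = 0.01,
                             engagement_beta0 = -1.55,
                             engagement_beta1 = 2,
                             n_review = min(100, n_patients),
                             study_start = as.Date("2018-03-01"),
                             study_days = 730) {
  cfg <- list(
    n_patients = n_patients, seed = seed,
    measurement_prob = per_component_param(measurement_prob, "measurement_prob"),
    prevalence = per_component_param(prevalence, "prevalence"),
    carriage_sensitivity = per_component_param(carriage_sensitivity,
                                               "carriage_sensitivity"),
    false_carriage = per_component_param(false_carriage, "false_carriage"),
    mnar_multiplier = mnar_multiplier,
    noise_code_mean = noise_code_mean,
    recovery_prob = per_component_param(recovery_prob, "recovery_prob"),
    protocol_error_prob = protocol_error_prob,
    engagement_beta0 = engagement_beta0, engagement_beta1 = engagement_beta1,
    n_review = n_review,
    study_start = as.Date(study_start), study_days = study_days)
  validate_generator_config(cfg)
  class(cfg) <- "ali_generator_config"
  cfg
}

per_component_param <- function(x, field) {
  ids <- component_ids()
  if (length(x) == 1 && is.null(names(x))) {
    out <- stats::setNames(rep(as.numeric(x), 10), ids)
  } else {
    bad <- setdiff(names(x), ids)
    if (length(bad) > 0) {
      stop(sprintf("config field %s names unknown component(s): %s", field,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    defaults <- eval(formals(generator_config)[[field]])
    out <- if (length(defaults) == 1) stats::setNames(rep(defaults, 10), ids) else defaults
    out[names(x)] <- as.numeric(x)
  }
  out[ids]
}

validate_generator_config <- function(cfg) {
  if (cfg$n_patients < 1) stop("config field n_patients must be >= 1", call. = FALSE)
  if (cfg$n_review > cfg$n_patients) {
    stop("config field n_review exceeds n_patients", call. = FALSE)
  }
  probs <- c("measurement_prob", "prevalence", "carriage_sensitivity",
             "false_carriage", "recovery_prob")
  for (field in probs) {
    v <- cfg[[field]]
    if (any(v < 0 | v > 1)) {
      stop(sprintf("config field %s has probability outside [0, 1]", field),
           call. = FALSE)
    }
  }
  if (cfg$protocol_error_prob < 0 || cfg$protocol_error_prob > 1) {
    stop("config field protocol_error_prob has probability outside [0, 1]",
         call. = FALSE)
  }
  if (cfg$noise_code_mean < 0) stop("config field noise_code_mean must be >= 0",
                                    call. = FALSE)
  if (cfg$mnar_multiplier < 0) stop("config field mnar_multiplier must be >= 0",
                                    call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic ICD-10 catalog discriminating token vs substring matching
#'
#' Builds a catalog with three strata: (1) for every roadmap term, codes
#' whose descriptions contain all of the term's tokens as whole words
#' (guaranteed token-mode matches); (2) decoy codes whose descriptions
#' contain each token only as a substring of a longer word (matched in
#' substring mode, rejected in token mode); (3) pure-noise codes with
#' randomized descriptions sharing no roadmap token, even as a substring.
#'
#' @param rm An `ali_roadmap` (non-empty).
#' @param n_decoys Number of decoy codes (0 for a catalog matching the
#'   roadmap universe exactly).
#' @param n_noise Number of pure-noise codes.
#' @param seed Integer seed.
#' @return An `ali_icd10_catalog`.
#' @export
generate_catalog <- function(rm, n_decoys = 20, n_noise = 200, seed = 1) {
  stopifnot(nrow(rm) > 0)
  terms <- tibble::as_tibble(rm)
  withr::with_seed(seed, {
    cap <- function(x) sub("^(.)", "\\U\\1", x, perl = TRUE)
    matched <- tibble::tibble(
      description = c(paste0(cap(terms$term), ", unspecified"),
                      paste("History of", terms$term)))
    matched$code <- sprintf("M%02d.%d", seq_len(nrow(matched)) %/% 10,
                            seq_len(nrow(matched)) %% 10)

    decoy <- NULL
    if (n_decoys > 0) {
      src <- terms[sample(nrow(terms), n_decoys, replace = TRUE), ]
      embedded <- vapply(src$term, function(t) {
        toks <- strsplit(t, " ", fixed = TRUE)[[1]]
        paste0(cap(paste0(toks, "oid", collapse = " ")), " state")
      }, character(1), USE.NAMES = FALSE)
      decoy <- tibble::tibble(
        description = embedded,
        code = sprintf("D%02d.%d", seq_len(n_decoys) %/% 10, seq_len(n_decoys) %% 10))
    }

    noise <- NULL
    if (n_noise > 0) {
      all_tokens <- unique(unlist(strsplit(terms$term, " ", fixed = TRUE)))
      long_tokens <- all_tokens[nchar(all_tokens) >= 3]
      gibberish <- function() paste0(
        paste(sample(letters[!letters %in% c("a", "e", "i", "o", "u")], 4,
                     replace = TRUE), collapse = ""),
        paste(sample(letters, 4, replace = TRUE), collapse = ""))
      words <- character(0)
      while (length(words) < 2 * n_noise) {
        w <- gibberish()
        clean <- !any(vapply(long_tokens, function(tk)
          grepl(tk, w, fixed = TRUE), logical(1)))
        if (clean) words <- c(words, w)
      }
      noise <- tibble::tibble(
        description = paste(cap(words[seq_len(n_noise)]),
                            words[n_noise + seq_len(n_noise)]),
        code = sprintf("N%03d.%d", seq_len(n_noise) %/% 10, seq_len(n_noise) %% 10))
    }
    icd10_catalog(dplyr::bind_rows(matched, decoy, noise)[, c("code", "description")])
  })
}

draw_biomarker_values <- function(component, unhealthy, sex,
                                  thresholds = ali_thresholds()) {
  bands <- c(SBP = 50, DBP = 30, BMI = 10, TRIG = 100, CHOL = 80, CRP = 8,
             HBA1C = 3, ALB = 1.5, CC = 40, HCST = 30)
  idx <- match(component, thresholds$component)
  cutoff <- ifelse(sex == "male", thresholds$cutoff_male[idx],
                   thresholds$cutoff_female[idx])
  band <- bands[component]
  dir <- thresholds$direction[idx]
  # margin keeps rounded values strictly on the intended side of the cutoff
  lo <- ifelse(dir %in% c("greater", "greater_equal"),
               ifelse(unhealthy, cutoff + 0.1, cutoff - band),
               ifelse(unhealthy, cutoff - band, cutoff + 0.1))
  hi <- ifelse(dir %in% c("greater", "greater_equal"),
               ifelse(unhealthy, cutoff + band, cutoff - 0.1),
               ifelse(unhealthy, cutoff - 0.1, cutoff + band))
  round(stats::runif(length(component), lo, hi), 2)
}

#' Generate a synthetic EHR cohort with known ground truth
#'
#' Draws, for every patient and component, a latent true status from the
#' component prevalence; observes a numeric biomarker value (consistent
#' with the true status relative to the clinical threshold) with the
#' component's measurement probability, else leaves it missing; gives truly
#' unhealthy patients a roadmap-matching diagnosis code with the
#' component's carriage sensitivity (healthy patients with the
#' false-carriage rate); adds Poisson background noise codes; simulates a
#' chart-review oracle that recovers missing truly-unhealthy points with
#' the recovery probability and stamps protocol errors; draws engagement in
#' care from a logistic model on the true ALI; and samples the chart-review
#' subset balanced 50/50 on engagement. All randomness flows from
#' `config$seed`; fixed seed implies identical output.
#'
#' @param config An `ali_generator_config`.
#' @param rm An `ali_roadmap` defining the matched-code sets used for code
#'   carriage.
#' @param catalog An `ali_icd10_catalog`, e.g. from [generate_catalog()].
#' @return List of class `ali_synthetic_study` with elements `cohort`,
#'   `biomarkers` (long, `NA` value = missing), `diagnoses`,
#'   `chart_review` (reviewed subset only), `catalog`, `roadmap`, and
#'   `truth` (list: `per_point` tibble with `true_unhealthy`, `measured`,
#'   `carries_code`, `chart_recovered`, `protocol_error`; `per_patient`
#'   tibble with `ali_true`, `p_engaged`, `engaged`, `reviewed`; `config`).
#' @export
generate_cohort <- function(config, rm, catalog) {
  stopifnot(inherits(config, "ali_generator_config"))
  validate_generator_config(config)
  universe <- expand_roadmap(rm, catalog, mode = "token")
  codes_by_comp <- split(universe$codes$code, universe$codes$component)
  matched_all <- unique(universe$codes$code)
  noise_pool <- setdiff(catalog$code, matched_all)
  thresholds <- ali_thresholds()
  ids <- component_ids()
  n <- config$n_patients

  withr::with_seed(config$seed, {
    cohort <- tibble::tibble(
      patient_id = sprintf("P%0*d", max(4, nchar(n)), seq_len(n)),
      age = sample(18:65, n, replace = TRUE),
      sex = sample(c("male", "female"), n, replace = TRUE,
                   prob = c(0.395, 0.605)),
      race = sample(c("White or Caucasian", "Black or African American",
                      "Asian Indian", "American Indian or Alaska Native", "Other"),
                    n, replace = TRUE, prob = c(0.715, 0.181, 0.030, 0.006, 0.068)),
      ethnicity = sample(c("Not Hispanic, Latino or Spanish",
                           "Hispanic, Latino or Spanish", "Patient refused"),
                         n, replace = TRUE, prob = c(0.934, 0.061, 0.005)))

    pts <- tidyr::expand_grid(patient_id = cohort$patient_id, component = ids)
    pts <- dplyr::left_join(pts, cohort[, c("patient_id", "sex")], by = "patient_id")
    pts$true_unhealthy <- stats::rbinom(nrow(pts), 1,
                                        config$prevalence[pts$component]) == 1
    p_measure <- pmin(1, config$measurement_prob[pts$component] *
                        ifelse(pts$true_unhealthy, config$mnar_multiplier, 1))
    pts$measured <- stats::rbinom(nrow(pts), 1, p_measure) == 1
    pts$value <- NA_real_
    pts$value[pts$measured] <- draw_biomarker_values(
      pts$component[pts$measured], pts$true_unhealthy[pts$measured],
      pts$sex[pts$measured], thresholds)

    p_carry <- ifelse(pts$true_unhealthy,
                      config$carriage_sensitivity[pts$component],
                      config$false_carriage[pts$component])
    p_carry[!pts$component %in% names(codes_by_comp)] <- 0
    pts$carries_code <- stats::rbinom(nrow(pts), 1, p_carry) == 1

    carried <- pts[pts$carries_code, , drop = FALSE]
    roadmap_dx <- if (nrow(carried) > 0) {
      tibble::tibble(
        patient_id = carried$patient_id,
        code = vapply(carried$component, function(comp) {
          pool <- codes_by_comp[[comp]]
          pool[sample.int(length(pool), 1)]
        }, character(1), USE.NAMES = FALSE))
    } else tibble::tibble(patient_id = character(), code = character())

    n_noise <- stats::rpois(n, config$noise_code_mean)
    noise_dx <- if (sum(n_noise) > 0 && length(noise_pool) > 0) {
      tibble::tibble(
        patient_id = rep(cohort$patient_id, n_noise),
        code = sample(noise_pool, sum(n_noise), replace = TRUE))
    } else tibble::tibble(patient_id = character(), code = character())

    diagnoses <- dplyr::bind_rows(roadmap_dx, noise_dx)
    diagnoses$date <- config$study_start +
      sample.int(config$study_days, nrow(diagnoses), replace = TRUE) - 1
    diagnoses <- dplyr::arrange(diagnoses, .data$patient_id, .data$code, .data$date)
    diagnoses$resolved <- TRUE

    # latent ALI over all 10 components drives engagement
    per_patient <- dplyr::summarise(
      dplyr::group_by(pts, .data$patient_id),
      ali_true = mean(.data$true_unhealthy), .groups = "drop")
    per_patient$p_engaged <- stats::plogis(
      config$engagement_beta0 + config$engagement_beta1 * per_patient$ali_true)
    per_patient$engaged <- stats::rbinom(n, 1, per_patient$p_engaged) == 1
    cohort$engaged <- per_patient$engaged[match(cohort$patient_id,
                                                per_patient$patient_id)]

    # 50/50 engaged/not-engaged case-control sample for chart review
    k_engaged <- min(floor(config$n_review / 2), sum(cohort$engaged))
    k_not <- min(config$n_review - k_engaged, sum(!cohort$engaged))
    reviewed_ids <- c(
      sample(cohort$patient_id[cohort$engaged], k_engaged),
      sample(cohort$patient_id[!cohort$engaged], k_not))
    per_patient$reviewed <- per_patient$patient_id %in% reviewed_ids

    pts$chart_recovered <- FALSE
    pts$protocol_error <- FALSE
    rev_rows <- pts$patient_id %in% reviewed_ids
    miss_rev <- rev_rows & !pts$measured
    pts$protocol_error[miss_rev] <- stats::runif(sum(miss_rev)) <
      config$protocol_error_prob
    cand <- miss_rev & !pts$protocol_error & pts$true_unhealthy
    pts$chart_recovered[cand] <- stats::runif(sum(cand)) <
      config$recovery_prob[pts$component[cand]]

    chart <- pts[rev_rows, , drop = FALSE]
    chart_status <- ifelse(
      chart$measured,
      discretize(chart$component, chart$value, chart$sex, thresholds),
      ifelse(chart$protocol_error, "PROTOCOL_ERROR",
             ifelse(chart$chart_recovered, "UNHEALTHY", "MISSING")))
    chart_review <- tibble::tibble(
      patient_id = chart$patient_id, component = chart$component,
      reviewed_status = chart_status)

    structure(list(
      cohort = cohort[, c("patient_id", "age", "sex", "race", "ethnicity",
                          "engaged")],
      biomarkers = pts[, c("patient_id", "component", "value")],
      diagnoses = diagnoses,
      chart_review = chart_review,
      catalog = catalog,
      roadmap = rm,
      truth = list(
        per_point = pts[, c("patient_id", "component", "true_unhealthy",
                            "measured", "carries_code", "chart_recovered",
                            "protocol_error")],
        per_patient = per_patient,
        config = config)),
      class = "ali_synthetic_study")
  })
}

#' @export
print.ali_synthetic_study <- function(x, ...) {
  cat(sprintf("<ali_synthetic_study> %d patients, %d diagnoses, %d reviewed\n",
              nrow(x$cohort), nrow(x$diagnoses),
              length(unique(x$chart_review$patient_id))))
  invisible(x)
}

#' Write a synthetic study to a fixture directory
#'
#' Writes `cohort.csv`, `biomarkers.csv`, `diagnoses.csv`,
#' `chart_review.csv`, `icd10_catalog.csv`, `roadmap.csv`, and
#' `truth.json`; [read_fixture_bundle()] reproduces the in-memory objects.
#'
#' @param study An `ali_synthetic_study`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    cohort = write_cohort(study$cohort, file.path(dir, "cohort.csv")),
    biomarkers = write_biomarkers(study$biomarkers, file.path(dir, "biomarkers.csv")),
    diagnoses = write_diagnoses(study$diagnoses, file.path(dir, "diagnoses.csv")),
    chart_review = write_chart_review(study$chart_review,
                                      file.path(dir, "chart_review.csv")),
    catalog = write_icd10_catalog(study$catalog, file.path(dir, "icd10_catalog.csv")),
    roadmap = write_roadmap(study$roadmap, file.path(dir, "roadmap.csv")))
  truth <- study$truth
  truth$config$study_start <- format(truth$config$study_start)
  jsonlite::write_json(
    list(per_point = truth$per_point, per_patient = truth$per_patient,
         config = unclass(truth$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  paths <- c(paths, truth = file.path(dir, "truth.json"))
  invisible(paths)
}

#' Read a fixture bundle back
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return List with elements `cohort`, `biomarkers`, `diagnoses`,
#'   `chart_review`, `catalog`, `roadmap`, `truth`.
#' @export
read_fixture_bundle <- function(dir) {
  catalog <- read_icd10_catalog(file.path(dir, "icd10_catalog.csv"))
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE)
  list(
    cohort = read_cohort(file.path(dir, "cohort.csv")),
    biomarkers = read_biomarkers(file.path(dir, "biomarkers.csv")),
    diagnoses = read_diagnoses(file.path(dir, "diagnoses.csv"), catalog),
    chart_review = read_chart_review(file.path(dir, "chart_review.csv")),
    catalog = catalog,
    roadmap = parse_roadmap(file.path(dir, "roadmap.csv")),
    truth = list(per_point = tibble::as_tibble(truth_raw$per_point),
                 per_patient = tibble::as_tibble(truth_raw$per_patient),
                 config = truth_raw$config))
}
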