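#' Tabulate status flows between two data sources
#'
#' Compares the same patient-by-component universe under two sources (e.g.
#' extracted EHR vs a recovery algorithm's output) and tabulates status
#' counts and transitions. For algorithm sources the one-sided recovery
#' rule is asserted, not silently corrected: any transition other than
#' `MISSING -> UNHEALTHY` raises an integrity error. Status totals are
#' conserved (every column sums to the number of data points, 10 per
#' patient).
#'
#' @param ehr Component-record tibble (`patient_id`, `component`, `status`)
#'   for the baseline source.
#' @param other Component-record tibble for the comparison source, covering
#'   the same (patient, component) universe.
#' @param source `"algorithm"` (one-sided rule asserted) or `"chart"`.
#' @return List of class `ali_flow` with `counts` (tibble `status`,
#'   `n_pre`, `n_post`), `transitions` (tibble `pre`, `post`, `n`),
#'   `n_points`, `n_missing_pre`, `n_recovered`.
#' @export
build_flow <- function(ehr, other, source = c("algorithm", "chart")) {
  source <- match.arg(source)
  require_columns(ehr, c("patient_id", "component", "status"), "ehr records")
  require_columns(other, c("patient_id", "component", "status"), "comparison records")
  key_a <- paste(ehr$patient_id, ehr$component)
  key_b <- paste(other$patient_id, other$component)
  if (length(key_a) != length(key_b) || !setequal(key_a, key_b) ||
      anyDuplicated(key_a) || anyDuplicated(key_b)) {
    stop("sources must cover the same (patient, component) universe exactly once",
         call. = FALSE)
  }
  joined <- tibble::tibble(pre = ehr$status,
                           post = other$status[match(key_a, key_b)])
  changed <- joined$pre != joined$post
  if (source == "algorithm") {
    illegal <- changed & !(joined$pre == "MISSING" & joined$post == "UNHEALTHY")
    if (any(illegal)) {
      i <- which(illegal)[1]
      stop(sprintf(
        "integrity error: algorithm source transitions %s -> %s (only MISSING -> UNHEALTHY is permitted)",
        joined$pre[i], joined$post[i]), call. = FALSE)
    }
  }
  lv <- c("UNHEALTHY", "HEALTHY", "MISSING")
  counts <- tibble::tibble(
    status = lv,
    n_pre = vapply(lv, function(s) sum(joined$pre == s), integer(1),
                   USE.NAMES = FALSE),
    n_post = vapply(lv, function(s) sum(joined$post == s), integer(1),
                    USE.NAMES = FALSE))
  transitions <- dplyr::count(joined[changed, , drop = FALSE],
                              .data$pre, .data$post, name = "n")
  structure(list(counts = counts, transitions = transitions,
                 n_points = nrow(joined),
                 n_missing_pre = sum(joined$pre == "MISSING"),
                 n_recovered = sum(joined$pre == "MISSING" &
                                     joined$post == "UNHEALTHY")),
            class = "ali_flow")
}

#' @export
print.ali_flow <- function(x, ...) {
  cat(sprintf("<ali_flow> %d data points; %d of %d missing recovered\n",
              x$n_points, x$n_recovered, x$n_missing_pre))
  print(x$counts)
  invisible(x)
}

#' Summarize missingness per patient and per component
#'
#' Quantiles use the linear-interpolation convention (R type 7), fixed so
#' that interquartile-range assertions are deterministic.
#'
#' @param records Component-record tibble (`patient_id`, `component`,
#'   `status`).
#' @return List with `per_patient` (tibble `patient_id`, `n_nonmissing`,
#'   `n_missing`), `per_component` (tibble `component`, `n_missing`,
#'   `n_total`), and `nonmissing_summary` (named numeric: `median`, `q1`,
#'   `q3`).
#' @export
missingness_summary <- function(records) {
  require_columns(records, c("patient_id", "component", "status"), "records")
  per_patient <- dplyr::summarise(
    dplyr::group_by(records, .data$patient_id),
    n_nonmissing = sum(.data$status != "MISSING"),
    n_missing = sum(.data$status == "MISSING"), .groups = "drop")
  per_component <- dplyr::summarise(
    dplyr::group_by(records, .data$component),
    n_missing = sum(.data$status == "MISSING"),
    n_total = dplyr::n(), .groups = "drop")
  per_component <- dplyr::arrange(per_component,
                                  match(.data$component, component_ids()))
  q <- stats::quantile(per_patient$n_nonmissing, c(0.25, 0.5, 0.75), type = 7)
  list(per_patient = per_patient, per_component = per_component,
       nonmissing_summary = c(median = unname(q[2]), q1 = unname(q[1]),
                              q3 = unname(q[3])))
}

#' Tabulate chart-review vs algorithm disagreements
#'
#' Two disagreement types are possible on the shared universe of recovered
#' points: the chart review recovers a point the algorithm does not
#' (`chart_only`, e.g. reviewers with access to information beyond coded
#' diagnoses), and the algorithm recovers a point the chart review does not
#' (`algorithm_only`, e.g. a matching code the reviewer deemed not
#' relevant). Points both sources recover are `agreement`s; the three sets
#' partition the union of recovered points.
#'
#' @param chart An `ali_recovery` for the chart-review source.
#' @param algo An `ali_recovery` for the algorithm source (same universe).
#' @return List with `per_component` (tibble `component`, `chart_only`,
#'   `algorithm_only`, `agreement`) and `total` (named numeric).
#' @export
disagreements <- function(chart, algo) {
  key_chart <- paste(chart$patient_id, chart$component)
  key_algo <- paste(algo$patient_id, algo$component)
  if (!setequal(key_chart, key_algo)) {
    stop("chart and algorithm results must cover the same universe", call. = FALSE)
  }
  rc <- recovered_points(chart)
  ra <- recovered_points(algo)
  kc <- paste(rc$patient_id, rc$component)
  ka <- paste(ra$patient_id, ra$component)
  all_pts <- dplyr::distinct(dplyr::bind_rows(rc, ra))
  k <- paste(all_pts$patient_id, all_pts$component)
  all_pts$type <- dplyr::case_when(
    k %in% kc & k %in% ka ~ "agreement",
    k %in% kc ~ "chart_only",
    .default = "algorithm_only")
  per_component <- tidyr::pivot_wider(
    dplyr::count(all_pts, .data$component, .data$type),
    names_from = "type", values_from = "n", values_fill = 0L)
  for (col in c("chart_only", "algorithm_only", "agreement")) {
    if (!col %in% names(per_component)) per_component[[col]] <- 0L
  }
  per_component <- dplyr::arrange(
    per_component[, c("component", "chart_only", "algorithm_only", "agreement")],
    match(.data$component, component_ids()))
  list(per_component = per_component,
       total = c(chart_only = sum(per_component$chart_only),
                 algorithm_only = sum(per_component$algorithm_only),
                 agreement = sum(per_component$agreement)))
}

#' Logistic regression of care engagement on the ALI
#'
#' Fits a maximum-likelihood logistic regression of the engagement flag
#' (at least one emergency department visit or hospitalization) on the
#' allostatic load index, with Wald 95 percent confidence intervals.
#' Patients with an undefined ALI are excluded and counted. Complete or
#' quasi-complete separation (or a constant ALI) is flagged rather than
#' reported as a finite estimate.
#'
#' @param patients Cohort tibble with `patient_id`, `engaged`.
#' @param ali ALI score tibble from [compute_ali()] (columns `patient_id`,
#'   `ali`), or any tibble with those columns.
#' @return List of class `ali_engagement_fit` with `coefficient` (slope on
#'   ALI), `intercept`, `ci_lower`, `ci_upper`, `se`, `n`, `n_excluded`,
#'   `flag` (`"ok"`, `"separation"`, or `"degenerate"`), and `fit` (the
#'   underlying `glm`).
#' @export
engagement_model <- function(patients, ali) {
  require_columns(patients, c("patient_id", "engaged"), "patients")
  require_columns(ali, c("patient_id", "ali"), "ali scores")
  df <- dplyr::inner_join(patients[, c("patient_id", "engaged")],
                          ali[, c("patient_id", "ali")], by = "patient_id")
  n_excluded <- sum(is.na(df$ali))
  df <- df[!is.na(df$ali), , drop = FALSE]
  if (nrow(df) < 2 || length(unique(df$ali)) < 2) {
    return(structure(list(coefficient = NA_real_, intercept = NA_real_,
                          ci_lower = NA_real_, ci_upper = NA_real_,
                          se = NA_real_, n = nrow(df), n_excluded = n_excluded,
                          flag = "degenerate", fit = NULL),
                     class = "ali_engagement_fit"))
  }
  fit <- suppressWarnings(
    stats::glm(engaged ~ ali, data = df, family = stats::binomial()))
  coefs <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))["ali"]
  separated <- !fit$converged || abs(coefs["ali"]) > 15 || se > 100
  z <- stats::qnorm(0.975)
  structure(list(
    coefficient = unname(coefs["ali"]),
    intercept = unname(coefs["(Intercept)"]),
    ci_lower = if (separated) -Inf else unname(coefs["ali"] - z * se),
    ci_upper = if (separated) Inf else unname(coefs["ali"] + z * se),
    se = unname(se), n = nrow(df), n_excluded = n_excluded,
    flag = if (separated) "separation" else "ok", fit = fit),
    class = "ali_engagement_fit")
}

#' @export
print.ali_engagement_fit <- function(x, ...) {
  cat(sprintf("<engagement ~ ALI logistic fit> n=%d (%d excluded), flag=%s\n",
              x$n, x$n_excluded, x$flag))
  cat(sprintf("  slope %.3f [%.3f, %.3f], intercept %.3f\n",
              x$coefficient, x$ci_lower, x$ci_upper, x$intercept))
  invisible(x)
}

#' Assemble the full evaluation report
#'
#' Combines flow accounting, missingness summaries, the disagreement
#' taxonomy, ALI distribution shifts and the engagement regression into one
#' machine-readable structure. Percentages are full-precision; round for
#' display.
#'
#' @param ehr Pre-recovery component records.
#' @param algo An `ali_recovery` from the algorithm.
#' @param patients Cohort tibble.
#' @param chart Optional `ali_recovery` for the chart-review source (for
#'   the disagreement report).
#' @param mode ALI denominator mode.
#' @return List of class `ali_evaluation`.
#' @export
evaluate_recovery <- function(ehr, algo, patients, chart = NULL,
                              mode = "nonmissing") {
  flow <- build_flow(ehr, post_records(algo), source = "algorithm")
  ali_pre <- compute_ali(ehr[, c("patient_id", "component", "status")], mode)
  ali_post <- compute_ali(post_records(algo), mode)
  summ <- function(x) {
    q <- stats::quantile(x[!is.na(x)], c(0.25, 0.5, 0.75), type = 7)
    c(median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]))
  }
  out <- list(
    flow = flow,
    missingness_pre = missingness_summary(ehr),
    missingness_post = missingness_summary(post_records(algo)),
    recovery = recovery_counts(algo),
    ali_pre = summ(ali_pre$ali), ali_post = summ(ali_post$ali),
    scatter = dplyr::inner_join(
      dplyr::rename(ali_pre[, c("patient_id", "ali")], ali_pre = "ali"),
      dplyr::rename(ali_post[, c("patient_id", "ali")], ali_post = "ali"),
      by = "patient_id"),
    engagement_naive = engagement_model(patients, ali_pre),
    engagement_augmented = engagement_model(patients, ali_post),
    disagreements = if (!is.null(chart)) disagreements(chart, algo) else NULL)
  class(out) <- "ali_evaluation"
  out
}

#' @rdname ali_io
#' @param evaluation An `ali_evaluation`.
#' @export
write_evaluation_report <- function(evaluation, path) {
  strip_fit <- function(f) f[setdiff(names(f), "fit")]
  out <- list(
    flow = list(counts = evaluation$flow$counts,
                transitions = evaluation$flow$transitions,
                n_points = evaluation$flow$n_points,
                n_missing_pre = evaluation$flow$n_missing_pre,
                n_recovered = evaluation$flow$n_recovered),
    missingness_pre = evaluation$missingness_pre[c("per_component", "nonmissing_summary")],
    missingness_post = evaluation$missingness_post[c("per_component", "nonmissing_summary")],
    recovery = evaluation$recovery,
    ali_pre = as.list(evaluation$ali_pre),
    ali_post = as.list(evaluation$ali_post),
    engagement_naive = strip_fit(unclass(evaluation$engagement_naive)),
    engagement_augmented = strip_fit(unclass(evaluation$engagement_augmented)),
    disagreements = evaluation$disagreements)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(path)
}
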