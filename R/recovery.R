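#' Reclassify chart-review protocol errors to missing
#'
#' Protocol errors are chart-review points that were missing in the
#' extracted EHR data but where the reviewer recorded a value from outside
#' the study period instead of applying the roadmap. For comparisons they
#' are returned to `MISSING` (the algorithm may still recover them); the
#' original label is preserved in a `protocol_error` audit flag. The
#' operation is idempotent.
#'
#' @param chart Chart-review tibble with columns `patient_id`, `component`
#'   and either `reviewed_status` (fresh chart-review records) or `status`
#'   (already-reclassified records).
#' @return Component-record tibble with columns `patient_id`, `component`,
#'   `status` (in `{UNHEALTHY, HEALTHY, MISSING}`), `protocol_error`.
#' @export
reclassify_protocol_errors <- function(chart) {
  require_columns(chart, c("patient_id", "component"), "chart records")
  status_col <- if ("reviewed_status" %in% names(chart)) "reviewed_status" else "status"
  require_columns(chart, status_col, "chart records")
  status <- chart[[status_col]]
  assert_statuses(status)
  prior_flag <- if ("protocol_error" %in% names(chart)) chart$protocol_error else FALSE
  is_pe <- status == "PROTOCOL_ERROR"
  tibble::tibble(
    patient_id = chart$patient_id,
    component = chart$component,
    status = ifelse(is_pe, "MISSING", status),
    protocol_error = prior_flag | is_pe)
}

#' Recover missing components from auxiliary diagnoses
#'
#' The missing-data recovery algorithm: a `MISSING` (patient, component)
#' data point is flipped to `UNHEALTHY` exactly when the patient carries at
#' least one diagnosis whose code lies in the component's matched-code set.
#' Non-missing points pass through unchanged -- absence of a matching code
#' is one-sided evidence, so a missing point can never become `HEALTHY`.
#' Every justifying (code, term) pair is recorded as evidence. The
#' operation is deterministic and idempotent.
#'
#' @param records Component-record tibble (`patient_id`, `component`,
#'   `status` in `{UNHEALTHY, HEALTHY, MISSING}`). Chart-review records with
#'   `PROTOCOL_ERROR` must first pass through
#'   [reclassify_protocol_errors()].
#' @param diagnoses Diagnoses tibble (`patient_id`, `code`).
#' @param universe An `ali_match_universe` from [expand_roadmap()].
#' @return Tibble of class `ali_recovery` with columns `patient_id`,
#'   `component`, `pre_status`, `post_status`, `evidence` (list column of
#'   tibbles with `code`, `term`, non-empty exactly when a flip occurred).
#' @export
recover <- function(records, diagnoses, universe) {
  require_columns(records, c("patient_id", "component", "status"), "records")
  require_columns(diagnoses, c("patient_id", "code"), "diagnoses")
  assert_statuses(records$status, c("UNHEALTHY", "HEALTHY", "MISSING"))
  assert_components(records$component)

  carried <- dplyr::distinct(diagnoses[, c("patient_id", "code")])
  # (patient, component, code, term) quadruples justifying recoveries
  evidence_pool <- dplyr::inner_join(
    carried, universe$matches[, c("component", "code", "term")],
    by = "code", relationship = "many-to-many")

  out <- tibble::tibble(
    patient_id = records$patient_id,
    component = records$component,
    pre_status = records$status)

  miss <- out$pre_status == "MISSING"
  key <- paste(out$patient_id, out$component)
  ev_key <- paste(evidence_pool$patient_id, evidence_pool$component)
  recovered <- miss & key %in% ev_key
  out$post_status <- ifelse(recovered, "UNHEALTHY", out$pre_status)

  empty_ev <- tibble::tibble(code = character(), term = character())
  evidence <- rep(list(empty_ev), nrow(out))
  rec_idx <- which(recovered)
  if (length(rec_idx) > 0) {
    pool <- dplyr::distinct(evidence_pool)
    pool <- pool[order(pool$patient_id, pool$component, pool$code, pool$term), ,
                 drop = FALSE]
    pool_rows <- split(seq_len(nrow(pool)),
                       paste(pool$patient_id, pool$component))
    new_ev <- function(code, term) {
      structure(list(code = code, term = term),
                class = c("tbl_df", "tbl", "data.frame"),
                row.names = seq_along(code))
    }
    code_v <- pool$code
    term_v <- pool$term
    for (i in rec_idx) {
      rows <- pool_rows[[key[i]]]
      evidence[[i]] <- new_ev(code_v[rows], term_v[rows])
    }
  }
  out$evidence <- evidence
  if ("protocol_error" %in% names(records)) {
    out$protocol_error <- records$protocol_error
  }
  class(out) <- c("ali_recovery", class(out))
  out
}

#' @export
print.ali_recovery <- function(x, ...) {
  cnt <- recovery_counts(x)
  cat(sprintf("<ali_recovery> %d data points; %d of %d missing recovered (%s)\n",
              nrow(x), cnt$n_recovered, cnt$n_missing_pre,
              if (is.na(cnt$pct)) "pct undefined" else sprintf("%.0f%%", cnt$pct)))
  invisible(x)
}

#' Recovered data points of a recovery result
#'
#' @param results An `ali_recovery`.
#' @return Tibble (`patient_id`, `component`) of points flipped
#'   `MISSING -> UNHEALTHY`.
#' @export
recovered_points <- function(results) {
  flipped <- results$pre_status == "MISSING" & results$post_status == "UNHEALTHY"
  tibble::as_tibble(results[flipped, c("patient_id", "component")])
}

#' Summarize recovery as counts and a percentage
#'
#' @param results An `ali_recovery`.
#' @return List with `n_missing_pre`, `n_recovered`, and `pct`
#'   (100 x recovered / missing; `NA` when nothing was missing).
#' @export
recovery_counts <- function(results) {
  n_missing <- sum(results$pre_status == "MISSING")
  n_recovered <- sum(results$pre_status == "MISSING" &
                       results$post_status == "UNHEALTHY")
  list(n_missing_pre = n_missing, n_recovered = n_recovered,
       pct = if (n_missing == 0) NA_real_ else 100 * n_recovered / n_missing)
}

#' Post-recovery component records
#'
#' @param results An `ali_recovery`.
#' @return Tibble (`patient_id`, `component`, `status`) with the
#'   post-algorithm statuses, suitable for [compute_ali()] or a second
#'   [recover()] pass.
#' @export
post_records <- function(results) {
  tibble::tibble(patient_id = results$patient_id,
                 component = results$component,
                 status = results$post_status)
}

#' @rdname ali_io
#' @param results An `ali_recovery`.
#' @export
write_recovery_results <- function(results, path) {
  flat <- tibble::tibble(
    patient_id = results$patient_id,
    component = results$component,
    pre_status = results$pre_status,
    post_status = results$post_status,
    evidence_codes = vapply(results$evidence, function(ev)
      paste(unique(ev$code), collapse = ";"), character(1)))
  readr::write_csv(flat, path, na = "")
  invisible(path)
}
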