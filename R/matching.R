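#' Decide whether a search term matches an ICD-10 description
#'
#' The merging rule requires every word of the search term to appear
#' somewhere in the code's description: `"vitamin deficiency"` matches
#' `"Vitamin D deficiency"` because both `vitamin` and `deficiency` are
#' present. Two interpretations of "appear" are supported:
#' \describe{
#'   \item{token}{(default) each term token must occur as a whole word of
#'     the normalized description. Avoids clinically absurd hits such as
#'     `"art"` matching `"Heart failure"`.}
#'   \item{substring}{each term token need only occur as a substring of the
#'     normalized description, so `"art"` does match `"Heart failure"`.}
#' }
#' Both sides are normalized identically (see [normalize_term()]), so
#' matching is symmetric with term parsing.
#'
#' @param term Character scalar (raw or normalized search term).
#' @param description Character vector of ICD-10 descriptions.
#' @param mode `"token"` or `"substring"`.
#' @return Logical vector, one element per description.
#' @examples
#' term_matches("vitamin deficiency", "Vitamin D deficiency")
#' term_matches("art", "Heart failure")                    # FALSE
#' term_matches("art", "Heart failure", mode = "substring") # TRUE
#' @export
term_matches <- function(term, description, mode = c("token", "substring")) {
  mode <- match.arg(mode)
  tokens <- term_tokens(term)[[1]]
  if (length(tokens) == 0) return(rep(FALSE, length(description)))
  norm_desc <- normalize_term(description)
  if (mode == "token") {
    desc_tokens <- strsplit(norm_desc, " ", fixed = TRUE)
    vapply(desc_tokens, function(dt) all(tokens %in% dt), logical(1))
  } else {
    hits <- vapply(tokens, function(tk) stringr::str_detect(
      norm_desc, stringr::fixed(tk)), logical(length(norm_desc)))
    if (length(norm_desc) == 1) all(hits) else rowSums(!hits) == 0
  }
}

#' Expand a roadmap into per-component matched ICD-10 code sets
#'
#' For each ALI component, finds every catalog code whose description is
#' matched by at least one of the component's search terms (AND across a
#' term's tokens, OR across terms), then removes the excluded codes. The
#' result is deterministic for fixed inputs: codes are sorted, and matching
#' is component-scoped (a code matched for CRP has no effect on any other
#' component).
#'
#' @param rm An `ali_roadmap`.
#' @param catalog An `ali_icd10_catalog` (or tibble with `code`,
#'   `description`).
#' @param mode Matching mode, `"token"` (default) or `"substring"`.
#' @param exclusions Additional ICD-10 codes to exclude, combined with the
#'   roadmap's own [code_exclusions()].
#' @return A `ali_match_universe`: list with elements `roadmap_name`,
#'   `mode`, `matches` (tibble `component`, `term`, `code`, `description`,
#'   every justifying pair), `codes` (tibble `component`, `code`, distinct),
#'   and `exclusions`.
#' @export
expand_roadmap <- function(rm, catalog, mode = c("token", "substring"),
                           exclusions = character()) {
  mode <- match.arg(mode)
  require_columns(catalog, c("code", "description"), "catalog")
  exclusions <- sort(unique(c(code_exclusions(rm), exclusions)))
  norm_desc <- normalize_term(catalog$description)
  desc_tokens <- if (mode == "token") strsplit(norm_desc, " ", fixed = TRUE) else NULL

  terms <- tibble::as_tibble(rm)
  match_one <- function(comp, term) {
    tokens <- strsplit(term, " ", fixed = TRUE)[[1]]
    hit <- if (mode == "token") {
      vapply(desc_tokens, function(dt) all(tokens %in% dt), logical(1))
    } else {
      Reduce(`&`, lapply(tokens, function(tk)
        stringr::str_detect(norm_desc, stringr::fixed(tk))))
    }
    if (!any(hit)) return(NULL)
    tibble::tibble(component = comp, term = term,
                   code = catalog$code[hit], description = catalog$description[hit])
  }
  matches <- purrr::pmap_dfr(list(terms$component, terms$term), match_one)
  if (nrow(matches) == 0) {
    matches <- tibble::tibble(component = character(), term = character(),
                              code = character(), description = character())
  }
  matches <- matches[!matches$code %in% exclusions, , drop = FALSE]
  matches <- dplyr::arrange(matches, match(.data$component, component_ids()),
                            .data$code, .data$term)
  codes <- dplyr::distinct(matches[, c("component", "code")])
  structure(list(roadmap_name = roadmap_name(rm), mode = mode,
                 matches = matches, codes = codes, exclusions = exclusions),
            class = "ali_match_universe")
}

#' @export
print.ali_match_universe <- function(x, ...) {
  cat(sprintf("<ali_match_universe '%s', mode=%s> %d distinct codes over %d components\n",
              x$roadmap_name, x$mode, length(unique(x$codes$code)),
              length(unique(x$codes$component))))
  invisible(x)
}

#' Count matched codes overall and in-sample
#'
#' `overall` is the number of distinct ICD-10 codes in the match universe;
#' `in_sample` is how many of those are actually carried by at least one
#' patient in the supplied diagnoses (the "matched in sample (overall)"
#' summary for a roadmap).
#'
#' @param universe An `ali_match_universe`.
#' @param diagnoses Diagnoses tibble with a `code` column.
#' @return List with numeric elements `overall` and `in_sample`.
#' @export
in_sample_counts <- function(universe, diagnoses) {
  matched <- unique(universe$codes$code)
  carried <- unique(diagnoses$code)
  list(overall = length(matched),
       in_sample = length(intersect(matched, carried)))
}

#' Write a machine-readable match report
#'
#' @param universe An `ali_match_universe`.
#' @param diagnoses Diagnoses tibble (for in-sample counts).
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_match_report <- function(universe, diagnoses, path) {
  counts <- in_sample_counts(universe, diagnoses)
  per_component <- lapply(split(universe$codes$code, universe$codes$component),
                          sort)
  report <- list(roadmap = universe$roadmap_name, mode = universe$mode,
                 overall = counts$overall, in_sample = counts$in_sample,
                 exclusions = universe$exclusions,
                 matched_codes = per_component)
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
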