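#' Normalize search-term text
#'
#' The matching algorithm is word-based: a term matches an ICD-10
#' description when every word of the term appears somewhere in the
#' description. Normalization therefore lowercases, replaces every
#' non-alphanumeric character with a space, and collapses whitespace, so
#' e.g. `"Auto-immune inflammatory syndrome"` becomes
#' `"auto immune inflammatory syndrome"` (tokens `auto`, `immune`, ...).
#' The function is idempotent.
#'
#' @param x Character vector of raw term or description text.
#' @return Character vector of normalized text (single-space-separated
#'   lowercase tokens).
#' @export
normalize_term <- function(x) {
  out <- tolower(x)
  out <- gsub("[^a-z0-9]+", " ", out)
  trimws(gsub(" +", " ", out))
}

term_tokens <- function(x) strsplit(normalize_term(x), " ", fixed = TRUE)

#' Expand enumerated severity grades in a term
#'
#' Clinical roadmaps abbreviate graded diagnoses as e.g.
#' `"Grade I, II, or III obesity"`; the matching algorithm needs one term
#' per grade. Only the exact `"A, B, or C"` enumeration pattern is
#' expanded (Roman or Arabic numerals/words); terms without it pass through
#' unchanged.
#'
#' @param raw Character scalar, a raw term.
#' @return Character vector of one or more raw terms.
#' @examples
#' expand_grade_terms("Grade I, II, or III obesity")
#' @export
expand_grade_terms <- function(raw) {
  stopifnot(length(raw) == 1)
  pattern <- "([A-Za-z0-9]+), ([A-Za-z0-9]+),? or ([A-Za-z0-9]+)"
  m <- regexec(pattern, raw)[[1]]
  if (m[1] == -1) return(raw)
  groups <- regmatches(raw, regexec(pattern, raw))[[1]]
  vapply(groups[2:4], function(g) sub(pattern, g, raw), character(1),
         USE.NAMES = FALSE)
}

#' Construct a roadmap object
#'
#' A roadmap is the algorithm's clinical knowledge base: for each ALI
#' component, a set of search terms whose presence in an ICD-10 description
#' marks the code as auxiliary evidence of an unhealthy value. Terms are
#' stored normalized (see [normalize_term()]) and de-duplicated within each
#' component; a component may legitimately have no terms (the original
#' clinicians' roadmap gives none for serum albumin).
#'
#' @param df Data frame with columns `component`, `term`, and optionally
#'   `provenance` (one of `original`, `proposed`, `endorsed`, `rejected`;
#'   default `original`) and `raw` (the pre-normalization text).
#' @param name Roadmap label, e.g. `"original"`, `"llm_baseline"`,
#'   `"llm_context"`, `"llm_context_clinicians"`, or any custom label.
#' @param code_exclusions Character vector of ICD-10 codes to exclude from
#'   the roadmap's match universe (populated by code-level adjudication).
#' @return Tibble of class `ali_roadmap` with columns `component`, `term`
#'   (normalized), `raw`, `provenance`, plus attributes `roadmap_name` and
#'   `code_exclusions`.
#' @export
roadmap <- function(df, name = "custom", code_exclusions = character()) {
  require_columns(df, c("component", "term"), "roadmap")
  assert_components(df$component, "component")
  if (!"provenance" %in% names(df)) df$provenance <- "original"
  df$provenance[is.na(df$provenance)] <- "original"
  bad <- setdiff(unique(df$provenance), c("original", "proposed", "endorsed", "rejected"))
  if (length(bad) > 0) {
    stop("unknown provenance value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"raw" %in% names(df)) df$raw <- df$term
  df$term <- normalize_term(df$term)
  df <- df[df$term != "", , drop = FALSE]
  out <- tibble::as_tibble(df[, c("component", "term", "raw", "provenance")])
  out <- out[!duplicated(out[, c("component", "term")]), ]
  out <- dplyr::arrange(out, match(.data$component, component_ids()), .data$term)
  attr(out, "roadmap_name") <- name
  attr(out, "code_exclusions") <- sort(unique(code_exclusions))
  class(out) <- c("ali_roadmap", class(out))
  out
}

#' @export
print.ali_roadmap <- function(x, ...) {
  cat(sprintf("<ali_roadmap '%s'> %d terms across %d components",
              roadmap_name(x), nrow(x), length(unique(x$component))))
  excl <- code_exclusions(x)
  if (length(excl) > 0) cat(sprintf(", %d code exclusion(s)", length(excl)))
  cat("\n")
  NextMethod()
}

#' @rdname roadmap
#' @param x An `ali_roadmap`.
#' @export
roadmap_name <- function(x) attr(x, "roadmap_name") %||% "custom"

#' @rdname roadmap
#' @export
code_exclusions <- function(x) attr(x, "code_exclusions") %||% character()

#' Parse a roadmap CSV
#'
#' Reads a `component, term[, provenance]` CSV, expands enumerated grade
#' terms (see [expand_grade_terms()]), normalizes and de-duplicates. With
#' the shipped clinicians'-original fixture this yields the 20-entry
#' knowledge base: one term each for the blood pressures, triglycerides and
#' cholesterol; five obesity terms for BMI after grade expansion; three
#' inflammation terms for CRP; two for hemoglobin A1c; none for serum
#' albumin; four for creatinine clearance; two for homocysteine.
#'
#' @param path Path to a roadmap CSV.
#' @param name Roadmap label (see [roadmap()]); defaults to the file name
#'   without extension.
#' @return An `ali_roadmap`.
#' @export
parse_roadmap <- function(path, name = NULL) {
  raw <- read_csv_strict(path, "roadmap")
  require_columns(raw, c("component", "term"), "roadmap file")
  assert_components(raw$component)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- raw[!is.na(raw$term) & trimws(raw$term) != "", , drop = FALSE]
  expanded <- purrr::pmap_dfr(
    list(raw$component, raw$term,
         if ("provenance" %in% names(raw)) raw$provenance else
           rep(NA_character_, nrow(raw))),
    function(comp, term, prov) {
      expanded <- expand_grade_terms(term)
      tibble::tibble(component = comp, term = expanded, raw = expanded,
                     provenance = prov)
    })
  roadmap(expanded, name = name)
}

#' The shipped clinicians' original roadmap
#'
#' @return The clinicians' original roadmap as an `ali_roadmap` (20 terms).
#' @export
original_roadmap <- function() {
  parse_roadmap(system.file("extdata", "roadmap_original.csv",
                            package = "alirecover"),
                name = "original")
}

#' @rdname ali_io
#' @param rm An `ali_roadmap`.
#' @export
write_roadmap <- function(rm, path) {
  readr::write_csv(tibble::as_tibble(rm)[, c("component", "term", "provenance")],
                   path, na = "")
  invisible(path)
}

#' Read an adjudication ledger
#'
#' Columns `item_type` (`term` or `code`), `item`, `component`, `reviewer`,
#' `verdict` (`endorse` or `reject`). Each row is one reviewer's verdict on
#' one roadmap term or one matched ICD-10 code.
#'
#' @param path Path to a ledger CSV.
#' @return Tibble with the five ledger columns.
#' @export
read_ledger <- function(path) {
  raw <- read_csv_strict(path, "adjudication ledger")
  require_columns(raw, c("item_type", "item", "component", "reviewer", "verdict"),
                  "ledger file")
  bad <- setdiff(unique(raw$item_type), c("term", "code"))
  if (length(bad) > 0) stop("unknown item_type: ", bad[1], call. = FALSE)
  bad <- setdiff(unique(raw$verdict), c("endorse", "reject"))
  if (length(bad) > 0) stop("unknown verdict: ", bad[1], call. = FALSE)
  tibble::as_tibble(raw[, c("item_type", "item", "component", "reviewer", "verdict")])
}

#' Apply clinician adjudication to a roadmap
#'
#' The endorsement rule is "at least one reviewer endorses, keep". Term-level
#' verdicts filter the roadmap's term set: the adjudicated roadmap keeps
#' exactly the terms with at least one `endorse` verdict (so an empty ledger
#' endorses nothing and empties the roadmap). Code-level verdicts operate on
#' the match universe instead: adjudicated codes with no `endorse` verdict
#' are added to the roadmap's code-exclusion list, applied after matching.
#' A ledger containing only code-level entries leaves the term set intact.
#' Verdicts on items not present in the roadmap's universe are ignored with
#' a warning. The operation is contractive and idempotent.
#'
#' @param rm An `ali_roadmap`.
#' @param ledger Ledger tibble as returned by [read_ledger()].
#' @return An `ali_roadmap` whose match universe is a subset of the input's.
#' @export
adjudicate <- function(rm, ledger) {
  require_columns(ledger, c("item_type", "item", "component", "verdict"), "ledger")
  term_entries <- ledger[ledger$item_type == "term", , drop = FALSE]
  code_entries <- ledger[ledger$item_type == "code", , drop = FALSE]

  out <- tibble::as_tibble(rm)
  if (nrow(term_entries) > 0 || nrow(ledger) == 0) {
    term_entries$item <- normalize_term(term_entries$item)
    known <- paste(out$component, out$term)
    referenced <- paste(term_entries$component, term_entries$item)
    unknown <- setdiff(referenced, known)
    if (length(unknown) > 0) {
      warning("adjudication verdict(s) on term(s) not in roadmap, ignored: ",
              paste(utils::head(unknown, 3), collapse = "; "), call. = FALSE)
    }
    endorsed <- unique(referenced[term_entries$verdict == "endorse"])
    keep <- known %in% endorsed
    out <- out[keep, , drop = FALSE]
    out$provenance <- "endorsed"
  }

  exclusions <- code_exclusions(rm)
  if (nrow(code_entries) > 0) {
    by_code <- dplyr::summarise(
      dplyr::group_by(code_entries, .data$item),
      any_endorse = any(.data$verdict == "endorse"), .groups = "drop")
    exclusions <- sort(unique(c(exclusions, by_code$item[!by_code$any_endorse])))
  }
  roadmap(out, name = paste0(roadmap_name(rm), "_adjudicated"),
          code_exclusions = exclusions)
}

#' Compare two roadmaps term by term
#'
#' Partitions each component's union of normalized terms into terms only in
#' `b` (`added`), only in `a` (`removed`), and in both (`shared`).
#'
#' @param a,b `ali_roadmap` objects.
#' @return Tibble with columns `component`, `term`, `change` (one of
#'   `added`, `removed`, `shared`).
#' @export
diff_roadmaps <- function(a, b) {
  ka <- paste(a$component, a$term)
  kb <- paste(b$component, b$term)
  all_terms <- dplyr::bind_rows(
    tibble::as_tibble(a)[, c("component", "term")],
    tibble::as_tibble(b)[, c("component", "term")])
  all_terms <- all_terms[!duplicated(all_terms), ]
  key <- paste(all_terms$component, all_terms$term)
  all_terms$change <- dplyr::case_when(
    key %in% ka & key %in% kb ~ "shared",
    key %in% kb ~ "added",
    .default = "removed")
  dplyr::arrange(all_terms, match(.data$component, component_ids()), .data$term)
}
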