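#' Self-consistency roadmap expansion
#'
#' Language-model (or other) term proposers tend to return different term
#' lists on every independent invocation. The expansion loop embraces this:
#' the proposer is called once per iteration in a fresh session (no shared
#' conversational state), and the expanded roadmap is the superset of all
#' proposals -- every term that appeared at least once. A saturation curve
#' (cumulative count of distinct matched ICD-10 codes after each iteration)
#' diagnoses when further iterations stop adding information.
#'
#' A proposer is any function with signature
#' `function(components, seed_examples, iteration)` returning a named list
#' mapping component codes to character vectors of raw term texts.
#' `components` is the [ali_components()] metadata tibble; `seed_examples`
#' is a named list of the seed roadmap's raw terms (context mode) or `NULL`
#' (baseline mode). Live-API adapters sit outside the tested surface: the
#' package ships a deterministic mock ([mock_proposer()]) and a
#' recorded-fixture replayer ([fixture_proposer()]).
#'
#' @param proposer A proposer function (see Details).
#' @param mode `"baseline"` (component names and unhealthy directions only)
#'   or `"context"` (seed-roadmap examples passed through to the proposer).
#' @param n_iterations Number of independent proposer invocations
#'   (default 20).
#' @param seed_roadmap An `ali_roadmap`; required in context mode.
#' @param catalog An `ali_icd10_catalog` used to compute the saturation
#'   curve.
#' @param match_mode Matching mode for the saturation curve.
#' @return List of class `ali_expansion_run` with elements `mode`,
#'   `n_iterations`, `proposals` (list of per-iteration tibbles
#'   `component`, `term`), `aggregate` (the superset `ali_roadmap`),
#'   `saturation` (integer vector), and `failed_iterations`.
#' @export
run_expansion <- function(proposer, mode = c("baseline", "context"),
                          n_iterations = 20, seed_roadmap = NULL,
                          catalog, match_mode = c("token", "substring")) {
  mode <- match.arg(mode)
  match_mode <- match.arg(match_mode)
  stopifnot(n_iterations >= 1)
  if (mode == "context" && is.null(seed_roadmap)) {
    stop("context mode requires a seed_roadmap", call. = FALSE)
  }
  seed_examples <- if (mode == "context") {
    split(seed_roadmap$raw, seed_roadmap$component)
  } else NULL
  comps <- ali_components()

  proposals <- vector("list", n_iterations)
  failed <- integer()
  for (i in seq_len(n_iterations)) {
    prop <- tryCatch(proposer(comps, seed_examples, i), error = function(e) e)
    if (inherits(prop, "error")) {
      warning(sprintf("proposer failed on iteration %d: %s", i,
                      conditionMessage(prop)), call. = FALSE)
      failed <- c(failed, i)
      proposals[[i]] <- tibble::tibble(component = character(), term = character())
      next
    }
    assert_components(names(prop), "proposal component")
    proposals[[i]] <- tibble::tibble(
      component = rep(names(prop), lengths(prop)),
      term = unlist(prop, use.names = FALSE) %||% character())
  }
  if (length(failed) == n_iterations) {
    stop("all proposer iterations failed", call. = FALSE)
  }

  # cumulative matched-code saturation: distinct codes matched by the union
  # of proposals 1..i
  saturation <- integer(n_iterations)
  cumulative <- tibble::tibble(component = character(), term = character())
  for (i in seq_len(n_iterations)) {
    cumulative <- dplyr::bind_rows(cumulative, proposals[[i]])
    rm_i <- roadmap(cumulative, name = sprintf("llm_%s_iter%d", mode, i))
    uni <- expand_roadmap(rm_i, catalog, mode = match_mode)
    saturation[i] <- length(unique(uni$codes$code))
  }

  aggregate_df <- dplyr::bind_rows(proposals)
  aggregate_df$provenance <- "proposed"
  aggregate <- roadmap(aggregate_df, name = paste0("llm_", mode))

  structure(list(mode = mode, n_iterations = n_iterations,
                 proposals = proposals, aggregate = aggregate,
                 saturation = saturation, failed_iterations = failed),
            class = "ali_expansion_run")
}

#' @export
print.ali_expansion_run <- function(x, ...) {
  cat(sprintf("<ali_expansion_run mode=%s> %d iterations, %d aggregate terms, saturation %d -> %d codes\n",
              x$mode, x$n_iterations, nrow(x$aggregate),
              x$saturation[1], x$saturation[x$n_iterations]))
  invisible(x)
}

#' Locate the plateau of a saturation curve
#'
#' Returns the smallest iteration index `i` such that every subsequent
#' per-iteration gain in distinct matched codes is at most `tolerance`
#' (default 0 -- no new codes at all); `n_iterations` if the curve never
#' plateaus.
#'
#' @param run An `ali_expansion_run` (or a list with a numeric `saturation`
#'   element of length >= 2).
#' @param tolerance Maximum per-iteration gain still counted as "flat".
#' @return Integer iteration index.
#' @examples
#' saturation_plateau(list(saturation = c(10, 18, 24, 24, 24)))  # 3
#' @export
saturation_plateau <- function(run, tolerance = 0) {
  s <- run$saturation
  n <- length(s)
  stopifnot(n >= 2)
  gains <- diff(s)
  flat_from <- which(rev(cumsum(rev(gains > tolerance))) == 0)
  if (length(flat_from) == 0) n else flat_from[1]
}

#' Deterministic mock term proposer
#'
#' Emulates a stochastic language-model proposer by sampling `k` terms per
#' component (without replacement) from a fixed pool on every invocation.
#' Draws are seeded from `base_seed + iteration`, so a fixed-seed run is
#' bit-reproducible while iterations remain mutually independent. In
#' context mode the mock echoes the seed examples back (as a cooperative
#' proposer instructed to include the given examples would).
#'
#' @param pool Tibble (`component`, `term`) of candidate terms.
#' @param k Terms drawn per component per invocation (capped at pool size).
#' @param base_seed Integer base seed.
#' @param echo_seeds Include `seed_examples` in every proposal when
#'   supplied (context mode behaviour).
#' @return A proposer function for [run_expansion()].
#' @export
mock_proposer <- function(pool, k = 5, base_seed = 1, echo_seeds = TRUE) {
  require_columns(pool, c("component", "term"), "pool")
  assert_components(pool$component)
  by_comp <- split(pool$term, pool$component)
  function(components, seed_examples, iteration) {
    withr::with_seed(base_seed + iteration, {
      prop <- lapply(by_comp, function(terms)
        sample(terms, size = min(k, length(terms))))
      if (!is.null(seed_examples) && echo_seeds) {
        for (comp in names(seed_examples)) {
          prop[[comp]] <- unique(c(prop[[comp]] %||% character(),
                                   seed_examples[[comp]]))
        }
      }
      prop
    })
  }
}

#' Replay recorded proposals from fixture files
#'
#' Reads one `component, term` CSV per iteration and replays it, allowing a
#' recorded live-proposer session to be re-run offline.
#'
#' @param paths Character vector of CSV paths, one per iteration (recycled
#'   if shorter than the requested number of iterations).
#' @return A proposer function for [run_expansion()].
#' @export
fixture_proposer <- function(paths) {
  stopifnot(length(paths) >= 1)
  function(components, seed_examples, iteration) {
    path <- paths[[(iteration - 1L) %% length(paths) + 1L]]
    df <- read_csv_strict(path, "proposal fixture")
    require_columns(df, c("component", "term"), "proposal fixture")
    split(df$term, df$component)
  }
}

#' @rdname ali_io
#' @param run An `ali_expansion_run`.
#' @export
write_expansion_run <- function(run, path) {
  out <- list(
    mode = run$mode, n_iterations = run$n_iterations,
    failed_iterations = run$failed_iterations,
    saturation = run$saturation,
    proposals = lapply(run$proposals, function(p) unclass(p)),
    aggregate = unclass(tibble::as_tibble(run$aggregate)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
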