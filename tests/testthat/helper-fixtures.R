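# Shared in-code fixtures: tiny deterministic objects plus random-instance
# generators for property-style tests. All randomness is seeded by callers.

tiny_catalog <- function() {
  icd10_catalog(tibble::tibble(
    code = c("I10", "E66.9", "E11.9", "A41.9", "N39.0", "E55.9", "I50.9",
             "Z99.9"),
    description = c("Essential (primary) hypertension",
                    "Obesity, unspecified",
                    "Type 2 diabetes mellitus without complications",
                    "Sepsis, unspecified organism",
                    "Urinary tract infection, site not specified",
                    "Vitamin D deficiency, unspecified",
                    "Heart failure, unspecified",
                    "Encounter for other administrative examinations")))
}

tiny_roadmap <- function(name = "tiny") {
  roadmap(tibble::tibble(
    component = c("SBP", "BMI", "CRP", "CRP", "HBA1C", "HCST"),
    term = c("Hypertension", "Obesity", "Sepsis", "infection", "Diabetes",
             "Vitamin deficiency")), name = name)
}

# one fully healthy/complete record set for n patients
complete_records <- function(patient_ids, status = "HEALTHY") {
  tidyr::expand_grid(patient_id = patient_ids, component = component_ids()) |>
    dplyr::mutate(status = status)
}

# random word vocabulary shared by roadmap and catalog generators so that
# term/description overlaps actually occur
prop_vocab <- c("renal", "failure", "acute", "chronic", "hyper", "tension",
                "hypertension", "obesity", "morbid", "sepsis", "infection",
                "vitamin", "deficiency", "diabetes", "kidney", "injury",
                "syndrome", "disease", "disorder", "unspecified", "severe",
                "mild", "heart", "art", "gly", "glycemic", "control")

random_roadmap <- function(n_terms = 12, seed = 1) {
  withr::with_seed(seed, {
    comps <- sample(component_ids(), n_terms, replace = TRUE)
    terms <- vapply(seq_len(n_terms), function(i)
      paste(sample(prop_vocab, sample(1:3, 1)), collapse = " "), character(1))
    roadmap(tibble::tibble(component = comps, term = terms),
            name = sprintf("random%d", seed))
  })
}

random_catalog <- function(n_codes = 60, seed = 1) {
  withr::with_seed(seed, {
    desc <- vapply(seq_len(n_codes), function(i)
      paste(sample(prop_vocab, sample(2:6, 1)), collapse = " "), character(1))
    icd10_catalog(tibble::tibble(
      code = sprintf("R%04d", seq_len(n_codes)), description = desc))
  })
}

# independent quadratic reference for roadmap expansion: plain double loop
# over (term, code) pairs with a scalar predicate written from the matching
# rule itself
oracle_expand <- function(rm, catalog, mode = "token",
                          exclusions = character()) {
  norm <- function(x) trimws(gsub(" +", " ", gsub("[^a-z0-9]+", " ", tolower(x))))
  pair_matches <- function(term, desc) {
    toks <- strsplit(norm(term), " ")[[1]]
    nd <- norm(desc)
    if (mode == "token") {
      dtoks <- strsplit(nd, " ")[[1]]
      all(vapply(toks, function(t) t %in% dtoks, logical(1)))
    } else {
      all(vapply(toks, function(t) grepl(t, nd, fixed = TRUE), logical(1)))
    }
  }
  excl <- unique(c(code_exclusions(rm), exclusions))
  hits <- list()
  for (i in seq_len(nrow(rm))) {
    for (j in seq_len(nrow(catalog))) {
      if (pair_matches(rm$term[i], catalog$description[j]) &&
          !catalog$code[j] %in% excl) {
        hits[[length(hits) + 1]] <- c(rm$component[i], catalog$code[j])
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(component = character(), code = character()))
  }
  out <- unique(tibble::tibble(component = vapply(hits, `[`, "", 1),
                               code = vapply(hits, `[`, "", 2)))
  out[order(out$component, out$code), ]
}

universe_codes <- function(universe) {
  u <- universe$codes
  u[order(u$component, u$code), ]
}

small_study <- function(seed = 11, n = 120, n_review = 30, ...) {
  rm0 <- original_roadmap()
  catl <- generate_catalog(rm0, n_decoys = 8, n_noise = 60, seed = seed)
  cfg <- generator_config(n_patients = n, seed = seed, n_review = n_review, ...)
  list(roadmap = rm0, catalog = catl, config = cfg,
       study = generate_cohort(cfg, rm0, catl))
}
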