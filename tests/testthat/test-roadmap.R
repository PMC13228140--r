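test_that("term normalization lowercases, strips punctuation, and is idempotent", {
  expect_equal(normalize_term("Auto-immune inflammatory syndrome"),
               "auto immune inflammatory syndrome")
  expect_equal(normalize_term("  Obesity "), "obesity")
  inputs <- c("Grade I obesity", "HYPER-tension!", "a  b\tc", "Sepsis")
  expect_equal(normalize_term(normalize_term(inputs)), normalize_term(inputs))
})

test_that("enumerated grade constructions expand to one term per grade", {
  expect_equal(expand_grade_terms("Grade I, II, or III obesity"),
               c("Grade I obesity", "Grade II obesity", "Grade III obesity"))
  expect_equal(expand_grade_terms("Hypertension"), "Hypertension")
  expect_equal(length(expand_grade_terms("Type 1, 2, or 3 example")), 3)
  expect_equal(expand_grade_terms("Type 1, 2, or 3 example")[2], "Type 2 example")
})

test_that("shipped original roadmap parses to the 20-entry knowledge base", {
  rm0 <- original_roadmap()
  expect_s3_class(rm0, "ali_roadmap")
  expect_equal(nrow(rm0), 20)
  per_comp <- table(factor(rm0$component, levels = component_ids()))
  expect_equal(unname(per_comp["ALB"]), 0, ignore_attr = TRUE)
  expect_equal(unname(per_comp["BMI"]), 5, ignore_attr = TRUE)
  expect_true(all(per_comp[setdiff(component_ids(), "ALB")] > 0))
  expect_true("auto immune inflammatory syndrome" %in% rm0$term)
})

test_that("roadmap construction collapses duplicates after normalization", {
  rm <- roadmap(tibble::tibble(component = c("BMI", "BMI", "BMI"),
                               term = c("Obesity", "obesity", "OBESITY!")))
  expect_equal(nrow(rm), 1)
  expect_error(roadmap(tibble::tibble(component = "XYZ", term = "x")),
               "unknown component")
})

test_that("adjudication keeps exactly the terms with at least one endorsement", {
  rm <- roadmap(tibble::tibble(component = rep("CRP", 3),
                               term = c("sepsis", "infection", "colitis")),
                name = "pre")
  ledger <- tibble::tibble(
    item_type = "term",
    item = c("sepsis", "sepsis", "infection", "infection", "colitis", "colitis"),
    component = "CRP",
    reviewer = rep(c("r1", "r2"), 3),
    verdict = c("endorse", "reject", "reject", "reject", "endorse", "endorse"))
  adj <- adjudicate(rm, ledger)
  expect_setequal(adj$term, c("sepsis", "colitis"))
  expect_true(all(adj$provenance == "endorsed"))

  empty <- tibble::tibble(item_type = character(), item = character(),
                          component = character(), reviewer = character(),
                          verdict = character())
  expect_equal(nrow(adjudicate(rm, empty)), 0)

  expect_warning(adjudicate(rm, tibble::tibble(
    item_type = "term", item = "not present", component = "CRP",
    reviewer = "r1", verdict = "endorse")), "not in roadmap")
})

test_that("code-level adjudication builds exclusion lists without touching terms", {
  rm <- tiny_roadmap()
  ledger <- tibble::tibble(
    item_type = "code", item = c("A41.9", "A41.9", "N39.0"),
    component = "CRP", reviewer = c("r1", "r2", "r1"),
    verdict = c("endorse", "reject", "reject"))
  adj <- adjudicate(rm, ledger)
  expect_equal(nrow(adj), nrow(rm))          # terms untouched
  expect_equal(code_exclusions(adj), "N39.0") # only the never-endorsed code
  uni_pre <- expand_roadmap(rm, tiny_catalog())
  uni_post <- expand_roadmap(adj, tiny_catalog())
  expect_true(all(uni_post$codes$code %in% uni_pre$codes$code))
  expect_false("N39.0" %in% uni_post$codes$code)
})

test_that("adjudication is contractive and idempotent on random instances", {
  for (seed in 1:15) {
    rm <- random_roadmap(n_terms = 10, seed = seed)
    withr::with_seed(seed + 100, {
      idx <- sample(nrow(rm), sample(0:nrow(rm), 1))
      ledger <- tibble::tibble(
        item_type = "term",
        item = c(rm$term[idx], rm$term[idx]),
        component = c(rm$component[idx], rm$component[idx]),
        reviewer = rep(c("r1", "r2"), each = length(idx)),
        verdict = sample(c("endorse", "reject"), 2 * length(idx), replace = TRUE))
    })
    adj <- adjudicate(rm, ledger)
    expect_true(all(paste(adj$component, adj$term) %in%
                      paste(rm$component, rm$term)))
    adj2 <- suppressWarnings(adjudicate(adj, ledger))
    expect_equal(tibble::as_tibble(adj2)[, c("component", "term")],
                 tibble::as_tibble(adj)[, c("component", "term")],
                 ignore_attr = TRUE)
  }
})

test_that("roadmap diffs partition the union into added/removed/shared", {
  a <- tiny_roadmap("a")
  expect_true(all(diff_roadmaps(a, a)$change == "shared"))

  b <- roadmap(dplyr::bind_rows(
    tibble::as_tibble(a)[, c("component", "term")],
    tibble::tibble(component = "CC", term = "renal failure")), name = "b")
  d <- diff_roadmaps(a, b)
  expect_equal(sum(d$change == "removed"), 0)
  expect_equal(d$term[d$change == "added"], "renal failure")

  for (seed in 1:10) {
    x <- random_roadmap(8, seed)
    y <- random_roadmap(8, seed + 50)
    d <- diff_roadmaps(x, y)
    key <- function(r) paste(r$component, r$term)
    expect_setequal(key(d), union(key(x), key(y)))
    expect_setequal(key(d[d$change != "added", ]), key(x))
    expect_setequal(key(d[d$change != "removed", ]), key(y))
  }
})

test_that("ledger reader validates item types and verdicts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item_type,item,component,reviewer,verdict",
               "term,sepsis,CRP,r1,endorse"), path)
  expect_equal(nrow(read_ledger(path)), 1)
  writeLines(c("item_type,item,component,reviewer,verdict",
               "term,sepsis,CRP,r1,maybe"), path)
  expect_error(read_ledger(path), "verdict")
})
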