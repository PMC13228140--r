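test_that("flow tables conserve totals and reject illegal algorithm transitions", {
  ehr <- complete_records(c("P1", "P2"), "HEALTHY")
  ehr$status[c(1, 5, 12)] <- "MISSING"
  post <- ehr
  post$status[1] <- "UNHEALTHY"
  flow <- build_flow(ehr, post, source = "algorithm")
  expect_equal(flow$n_points, 20)
  expect_equal(sum(flow$counts$n_pre), 20)
  expect_equal(sum(flow$counts$n_post), 20)
  expect_equal(flow$n_missing_pre, 3)
  expect_equal(flow$n_recovered, 1)

  # identical inputs: zero transitions
  expect_equal(nrow(build_flow(ehr, ehr)$transitions), 0)

  # algorithm flipping a healthy point is an integrity error
  bad <- ehr
  bad$status[2] <- "UNHEALTHY"
  expect_error(build_flow(ehr, bad, source = "algorithm"), "integrity error")
  # ... but a chart source may disagree on non-missing points
  expect_silent(build_flow(ehr, bad, source = "chart"))

  expect_error(build_flow(ehr, post[1:10, ]), "same .patient, component. universe")
})

test_that("flow counting matches a direct oracle on random valid instances", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      ehr <- complete_records(sprintf("P%d", 1:15))
      ehr$status <- sample(c("UNHEALTHY", "HEALTHY", "MISSING"), 150,
                           replace = TRUE)
      post <- ehr
      miss <- which(post$status == "MISSING")
      flip <- miss[stats::runif(length(miss)) < 0.5]
      post$status[flip] <- "UNHEALTHY"
    })
    flow <- build_flow(ehr, post, source = "algorithm")
    expect_equal(flow$n_recovered, length(flip))
    expect_equal(flow$counts$n_post[flow$counts$status == "UNHEALTHY"],
                 sum(ehr$status == "UNHEALTHY") + length(flip))
  }
})

test_that("missingness summaries report per-patient and per-component counts", {
  recs <- complete_records(c("P1", "P2"))
  ms <- missingness_summary(recs)
  expect_equal(unname(ms$nonmissing_summary["median"]), 10)
  expect_true(all(ms$per_component$n_missing == 0))

  one <- complete_records("P1")
  one$status[one$component %in% c("CRP", "HCST", "CC", "ALB")] <- "MISSING"
  ms <- missingness_summary(one)
  expect_equal(unname(ms$nonmissing_summary["median"]), 6)
  expect_equal(ms$per_component$n_missing[ms$per_component$component == "CRP"], 1)
  expect_equal(ms$per_component$component, component_ids())
})

test_that("disagreement taxonomy partitions the union of recovered points", {
  base <- complete_records(c("P1", "P2"))
  base$status[base$component %in% c("CRP", "HCST")] <- "MISSING"
  mk <- function(recover_keys) {
    post <- base
    keys <- paste(post$patient_id, post$component)
    post$status[keys %in% recover_keys & post$status == "MISSING"] <- "UNHEALTHY"
    chart_as_recovery(base, post)
  }
  chart <- mk("P1 CRP")
  algo <- mk("P2 HCST")
  d <- disagreements(chart, algo)
  expect_equal(unname(d$total), c(1, 1, 0), ignore_attr = TRUE)

  same <- disagreements(mk("P1 CRP"), mk("P1 CRP"))
  expect_equal(unname(same$total), c(0, 0, 1), ignore_attr = TRUE)

  for (seed in 1:10) {
    withr::with_seed(seed, {
      keys <- paste(base$patient_id, base$component)[base$status == "MISSING"]
      kc <- sample(keys, sample(0:4, 1))
      ka <- sample(keys, sample(0:4, 1))
    })
    d <- disagreements(mk(kc), mk(ka))
    expect_equal(d$total[["chart_only"]], length(setdiff(kc, ka)))
    expect_equal(d$total[["algorithm_only"]], length(setdiff(ka, kc)))
    expect_equal(d$total[["agreement"]], length(intersect(kc, ka)))
  }
})

test_that("engagement regression flags degenerate designs and separations", {
  patients <- tibble::tibble(patient_id = sprintf("P%d", 1:50),
                             engaged = rep(c(TRUE, FALSE), 25))
  const_ali <- tibble::tibble(patient_id = patients$patient_id, ali = 0.4)
  fit <- engagement_model(patients, const_ali)
  expect_equal(fit$flag, "degenerate")
  expect_true(is.na(fit$coefficient))

  sep <- tibble::tibble(patient_id = patients$patient_id,
                        ali = ifelse(patients$engaged, 0.9, 0.1))
  fit <- engagement_model(patients, sep)
  expect_equal(fit$flag, "separation")
  expect_equal(fit$ci_lower, -Inf)
  expect_equal(fit$ci_upper, Inf)
})

test_that("engagement estimates are invariant to duplicating every observation", {
  withr::with_seed(8, {
    ali <- stats::runif(200)
    patients <- tibble::tibble(
      patient_id = sprintf("P%d", 1:200),
      engaged = stats::rbinom(200, 1, stats::plogis(-1 + 2 * ali)) == 1)
  })
  scores <- tibble::tibble(patient_id = patients$patient_id, ali = ali)
  fit1 <- engagement_model(patients, scores)
  doubled_p <- dplyr::bind_rows(patients,
                                dplyr::mutate(patients,
                                              patient_id = paste0(patient_id, "b")))
  doubled_s <- dplyr::bind_rows(scores,
                                dplyr::mutate(scores,
                                              patient_id = paste0(patient_id, "b")))
  fit2 <- engagement_model(doubled_p, doubled_s)
  expect_equal(fit2$coefficient, fit1$coefficient, tolerance = 1e-6)
  expect_equal(fit2$n, 2 * fit1$n)
})

test_that("patients with undefined ALI are excluded and counted", {
  patients <- tibble::tibble(patient_id = sprintf("P%d", 1:40),
                             engaged = rep(c(TRUE, FALSE), 20))
  withr::with_seed(3, scores <- tibble::tibble(
    patient_id = patients$patient_id,
    ali = c(NA, NA, stats::runif(38))))
  fit <- engagement_model(patients, scores)
  expect_equal(fit$n_excluded, 2)
  expect_equal(fit$n, 38)
})

test_that("the engagement fit recovers the generator's true slope at n = 5000", {
  sim <- small_study(seed = 99, n = 5000, n_review = 100)
  truth <- sim$study$truth$per_patient
  fit <- engagement_model(sim$study$cohort,
                          tibble::tibble(patient_id = truth$patient_id,
                                         ali = truth$ali_true))
  beta1 <- sim$config$engagement_beta1
  expect_equal(fit$flag, "ok")
  expect_lt(abs(fit$coefficient - beta1), 3 * fit$se)
  expect_true(fit$ci_lower < beta1 && beta1 < fit$ci_upper)
})

test_that("the full evaluation report assembles and serializes", {
  sim <- small_study(seed = 71, n = 60, n_review = 20)
  uni <- expand_roadmap(sim$roadmap, sim$catalog)
  ehr <- discretize_biomarkers(sim$study$biomarkers, sim$study$cohort)
  algo <- recover(ehr, sim$study$diagnoses, uni)
  ev <- evaluate_recovery(ehr, algo, sim$study$cohort)
  expect_equal(ev$flow$n_points, 600)
  expect_gte(ev$ali_post[["median"]], ev$ali_pre[["median"]])
  expect_equal(nrow(ev$scatter), 60)
  path <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(ev, path)
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(report$flow$n_points, 600)
  expect_equal(report$recovery$n_recovered, recovery_counts(algo)$n_recovered)
})
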