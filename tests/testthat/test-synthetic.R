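test_that("generator configs validate probabilities and sizes", {
  expect_s3_class(generator_config(n_patients = 10, n_review = 5),
                  "ali_generator_config")
  expect_error(generator_config(prevalence = 1.2), "prevalence")
  expect_error(generator_config(n_patients = 10, n_review = 20), "n_review")
  expect_error(generator_config(measurement_prob = c(CRP = -0.1)),
               "measurement_prob")
  expect_error(generator_config(measurement_prob = c(XYZ = 0.5)), "XYZ")
  # scalar recycling and named overrides
  cfg <- generator_config(prevalence = 0.2,
                          measurement_prob = c(CRP = 0.5))
  expect_equal(unname(cfg$prevalence), rep(0.2, 10))
  expect_equal(unname(cfg$measurement_prob["CRP"]), 0.5)
  expect_equal(unname(cfg$measurement_prob["SBP"]), 1)
})

test_that("synthetic catalogs separate token matches, decoys, and noise", {
  rm0 <- original_roadmap()
  catl <- generate_catalog(rm0, n_decoys = 15, n_noise = 40, seed = 5)
  u_token <- expand_roadmap(rm0, catl, mode = "token")
  u_sub <- expand_roadmap(rm0, catl, mode = "substring")
  # every component with terms matches at least one code in token mode
  expect_setequal(unique(u_token$codes$component),
                  setdiff(unique(rm0$component), character(0)))
  # decoys (code prefix D) are substring-only matches
  expect_false(any(grepl("^D", u_token$codes$code)))
  expect_true(any(grepl("^D", u_sub$codes$code)))
  # noise codes (prefix N) match in neither mode
  expect_false(any(grepl("^N", u_sub$codes$code)))

  # zero decoys/noise: catalog matches the roadmap universe exactly
  pure <- generate_catalog(rm0, n_decoys = 0, n_noise = 0, seed = 5)
  u_pure <- expand_roadmap(rm0, pure, mode = "token")
  expect_setequal(unique(u_pure$codes$code), pure$code)
})

test_that("fixed seeds reproduce studies exactly; different seeds diverge", {
  rm0 <- original_roadmap()
  catl <- generate_catalog(rm0, n_decoys = 5, n_noise = 30, seed = 1)
  cfg <- generator_config(n_patients = 50, seed = 42, n_review = 10)
  s1 <- generate_cohort(cfg, rm0, catl)
  s2 <- generate_cohort(cfg, rm0, catl)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$diagnoses, s2$diagnoses)
  expect_identical(s1$chart_review, s2$chart_review)

  cfg3 <- generator_config(n_patients = 50, seed = 43, n_review = 10)
  s3 <- generate_cohort(cfg3, rm0, catl)
  expect_false(identical(s1$diagnoses, s3$diagnoses))

  # same-seed bundles are byte-identical on disk
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(s1, d1)
  write_fixture_bundle(s2, d2)
  for (f in c("cohort.csv", "biomarkers.csv", "diagnoses.csv",
              "chart_review.csv", "icd10_catalog.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("full measurement probability yields a complete dataset", {
  rm0 <- original_roadmap()
  catl <- generate_catalog(rm0, n_decoys = 0, n_noise = 20, seed = 2)
  cfg <- generator_config(n_patients = 40, seed = 3, n_review = 10,
                          measurement_prob = 1)
  st <- generate_cohort(cfg, rm0, catl)
  expect_false(any(is.na(st$biomarkers$value)))
  ehr <- discretize_biomarkers(st$biomarkers, st$cohort)
  expect_false(any(ehr$status == "MISSING"))
  # and values discretize back to the latent truth
  expect_equal(ehr$status == "UNHEALTHY", st$truth$per_point$true_unhealthy)
})

test_that("empirical rates converge to configured values at n = 5000", {
  sim <- small_study(seed = 77, n = 5000, n_review = 100)
  st <- sim$study
  cfg <- sim$config
  pts <- st$truth$per_point

  # per-component missingness within 3 binomial standard errors
  for (comp in component_ids()) {
    p_miss <- 1 - cfg$measurement_prob[[comp]]
    obs <- sum(is.na(st$biomarkers$value[st$biomarkers$component == comp]))
    se <- sqrt(p_miss * (1 - p_miss) * 5000)
    expect_lte(abs(obs - 5000 * p_miss), max(3 * se, 1e-9))
  }

  # carriage sensitivity among truly unhealthy, for components with codes
  uni <- expand_roadmap(sim$roadmap, sim$catalog)
  with_codes <- unique(uni$codes$component)
  for (comp in with_codes) {
    sub <- pts[pts$component == comp & pts$true_unhealthy, ]
    p <- cfg$carriage_sensitivity[[comp]]
    se <- sqrt(p * (1 - p) / nrow(sub))
    expect_lte(abs(mean(sub$carries_code) - p), 3 * se)
  }

  # engagement rate near the logistic model's implied marginal
  truth <- st$truth$per_patient
  expect_lte(abs(mean(truth$engaged) - mean(truth$p_engaged)),
             3 * sqrt(0.25 / 5000))

  # prevalence calibration
  p <- cfg$prevalence[["TRIG"]]
  obs <- mean(pts$true_unhealthy[pts$component == "TRIG"])
  expect_lte(abs(obs - p), 3 * sqrt(p * (1 - p) / 5000))
})

test_that("perfect carriage recovers exactly the truly-unhealthy missing set", {
  rm0 <- original_roadmap()
  catl <- generate_catalog(rm0, n_decoys = 10, n_noise = 50, seed = 8)
  cfg <- generator_config(n_patients = 400, seed = 9, n_review = 40,
                          carriage_sensitivity = 1, false_carriage = 0)
  st <- generate_cohort(cfg, rm0, catl)
  ehr <- discretize_biomarkers(st$biomarkers, st$cohort)
  uni <- expand_roadmap(rm0, catl)
  res <- recover(ehr, st$diagnoses, uni)
  got <- recovered_points(res)
  pts <- st$truth$per_point
  with_codes <- unique(uni$codes$component)
  want <- pts[pts$true_unhealthy & !pts$measured &
                pts$component %in% with_codes, c("patient_id", "component")]
  expect_setequal(paste(got$patient_id, got$component),
                  paste(want$patient_id, want$component))
})

test_that("chart-review oracle respects protocol-error and recovery rules", {
  sim <- small_study(seed = 55, n = 200, n_review = 60)
  st <- sim$study
  chart <- st$chart_review
  pts <- st$truth$per_point
  key <- paste(pts$patient_id, pts$component)
  idx <- match(paste(chart$patient_id, chart$component), key)
  # protocol errors and recoveries only occur on points missing in the EHR
  pe <- chart$reviewed_status == "PROTOCOL_ERROR"
  expect_true(all(!pts$measured[idx][pe]))
  rec <- !pts$measured[idx] & chart$reviewed_status == "UNHEALTHY"
  expect_true(all(pts$true_unhealthy[idx][rec]))
  # measured points validate: chart equals discretized EHR value
  ehr <- discretize_biomarkers(st$biomarkers, st$cohort)
  ehr_idx <- match(paste(chart$patient_id, chart$component),
                   paste(ehr$patient_id, ehr$component))
  measured <- pts$measured[idx]
  expect_equal(chart$reviewed_status[measured], ehr$status[ehr_idx][measured])
  # review subset balanced 50/50 on engagement
  reviewed <- unique(chart$patient_id)
  engaged <- st$cohort$engaged[match(reviewed, st$cohort$patient_id)]
  expect_equal(sum(engaged), 30)
})

test_that("sicker-measured-more MNAR knob shifts observed prevalence", {
  rm0 <- original_roadmap()
  catl <- generate_catalog(rm0, n_decoys = 0, n_noise = 20, seed = 4)
  base <- generator_config(n_patients = 2000, seed = 13, n_review = 50,
                           measurement_prob = 0.4)
  mnar <- generator_config(n_patients = 2000, seed = 13, n_review = 50,
                           measurement_prob = 0.4, mnar_multiplier = 2)
  st_base <- generate_cohort(base, rm0, catl)
  st_mnar <- generate_cohort(mnar, rm0, catl)
  frac_unhealthy <- function(st) {
    ehr <- discretize_biomarkers(st$biomarkers, st$cohort)
    mean(ehr$status[ehr$status != "MISSING"] == "UNHEALTHY")
  }
  expect_gt(frac_unhealthy(st_mnar), frac_unhealthy(st_base) + 0.05)
})
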