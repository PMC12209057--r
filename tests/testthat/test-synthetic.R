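test_that("generation is deterministic for a fixed seed and config", {
  cfg <- sim_config(n_patients = 200L, seed = 61L)
  a <- simulate_claims(cfg)
  b <- simulate_claims(cfg)
  expect_identical(a$bundle$enrollment, b$bundle$enrollment)
  expect_identical(a$bundle$prescriptions, b$bundle$prescriptions)
  expect_identical(a$bundle$diagnoses, b$bundle$diagnoses)
  expect_identical(a$bundle$visits, b$bundle$visits)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  c_ <- simulate_claims(sim_config(n_patients = 200L, seed = 62L))
  expect_false(identical(a$bundle$prescriptions, c_$bundle$prescriptions))
})

test_that("zero patients give an empty but valid bundle", {
  out <- simulate_claims(sim_config(n_patients = 0L))
  expect_s3_class(out$bundle, "claims_bundle")
  expect_equal(nrow(out$bundle$enrollment), 0L)
  expect_equal(nrow(out$truth), 0L)
})

test_that("configuration validation rejects impossible values", {
  expect_error(sim_config(frac_new_users = 1.2), "probabilities")
  expect_error(sim_config(discontinuation_hazard = -0.1), "hazard")
  expect_error(sim_config(n_patients = -5), "n_patients")
  expect_error(sim_config(supply_probs = c("30" = 0.5, "60" = 0.4)), "sum to 1")
  expect_error(
    simulate_claims(sim_config(covariate_log_odds = c(not_a_covariate = 1))),
    "unknown covariate")
})

test_that("emitted diagnoses hit the configured comorbidity prevalence", {
  n <- 5000L
  sim <- simulate_claims(sim_config(n_patients = n, seed = 67L))
  b <- sim$bundle
  # measure hypertension from the claims themselves: a non-suspected I10
  # diagnosis in the 180-day pre-index window
  idx <- as.integer(sim$truth$index_date)[match(b$diagnoses$patient_id,
                                                sim$truth$patient_id)]
  day <- as.integer(b$diagnoses$dx_date) - idx
  hit <- startsWith(b$diagnoses$icd10_code, "I10") & !b$diagnoses$suspected_flag &
    day >= -180L & day < 0L
  frac <- length(unique(b$diagnoses$patient_id[hit])) / n
  p <- 0.611
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), 3 * se)
  # and the claims agree with the planted truth flags
  expect_equal(sort(unique(b$diagnoses$patient_id[hit])),
               sort(sim$truth$patient_id[sim$truth$hypertension]))
})

test_that("initiators have full pre- and post-index enrollment coverage", {
  sim <- simulate_claims(sim_config(n_patients = 400L, seed = 71L))
  tr <- sim$truth[sim$truth$role %in% c("new_user", "combo_at_index", "fdc_at_index"), ]
  enr <- sim$bundle$enrollment[match(tr$patient_id, sim$bundle$enrollment$patient_id), ]
  expect_true(all(tr$index_date - 180L >= enr$obs_start))
  expect_true(all(tr$index_date + 364L <= enr$obs_end))
  # index dates span both calendar-year strata
  expect_setequal(sort(unique(format(tr$index_date, "%Y"))), c("2018", "2019"))
})

test_that("doubling the hazard does not increase mean persistence", {
  run <- function(h) {
    sim <- simulate_claims(sim_config(n_patients = 2000L, seed = 73L,
                                      discontinuation_hazard = h))
    cb <- build_cohort(sim$bundle)
    e <- compute_exposure(cb$cohort, sim$bundle, gap_policy(90))
    mean(e$persistence_days)
  }
  expect_lte(run(0.0032), run(0.0016))
})

test_that("the measured exposure agrees with the planted truth", {
  sim <- simulate_claims(sim_config(n_patients = 1500L, seed = 79L,
                                    switch_prob = 0))
  cb <- build_cohort(sim$bundle)
  e <- compute_exposure(cb$cohort, sim$bundle, gap_policy(90))
  tr <- sim$truth[match(e$patient_id, sim$truth$patient_id), ]
  # every planted event among cohort members is detected, and no
  # spontaneous events occur among planted persisters
  expect_equal(e$discontinued, !is.na(tr$true_discontinuation_day))
  # restarters are recovered exactly on gap discontinuers
  gap_ev <- e$discontinued & e$reason == "gap"
  expect_equal(e$restarted[gap_ev], tr$true_restarter[gap_ev])
})

test_that("the worked fixture ships its branches and survives a round trip", {
  wf <- worked_fixture()
  expect_true("P_gap100" %in% wf$bundle$enrollment$patient_id)
  expect_equal(nrow(wf$expected), 13L)
  expect_equal(sum(wf$expected$in_cohort), 7L)
  # one patient per selection branch
  expect_equal(anyDuplicated(stats::na.omit(wf$expected$drop_stage)), 0L)
  # one patient per exposure branch under the primary policy
  inc <- wf$expected[wf$expected$in_cohort, ]
  expect_equal(sum(inc$reason_90 == "gap" & inc$restarted_90), 1L)
  expect_equal(sum(inc$reason_90 == "gap" & !inc$restarted_90), 1L)
  expect_equal(sum(inc$reason_90 == "switch"), 1L)
  expect_equal(sum(inc$reason_90 == "none"), 4L)
  dir <- withr::local_tempdir()
  write_claims_bundle(wf$bundle, dir)
  back <- read_claims_bundle(dir, quiet = TRUE)
  expect_equal(back$prescriptions, wf$bundle$prescriptions)
})
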