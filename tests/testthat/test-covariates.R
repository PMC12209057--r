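idx0 <- as.Date("2018-06-01")

dx_row <- function(code, offset, suspected = FALSE) {
  data.frame(patient_id = "X", dx_date = idx0 + offset, icd10_code = code,
             suspected_flag = suspected, stringsAsFactors = FALSE)
}

test_that("comorbidity flags respect code prefix, suspected flag, and window", {
  expect_true(flag_comorbidity(dx_row("I10", -30L), "I10", idx0))
  expect_false(flag_comorbidity(dx_row("E78", -30L, suspected = TRUE), "E78", idx0))
  expect_false(flag_comorbidity(dx_row("E790", -200L), "E790", idx0))
  expect_false(flag_comorbidity(dx_row("I10", 0L), "I10", idx0))  # index day excluded
  # prefix matching is on normalized codes (dots stripped, case-folded)
  expect_true(flag_comorbidity(dx_row("e79.0", -10L), "E790", idx0))
  expect_false(flag_comorbidity(dx_row("E791", -10L), "E790", idx0))
})

test_that("concomitant classes count distinct classes, not fills", {
  rx_row <- function(code, offset) {
    data.frame(patient_id = "X", rx_date = idx0 + offset, atc_code = code,
               days_supply = 30L, fdc_flag = FALSE, stringsAsFactors = FALSE)
  }
  two <- rbind(rx_row("C09AA05", -60L), rx_row("C10AA07", -40L))
  expect_equal(count_concomitant_classes(two, idx0), 2L)
  five_same <- do.call(rbind, lapply(seq(-150L, -30L, 30L), rx_row, code = "C08CA01"))
  expect_equal(count_concomitant_classes(five_same, idx0), 1L)
  expect_equal(count_concomitant_classes(two[0L, ], idx0), 0L)
  # out-of-window fills do not count
  expect_equal(count_concomitant_classes(rx_row("C03CA01", -200L), idx0), 0L)
})

test_that("visit statistics count claims but collapse duplicate dates for the interval", {
  v <- function(offsets) data.frame(patient_id = "X", visit_date = idx0 + offsets,
                                    stringsAsFactors = FALSE)
  expect_equal(visit_stats(v(c(-180L, -120L, -60L)), idx0),
               list(n_visits = 3L, mean_interval_days = 60))
  expect_equal(visit_stats(v(c(-40L, -7L)), idx0),
               list(n_visits = 2L, mean_interval_days = 33))
  # duplicate same-day claims: counted in n_visits, collapsed for the interval
  expect_equal(visit_stats(v(c(-80L, -40L, -40L)), idx0),
               list(n_visits = 3L, mean_interval_days = 40))
  expect_error(visit_stats(v(-30L), idx0), "fewer than two")
})

test_that("the Charlson index sums weights with severity hierarchies", {
  expect_equal(compute_cci(dx_row("E119", -10L)[0L, ], idx0), 0L)
  expect_equal(compute_cci(dx_row("E119", -10L), idx0), 1L)
  expect_equal(compute_cci(rbind(dx_row("E119", -10L), dx_row("K703", -20L)), idx0), 2L)
  # complicated diabetes supersedes uncomplicated: weight 2, not 3
  expect_equal(compute_cci(rbind(dx_row("E119", -10L), dx_row("E112", -20L)), idx0), 2L)
  # metastasis supersedes malignancy: 6, not 8
  expect_equal(compute_cci(rbind(dx_row("C50", -10L), dx_row("C780", -20L)), idx0), 6L)
  # suspected and out-of-window diagnoses are ignored
  expect_equal(compute_cci(rbind(dx_row("E119", -10L, suspected = TRUE),
                                 dx_row("I21", -300L)), idx0), 0L)
})

test_that("adding a diagnosis never decreases the Charlson score", {
  set.seed(37)
  pool <- c("E119", "E112", "I21", "I50", "K703", "K704", "C50", "C780",
            "J44", "N189", "F01", "M05", "B20")
  for (i in 1:50) {
    base_codes <- sample(pool, sample.int(4L, 1L))
    extra <- sample(pool, 1L)
    base <- do.call(rbind, lapply(base_codes, dx_row, offset = -20L))
    bigger <- rbind(base, dx_row(extra, -40L))
    expect_lte(compute_cci(base, idx0), compute_cci(bigger, idx0))
  }
})

test_that("the vectorized covariate builder agrees with the per-patient operations", {
  wf <- worked_fixture()
  cb <- build_cohort(wf$bundle)
  cv <- build_covariates(cb$cohort, wf$bundle)
  cm <- default_code_map()
  for (i in seq_len(nrow(cb$cohort))) {
    pid <- cb$cohort$patient_id[i]
    idx <- cb$cohort$index_date[i]
    pdx <- wf$bundle$diagnoses[wf$bundle$diagnoses$patient_id == pid, ]
    prx <- wf$bundle$prescriptions[wf$bundle$prescriptions$patient_id == pid, ]
    pvis <- wf$bundle$visits[wf$bundle$visits$patient_id == pid, ]
    row <- cv[cv$patient_id == pid, ]
    vs <- visit_stats(pvis, idx)
    expect_equal(row$n_visits, vs$n_visits, info = pid)
    expect_equal(row$mean_visit_interval_days, vs$mean_interval_days, info = pid)
    expect_equal(row$n_concomitant_classes,
                 count_concomitant_classes(prx, idx), info = pid)
    for (nm in names(cm$comorbidity)) {
      expect_equal(row[[nm]], flag_comorbidity(pdx, cm$comorbidity[[nm]], idx),
                   info = paste(pid, nm))
    }
    expect_equal(row$cci, compute_cci(pdx, idx), info = pid)
  }
})

test_that("fixture covariates match their hand-authored baseline", {
  wf <- worked_fixture()
  cb <- build_cohort(wf$bundle)
  cv <- build_covariates(cb$cohort, wf$bundle)
  g <- function(pid) cv[cv$patient_id == pid, ]
  expect_true(g("P_persist")$hypertension)
  expect_false(g("P_persist")$dyslipidemia)      # only a suspected E78 claim
  expect_equal(g("P_persist")$n_concomitant_classes, 2L)
  expect_false(g("P_gap100")$hyperuricemia)      # diagnosis outside the window
  expect_true(g("P_gap60")$hyperuricemia)
  expect_true(g("P_switch")$nephropathy)
  expect_equal(g("P_switch")$cci, 2L)            # complicated-diabetes hierarchy
  expect_true(g("P_trailing")$depression)
  expect_true(g("P_censor365")$obesity)
  expect_true(g("P_y2019")$dyslipidemia)
  expect_true(all(cv$cci >= 1L))                 # everyone carries the E11 code
})

test_that("covariates other than year, age and sex use only pre-index claims", {
  wf <- worked_fixture()
  cb <- build_cohort(wf$bundle)
  before <- build_covariates(cb$cohort, wf$bundle)
  b <- wf$bundle
  post_dx <- data.frame(patient_id = "P_persist", dx_date = idx0 + 30L,
                        icd10_code = "I10", suspected_flag = FALSE,
                        stringsAsFactors = FALSE)
  post_rx <- data.frame(patient_id = "P_gap60", rx_date = idx0 + 10L,
                        atc_code = "C09AA05", days_supply = 30L, fdc_flag = FALSE,
                        stringsAsFactors = FALSE)
  b2 <- claims_bundle(b$enrollment, rbind(b$prescriptions, post_rx),
                      rbind(b$diagnoses, post_dx), b$visits)
  after <- build_covariates(cb$cohort, b2)
  expect_equal(after, before)
})
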