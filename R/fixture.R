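#' Hand-authored worked example bundle
#'
#' A small bundle of 13 patients constructed so that every cohort-selection
#' branch and every exposure-engine branch occurs exactly once, with the
#' expected per-patient classification shipped alongside. Seven patients
#' enter the cohort:
#'
#' * `P_persist` — monthly refills through day 330; persistent under the
#'   90-day policy, trailing-gap event under the 30-day policy.
#' * `P_gap100` — fills on days 0 and 100 only: gap event at day 30,
#'   restarter.
#' * `P_gap60` — one 60-day gap then monthly refills: persistent under 90,
#'   gap event under 30.
#' * `P_switch` — a second antidiabetic agent on day 40: switch event.
#' * `P_trailing` — last fill on day 30: trailing-gap event at day 60.
#' * `P_censor365` — 90-day supplies with exactly-90-day gaps: the boundary
#'   case, persistent.
#' * `P_y2019` — indexed in calendar year 2019, fully covered.
#'
#' The other six exercise the selection cascade: prior antidiabetic use,
#' insufficient enrollment, combination start at index, fixed-dose
#' combination at index, a single post-index prescription, and fewer than
#' two pre-index visits.
#'
#' @return list with `bundle` (a validated [claims_bundle()]) and
#'   `expected` (data frame of hand-computed per-patient expectations:
#'   cohort membership, exclusion stage, and persistence / restart /
#'   covered-days results under both gap policies).
#' @export
worked_fixture <- function() {
  idx18 <- as.Date("2018-06-01")
  idx19 <- as.Date("2019-02-01")
  win_s <- as.Date("2017-10-01")
  win_e <- as.Date("2020-09-30")

  pat <- list(
    #            id            index  birth      sex      obs_end
    P_persist   = list(idx18, "196803", "male",   win_e),
    P_gap100    = list(idx18, "197511", "female", win_e),
    P_gap60     = list(idx18, "196207", "male",   win_e),
    P_switch    = list(idx18, "198001", "male",   win_e),
    P_trailing  = list(idx18, "197309", "female", win_e),
    P_censor365 = list(idx18, "195806", "male",   win_e),
    P_y2019     = list(idx19, "196911", "female", win_e),
    P_prior_a10 = list(idx18, "197204", "male",   win_e),
    P_short     = list(idx18, "197702", "male",   idx18 + 200L),
    P_combo     = list(idx18, "196510", "female", win_e),
    P_fdc       = list(idx18, "197106", "male",   win_e),
    P_single    = list(idx18, "197908", "male",   win_e),
    P_fewvisits = list(idx18, "196401", "female", win_e)
  )
  ids <- names(pat)
  index_of <- vapply(pat, function(p) as.integer(p[[1L]]), integer(1))
  enrollment <- data.frame(
    patient_id = ids,
    birth_ym = parse_claim_date(vapply(pat, function(p) p[[2L]], character(1))),
    sex = vapply(pat, function(p) p[[3L]], character(1)),
    obs_start = win_s,
    obs_end = as.Date(vapply(pat, function(p) as.integer(p[[4L]]), integer(1)),
                      origin = "1970-01-01"),
    stringsAsFactors = FALSE)

  monthly <- c(seq(0L, 330L, 30L), 360L)
  fills <- list(  # SGLT2i fill day offsets and supplies
    P_persist   = list(seq(0L, 330L, 30L), 30L),
    P_gap100    = list(c(0L, 100L), 30L),
    P_gap60     = list(c(0L, seq(60L, 330L, 30L), 360L), 30L),
    P_switch    = list(c(0L, 30L), 30L),
    P_trailing  = list(c(0L, 30L), 30L),
    P_censor365 = list(c(0L, 90L, 180L, 270L, 355L), 90L),
    P_y2019     = list(monthly, 30L),
    P_prior_a10 = list(monthly, 30L),
    P_short     = list(seq(0L, 180L, 30L), 30L),
    P_combo     = list(monthly, 30L),
    P_fdc       = list(monthly, 30L),
    P_single    = list(0L, 30L),
    P_fewvisits = list(monthly, 30L)
  )
  rx <- do.call(rbind, lapply(ids, function(id) {
    f <- fills[[id]]
    data.frame(patient_id = id,
               rx_date = as.Date(index_of[id] + f[[1L]], origin = "1970-01-01"),
               atc_code = "A10PA01", days_supply = f[[2L]],
               fdc_flag = id == "P_fdc" & f[[1L]] == 0L,
               stringsAsFactors = FALSE)
  }))
  other <- data.frame(
    patient_id = c("P_switch", "P_prior_a10", "P_combo"),
    rx_date = as.Date(index_of[c("P_switch", "P_prior_a10", "P_combo")] +
                        c(40L, -90L, 0L), origin = "1970-01-01"),
    atc_code = c("A10BB01", "A10BA02", "A10BB01"),
    days_supply = c(30L, 30L, 30L), fdc_flag = FALSE, stringsAsFactors = FALSE)
  conc <- data.frame(
    patient_id = c("P_persist", "P_persist", "P_y2019"),
    rx_date = as.Date(index_of[c("P_persist", "P_persist", "P_y2019")] +
                        c(-60L, -60L, -90L), origin = "1970-01-01"),
    atc_code = c("C09AA05", "C10AA07", "C08CA01"),
    days_supply = 30L, fdc_flag = FALSE, stringsAsFactors = FALSE)
  prescriptions <- rbind(rx, other, conc)

  dx1 <- data.frame(  # everyone carries uncomplicated T2DM
    patient_id = ids,
    dx_date = as.Date(index_of - 100L, origin = "1970-01-01"),
    icd10_code = "E119", suspected_flag = FALSE, stringsAsFactors = FALSE)
  dx2 <- data.frame(
    patient_id = c("P_persist", "P_persist", "P_gap60", "P_switch",
                   "P_trailing", "P_censor365", "P_y2019", "P_gap100"),
    dx_date = as.Date(index_of[c("P_persist", "P_persist", "P_gap60", "P_switch",
                                 "P_trailing", "P_censor365", "P_y2019", "P_gap100")] +
                        c(-30L, -50L, -20L, -10L, -90L, -70L, -40L, -200L),
                      origin = "1970-01-01"),
    icd10_code = c("I10", "E780", "E790", "E112", "F329", "E669", "E782", "E790"),
    suspected_flag = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  diagnoses <- rbind(dx1, dx2)

  vis_days <- list(default = c(-150L, -90L, -30L),
                   P_gap100 = c(-170L, -10L),
                   P_gap60 = c(-120L, -60L),
                   P_trailing = c(-80L, -40L, -40L),  # duplicate same-day claims
                   P_fewvisits = -30L)
  visits <- do.call(rbind, lapply(ids, function(id) {
    d <- vis_days[[id]] %||% vis_days$default
    data.frame(patient_id = id,
               visit_date = as.Date(index_of[id] + c(d, 0L), origin = "1970-01-01"),
               stringsAsFactors = FALSE)
  }))

  bundle <- claims_bundle(enrollment, prescriptions, diagnoses, visits)

  expected <- data.frame(
    patient_id = ids,
    in_cohort = c(rep(TRUE, 7L), rep(FALSE, 6L)),
    drop_stage = c(rep(NA_character_, 7L),
                   "prior_antidiabetic", "insufficient_enrollment",
                   "combination_at_index", "fixed_dose_combination_at_index",
                   "single_sglt2i_prescription", "fewer_than_two_visits"),
    reason_90 = c("none", "gap", "none", "switch", "gap", "none", "none",
                  rep(NA, 6L)),
    persistence_90 = c(365L, 30L, 365L, 40L, 60L, 365L, 365L, rep(NA, 6L)),
    restarted_90 = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, rep(NA, 6L)),
    reason_30 = c("gap", "gap", "gap", "switch", "gap", "gap", "none",
                  rep(NA, 6L)),
    persistence_30 = c(360L, 30L, 30L, 40L, 60L, 90L, 365L, rep(NA, 6L)),
    restarted_30 = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, rep(NA, 6L)),
    covered_days = c(360L, 60L, 335L, 60L, 60L, 365L, 365L, rep(NA, 6L)),
    stringsAsFactors = FALSE)
  rownames(expected) <- NULL
  list(bundle = bundle, expected = expected)
}
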