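#' Configuration for the synthetic claims generator
#'
#' Defaults describe the study conditions emulated by the generator: a
#' three-year employee-insurance observation window, new users of SGLT2i
#' monotherapy with a mean age of 51.9 (SD 9.1) years and 73.4% male,
#' baseline comorbidity prevalences of 61.1% hypertension, 65.1%
#' dyslipidemia, 8.5% depression, 5.7% obesity, 21.4% hyperuricemia and
#' 7.8% diabetic nephropathy, concomitant cardiovascular/lipid drug classes
#' at 44.8/12.9/29.9/9.4/48.3%, a refill cadence driven by the dispensed
#' days of supply (median 30 days), and a per-day baseline discontinuation
#' hazard with planted covariate effects on the log-odds of the 365-day
#' discontinuation indicator.
#'
#' @param n_patients number of simulated patients.
#' @param seed RNG seed; identical config + seed gives identical output.
#' @param obs_start,obs_end database observation window.
#' @param frac_new_users probability a patient is a treatment-naive SGLT2i
#'   initiator; the remainder are prevalent antidiabetic users who fail the
#'   washout.
#' @param supply_probs named probabilities over days of supply
#'   (names "14", "30", "60", "90").
#' @param refill_jitter_sd SD (days) of the refill-timing jitter; jitter is
#'   centred at -2 days and capped at 0 so refills occur on or before
#'   supply exhaustion, never after (early refills deliberately create
#'   overlapping supply).
#' @param discontinuation_hazard per-day baseline hazard; sets both the
#'   baseline 365-day discontinuation probability
#'   `p0 = 1 - exp(-365 * hazard)` and the shape of the event-day
#'   distribution.
#' @param switch_prob probability a patient adds a second antidiabetic
#'   agent (combination initiation) during follow-up.
#' @param restart_prob probability a gap discontinuer later restarts.
#' @param covariate_log_odds named vector of planted log-odds effects on
#'   the discontinuation indicator; names are covariate columns
#'   (`hypertension`, `dyslipidemia`, ..., `sex_male`) or `age_per_year`
#'   (applied to age centred at `age_mean`).
#' @param comorbidity_prevalence,concomitant_prevalence named prevalence
#'   vectors.
#' @param age_mean,age_sd,age_range age distribution (normal, truncated).
#' @param male_frac proportion male.
#' @param visit_mean mean pre-index outpatient visit count (Poisson).
#' @param suspected_dx_prob probability of an extra *suspected* (ignored)
#'   diagnosis claim per patient.
#' @param extra_dx_prob named probabilities of additional chronic-disease
#'   diagnoses that feed only the Charlson index.
#' @param combo_at_index_prob probability a new user starts combination
#'   therapy on the index date (a cohort exclusion branch).
#' @param fdc_at_index_prob probability the index product is a fixed-dose
#'   combination tablet (a cohort exclusion branch).
#' @param short_enrollment_prob probability enrollment ends before the
#'   post-index window completes (a cohort exclusion branch).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 1000L,
                       seed = 1L,
                       obs_start = as.Date("2017-10-01"),
                       obs_end = as.Date("2020-09-30"),
                       frac_new_users = 0.92,
                       supply_probs = c("14" = 0.10, "30" = 0.75, "60" = 0.10, "90" = 0.05),
                       refill_jitter_sd = 2,
                       discontinuation_hazard = 0.0016,
                       switch_prob = 0.08,
                       restart_prob = 0.454,
                       covariate_log_odds = c(age_per_year = -0.033,
                                              hypertension = -0.33,
                                              dyslipidemia = -0.30,
                                              hyperuricemia = -0.28),
                       comorbidity_prevalence = c(hypertension = 0.611,
                                                  dyslipidemia = 0.651,
                                                  depression = 0.085,
                                                  obesity = 0.057,
                                                  hyperuricemia = 0.214,
                                                  nephropathy = 0.078),
                       concomitant_prevalence = c(ras_agents = 0.448,
                                                  beta_blockers = 0.129,
                                                  ccb = 0.299,
                                                  diuretics = 0.094,
                                                  lipid_lowering = 0.483),
                       age_mean = 51.9, age_sd = 9.1, age_range = c(20.5, 72),
                       male_frac = 0.734,
                       visit_mean = 6.2,
                       suspected_dx_prob = 0.05,
                       extra_dx_prob = c(J449 = 0.04, K760 = 0.06, I219 = 0.015),
                       combo_at_index_prob = 0.03,
                       fdc_at_index_prob = 0.02,
                       short_enrollment_prob = 0.02) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              obs_start = as.Date(obs_start), obs_end = as.Date(obs_end),
              frac_new_users = frac_new_users, supply_probs = supply_probs,
              refill_jitter_sd = refill_jitter_sd,
              discontinuation_hazard = discontinuation_hazard,
              switch_prob = switch_prob, restart_prob = restart_prob,
              covariate_log_odds = covariate_log_odds,
              comorbidity_prevalence = comorbidity_prevalence,
              concomitant_prevalence = concomitant_prevalence,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              male_frac = male_frac, visit_mean = visit_mean,
              suspected_dx_prob = suspected_dx_prob,
              extra_dx_prob = extra_dx_prob,
              combo_at_index_prob = combo_at_index_prob,
              fdc_at_index_prob = fdc_at_index_prob,
              short_enrollment_prob = short_enrollment_prob)
  probs <- c(cfg$frac_new_users, cfg$switch_prob, cfg$restart_prob,
             cfg$comorbidity_prevalence, cfg$concomitant_prevalence,
             cfg$male_frac, cfg$suspected_dx_prob, cfg$extra_dx_prob,
             cfg$combo_at_index_prob, cfg$fdc_at_index_prob,
             cfg$short_enrollment_prob, cfg$supply_probs)
  if (any(probs < 0 | probs > 1)) stop("sim_config: probabilities must lie in [0, 1]")
  if (cfg$discontinuation_hazard < 0) stop("sim_config: hazard must be >= 0")
  if (cfg$n_patients < 0L) stop("sim_config: n_patients must be >= 0")
  if (abs(sum(cfg$supply_probs) - 1) > 1e-8) stop("sim_config: supply_probs must sum to 1")
  if (cfg$obs_start > cfg$obs_end) stop("sim_config: obs_start after obs_end")
  class(cfg) <- "sim_config"
  cfg
}

# ICD-10 codes emitted per comorbidity (conventional assignment)
sim_comorbidity_codes <- list(
  hypertension  = "I10",
  dyslipidemia  = c("E780", "E782", "E785"),
  depression    = c("F329", "F331"),
  obesity       = c("E66", "E669"),
  hyperuricemia = "E790",
  nephropathy   = c("E112", "N083", "N189", "E142")
)

sim_concomitant_codes <- c(ras_agents = "C09AA05", beta_blockers = "C07AB02",
                           ccb = "C08CA01", diuretics = "C03CA01",
                           lipid_lowering = "C10AA07")

#' Generate a synthetic claims bundle with known ground truth
#'
#' Simulates a claims database population under the conditions described in
#' [sim_config()]. Each new user receives an index SGLT2i fill with at
#' least 180 days of enrollment before and 365 after it; refills follow
#' the previous fill plus days of supply plus (non-positive) jitter. The
#' 365-day discontinuation indicator is Bernoulli with
#' `logit(p) = logit(1 - exp(-365 h)) + sum(planted log-odds effects)`;
#' given an event the stop day is drawn from the hazard's truncated
#' exponential, restricted to days 1-260 so the simulated event is always
#' observable under the 90-day-gap measurement rule. Discontinuers restart
#' with the configured probability (after a gap of more than 90 days), and
#' switchers receive a second antidiabetic agent mid-follow-up. Pre-index
#' comorbidity diagnoses, the type 2 diabetes code, concomitant drug fills
#' and outpatient visits are emitted at the configured prevalences.
#'
#' @param config a [sim_config()].
#' @return list with `bundle` (a validated [claims_bundle()]) and `truth`
#'   (data frame: per-patient planted covariates,
#'   `true_discontinuation_day`, `true_restarter`, `true_switch_day`,
#'   `role`).
#' @export
simulate_claims <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  if (n == 0L) {
    empty <- claims_bundle(
      data.frame(patient_id = character(), birth_ym = as.Date(character()),
                 sex = character(), obs_start = as.Date(character()),
                 obs_end = as.Date(character()), stringsAsFactors = FALSE),
      data.frame(patient_id = character(), rx_date = as.Date(character()),
                 atc_code = character(), days_supply = integer(),
                 fdc_flag = logical(), stringsAsFactors = FALSE),
      data.frame(patient_id = character(), dx_date = as.Date(character()),
                 icd10_code = character(), suspected_flag = logical(),
                 stringsAsFactors = FALSE),
      data.frame(patient_id = character(), visit_date = as.Date(character()),
                 stringsAsFactors = FALSE))
    return(list(bundle = empty, truth = data.frame(patient_id = character())))
  }
  ids <- sprintf("P%06d", seq_len(n))

  ## patient attributes -----------------------------------------------------
  sex <- ifelse(stats::runif(n) < config$male_frac, "male", "female")
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  # index date uniform over the dates admitting full pre/post windows
  idx_lo <- as.integer(config$obs_start) + 180L
  idx_hi <- as.integer(config$obs_end) - 365L
  if (idx_hi < idx_lo) stop("simulate_claims: observation window too short for the study windows")
  index_abs <- idx_lo + sample.int(idx_hi - idx_lo + 1L, n, replace = TRUE) - 1L
  index_date <- as.Date(index_abs, origin = "1970-01-01")
  supply <- as.integer(sample(names(config$supply_probs), n, replace = TRUE,
                              prob = config$supply_probs))

  draw_flags <- function(prev) {
    m <- matrix(FALSE, n, length(prev), dimnames = list(NULL, names(prev)))
    for (nm in names(prev)) m[, nm] <- stats::runif(n) < prev[[nm]]
    m
  }
  comorb <- draw_flags(config$comorbidity_prevalence)
  conc <- draw_flags(config$concomitant_prevalence)

  role <- rep("new_user", n)
  u <- stats::runif(n)
  role[u >= config$frac_new_users] <- "prevalent_user"
  br <- stats::runif(n)
  is_new <- role == "new_user"
  role[is_new & br < config$combo_at_index_prob] <- "combo_at_index"
  role[is_new & br >= config$combo_at_index_prob &
         br < config$combo_at_index_prob + config$fdc_at_index_prob] <- "fdc_at_index"
  role[is_new & br >= config$combo_at_index_prob + config$fdc_at_index_prob &
         br < config$combo_at_index_prob + config$fdc_at_index_prob +
             config$short_enrollment_prob] <- "short_enrollment"

  ## planted discontinuation ------------------------------------------------
  h <- config$discontinuation_hazard
  p0 <- 1 - exp(-365 * h)
  lp <- rep(0, n)
  eff <- config$covariate_log_odds
  for (nm in names(eff)) {
    lp <- lp + eff[[nm]] * switch(nm,
      age_per_year = age - config$age_mean,
      sex_male = as.numeric(sex == "male"),
      {
        if (!nm %in% colnames(comorb)) {
          stop("sim_config: planted effect for unknown covariate: ", nm)
        }
        as.numeric(comorb[, nm])
      })
  }
  p_disc <- stats::plogis(stats::qlogis(p0) + lp)
  disc_event <- stats::runif(n) < p_disc
  # event day: hazard-shaped, truncated to the observable range
  trunc_day <- 260
  uu <- stats::runif(n)
  raw_day <- if (h > 0) -log(1 - uu * (1 - exp(-h * trunc_day))) / h else uu * trunc_day
  disc_day <- ifelse(disc_event, pmax(1L, as.integer(floor(raw_day))), NA_integer_)

  restarter <- disc_event & stats::runif(n) < config$restart_prob
  switcher <- stats::runif(n) < config$switch_prob
  switch_day <- ifelse(switcher, 30L + as.integer(floor(stats::runif(n) * 270)), NA_integer_)

  ## enrollment -------------------------------------------------------------
  obs_start <- rep(config$obs_start, n)
  obs_end <- rep(config$obs_end, n)
  short <- role == "short_enrollment"
  obs_end[short] <- index_date[short] + 30L + as.integer(floor(stats::runif(sum(short)) * 270))
  birth <- index_date - as.integer(round(age * 365.25))
  # store birth at month resolution with the imputed day 15
  birth_ym <- as.Date(paste0(format(birth, "%Y-%m"), "-15"))
  enrollment <- data.frame(patient_id = ids, birth_ym = birth_ym, sex = sex,
                           obs_start = obs_start, obs_end = obs_end,
                           stringsAsFactors = FALSE)

  ## SGLT2i refill schedules ------------------------------------------------
  max_fills <- as.integer(ceiling(365 / min(supply))) + 2L
  fill_day <- matrix(NA_integer_, n, max_fills)
  fill_day[, 1L] <- 0L
  for (k in 2L:max_fills) {
    jit <- pmin(pmax(as.integer(round(stats::rnorm(n, -2, config$refill_jitter_sd))), -7L), 0L)
    cand <- fill_day[, k - 1L] + supply + jit
    cand[cand >= 365L] <- NA_integer_
    fill_day[, k] <- cand
  }
  # stop refilling at the planted stop day
  stop_day <- ifelse(is.na(disc_day), 366L, disc_day)
  fill_day[, -1L][sweep(fill_day[, -1L, drop = FALSE], 1L, stop_day, ">=")] <- NA_integer_
  last_fill <- apply(fill_day, 1L, function(r) max(r, na.rm = TRUE))

  # restart fills: resume after a gap of > 90 days from the last fill
  restart_start <- last_fill + 91L + as.integer(floor(stats::runif(n) * 120))
  feasible <- restarter & restart_start < 360L
  restarter <- feasible
  restart_mat <- matrix(NA_integer_, n, 8L)
  restart_mat[feasible, 1L] <- restart_start[feasible]
  for (k in 2L:8L) {
    jit <- pmin(pmax(as.integer(round(stats::rnorm(n, -2, config$refill_jitter_sd))), -7L), 0L)
    cand <- restart_mat[, k - 1L] + supply + jit
    cand[cand >= 365L] <- NA_integer_
    restart_mat[, k] <- cand
  }

  sglt_codes <- c("A10PA01", "A10PA02", "A10PA03")
  patient_code <- sample(sglt_codes, n, replace = TRUE)
  fdc <- role == "fdc_at_index"

  all_fills <- cbind(fill_day, restart_mat)
  keep <- !is.na(all_fills)
  rx_row <- row(all_fills)[keep]
  rx_day <- all_fills[keep]
  prescriptions <- data.frame(
    patient_id = ids[rx_row],
    rx_date = as.Date(index_abs[rx_row] + rx_day, origin = "1970-01-01"),
    atc_code = patient_code[rx_row],
    days_supply = supply[rx_row],
    fdc_flag = fdc[rx_row] & rx_day == 0L,
    stringsAsFactors = FALSE)

  ## other antidiabetic fills ----------------------------------------------
  other_code <- "A10BB01"
  extra <- list()
  prev <- role == "prevalent_user"
  if (any(prev)) {
    # metformin before and at the start of follow-up: fails the washout
    extra$prev <- data.frame(
      patient_id = rep(ids[prev], each = 2L),
      rx_date = as.Date(rep(index_abs[prev], each = 2L) + c(-120L, -30L),
                        origin = "1970-01-01"),
      atc_code = "A10BA02", days_supply = 90L, fdc_flag = FALSE,
      stringsAsFactors = FALSE)
  }
  combo <- role == "combo_at_index"
  if (any(combo)) {
    extra$combo <- data.frame(
      patient_id = ids[combo],
      rx_date = as.Date(index_abs[combo], origin = "1970-01-01"),
      atc_code = other_code, days_supply = supply[combo], fdc_flag = FALSE,
      stringsAsFactors = FALSE)
  }
  sw <- switcher & !is.na(switch_day)
  if (any(sw)) {
    extra$switch <- data.frame(
      patient_id = ids[sw],
      rx_date = as.Date(index_abs[sw] + switch_day[sw], origin = "1970-01-01"),
      atc_code = other_code, days_supply = 30L, fdc_flag = FALSE,
      stringsAsFactors = FALSE)
  }

  ## concomitant drug fills --------------------------------------------------
  conc_fills <- lapply(colnames(conc), function(cl) {
    who <- which(conc[, cl])
    if (!length(who)) return(NULL)
    d <- -as.integer(floor(stats::runif(length(who)) * 170)) - 10L
    data.frame(patient_id = ids[who],
               rx_date = as.Date(index_abs[who] + d, origin = "1970-01-01"),
               atc_code = sim_concomitant_codes[[cl]],
               days_supply = 30L, fdc_flag = FALSE, stringsAsFactors = FALSE)
  })
  prescriptions <- do.call(rbind, c(list(prescriptions), extra, conc_fills))

  ## diagnoses ---------------------------------------------------------------
  dx_parts <- lapply(colnames(comorb), function(cm) {
    who <- which(comorb[, cm])
    if (!length(who)) return(NULL)
    codes <- sim_comorbidity_codes[[cm]]
    d <- -as.integer(floor(stats::runif(length(who)) * 170)) - 5L
    data.frame(patient_id = ids[who],
               dx_date = as.Date(index_abs[who] + d, origin = "1970-01-01"),
               icd10_code = sample(codes, length(who), replace = TRUE),
               suspected_flag = FALSE, stringsAsFactors = FALSE)
  })
  # every patient carries the type 2 diabetes diagnosis (uncomplicated code)
  t2dm <- data.frame(patient_id = ids,
                     dx_date = as.Date(index_abs -
                       as.integer(floor(stats::runif(n) * 170)) - 5L,
                       origin = "1970-01-01"),
                     icd10_code = sample(c("E119", "E118", "E116"), n, replace = TRUE),
                     suspected_flag = FALSE, stringsAsFactors = FALSE)
  extra_parts <- lapply(names(config$extra_dx_prob), function(code) {
    who <- which(stats::runif(n) < config$extra_dx_prob[[code]])
    if (!length(who)) return(NULL)
    d <- -as.integer(floor(stats::runif(length(who)) * 170)) - 5L
    data.frame(patient_id = ids[who],
               dx_date = as.Date(index_abs[who] + d, origin = "1970-01-01"),
               icd10_code = code, suspected_flag = FALSE, stringsAsFactors = FALSE)
  })
  susp_who <- which(stats::runif(n) < config$suspected_dx_prob)
  susp <- if (length(susp_who)) {
    data.frame(patient_id = ids[susp_who],
               dx_date = as.Date(index_abs[susp_who] -
                 as.integer(floor(stats::runif(length(susp_who)) * 170)) - 5L,
                 origin = "1970-01-01"),
               icd10_code = "I10", suspected_flag = TRUE, stringsAsFactors = FALSE)
  } else NULL
  diagnoses <- do.call(rbind, c(dx_parts, list(t2dm), extra_parts, list(susp)))

  ## outpatient visits -------------------------------------------------------
  n_vis <- stats::rpois(n, config$visit_mean)
  vis_rows <- rep(seq_len(n), n_vis)
  vis_day <- -as.integer(floor(stats::runif(length(vis_rows)) * 180)) - 1L
  visits <- data.frame(patient_id = ids[vis_rows],
                       visit_date = as.Date(index_abs[vis_rows] + vis_day,
                                            origin = "1970-01-01"),
                       stringsAsFactors = FALSE)
  # plus the index-day visit at which the first prescription is written
  visits <- rbind(visits,
                  data.frame(patient_id = ids, visit_date = index_date,
                             stringsAsFactors = FALSE))

  ## clip to enrollment and assemble -----------------------------------------
  clip <- function(tbl, col) {
    i <- match(tbl$patient_id, ids)
    keep <- tbl[[col]] >= obs_start[i] & tbl[[col]] <= obs_end[i]
    tbl[keep, , drop = FALSE]
  }
  prescriptions <- clip(prescriptions, "rx_date")
  diagnoses <- clip(diagnoses, "dx_date")
  visits <- clip(visits, "visit_date")
  ord <- function(tbl, col) tbl[order(tbl$patient_id, tbl[[col]]), , drop = FALSE]
  bundle <- claims_bundle(enrollment, ord(prescriptions, "rx_date"),
                          ord(diagnoses, "dx_date"), ord(visits, "visit_date"))

  truth <- data.frame(patient_id = ids, role = role, sex = sex,
                      age_years = age, index_date = index_date,
                      days_supply = supply,
                      true_discontinuation_day = disc_day,
                      true_restarter = restarter,
                      true_switch_day = switch_day,
                      stringsAsFactors = FALSE)
  for (cm in colnames(comorb)) truth[[cm]] <- comorb[, cm]
  rownames(truth) <- NULL
  list(bundle = bundle, truth = truth)
}
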