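#' Default comorbidity and concomitant-drug code map
#'
#' ICD-10 prefixes for the six baseline comorbidities and ATC prefixes for
#' the five concomitant drug classes counted at baseline. The comorbidity
#' assignment is the conventional one (hypertension I10, dyslipidemia E78);
#' both domains are overridable, e.g. to reproduce a source that codes them
#' differently.
#'
#' @return a list with elements `comorbidity` (named list of ICD-10 prefix
#'   vectors) and `drug_class` (named list of ATC prefix vectors).
#' @export
default_code_map <- function() {
  list(
    comorbidity = list(
      hypertension  = "I10",
      dyslipidemia  = "E78",
      depression    = c("F32", "F33"),
      obesity       = "E66",
      hyperuricemia = "E790",
      nephropathy   = c("E112", "E142", "N083", "N189")
    ),
    drug_class = list(
      ras_agents       = "C09",
      beta_blockers    = "C07",
      ccb              = "C08",
      diuretics        = "C03",
      lipid_lowering   = "C10"
    )
  )
}

# TRUE where any code starts with any of the prefixes
matches_prefix <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

#' Flag a comorbidity from pre-index diagnoses
#'
#' A comorbidity is present when at least one *non-suspected* diagnosis
#' claim whose ICD-10 code starts with one of the given prefixes falls in
#' the pre-index window `[index - pre_days, index)`. Suspected
#' (tentative/rule-out) diagnoses are excluded to avoid misclassification.
#'
#' @param diagnoses one patient's diagnosis claims (`dx_date`,
#'   `icd10_code`, `suspected_flag`).
#' @param prefixes ICD-10 code prefixes (dots stripped, uppercase).
#' @param index_date the patient's index date.
#' @param pre_days pre-index window length (default 180).
#' @return logical scalar.
#' @export
flag_comorbidity <- function(diagnoses, prefixes, index_date, pre_days = 180L) {
  if (nrow(diagnoses) == 0L) return(FALSE)
  day <- as.integer(as.Date(diagnoses$dx_date)) - as.integer(as.Date(index_date))
  ok <- !diagnoses$suspected_flag & day >= -pre_days & day < 0L
  any(ok & matches_prefix(normalize_icd10(diagnoses$icd10_code), prefixes))
}

#' Count concomitant drug classes at baseline
#'
#' Number of distinct classes among the five counted classes (RAS agents
#' C09, beta blockers C07, calcium channel blockers C08, diuretics C03,
#' lipid-lowering agents C10) with at least one fill in the pre-index
#' window. Fixed-dose combination products count toward every class they
#' match.
#'
#' @param prescriptions one patient's prescription claims.
#' @param index_date index date.
#' @param drug_classes named list of ATC prefix vectors (default the five
#'   classes of [default_code_map()]).
#' @param pre_days pre-index window length.
#' @return integer in `0..length(drug_classes)`.
#' @export
count_concomitant_classes <- function(prescriptions, index_date,
                                      drug_classes = default_code_map()$drug_class,
                                      pre_days = 180L) {
  if (nrow(prescriptions) == 0L) return(0L)
  day <- as.integer(as.Date(prescriptions$rx_date)) - as.integer(as.Date(index_date))
  in_win <- day >= -pre_days & day < 0L
  codes <- toupper(as.character(prescriptions$atc_code[in_win]))
  sum(vapply(drug_classes, function(p) any(matches_prefix(codes, p)), logical(1)))
}

#' Outpatient visit count and mean inter-visit interval at baseline
#'
#' `n_visits` counts every visit claim in the pre-index window (one claim =
#' one visit, so same-day duplicate claims all count); the mean interval is
#' computed over *distinct* sorted visit dates as
#' `(last - first) / (n_distinct - 1)`.
#'
#' @param visits one patient's visit claims (`visit_date`).
#' @param index_date index date.
#' @param pre_days pre-index window length.
#' @return list with `n_visits` (integer) and `mean_interval_days` (double).
#' @export
visit_stats <- function(visits, index_date, pre_days = 180L) {
  day <- as.integer(as.Date(visits$visit_date)) - as.integer(as.Date(index_date))
  day <- day[day >= -pre_days & day < 0L]
  n <- length(day)
  if (n < 2L) {
    stop("visit_stats: fewer than two pre-index visits; ",
         "the cohort exclusion should have removed this patient")
  }
  d <- sort(unique(day))
  if (length(d) == 1L) {
    # all claims on one date: interval over distinct dates is undefined;
    # report 0 (visits n times on the same day)
    return(list(n_visits = n, mean_interval_days = 0))
  }
  list(n_visits = n,
       mean_interval_days = (d[length(d)] - d[1L]) / (length(d) - 1L))
}

#' Charlson comorbidity index category map (ICD-10, Quan 2005 coding)
#'
#' The 17 Charlson categories as ICD-10 code-prefix sets with the original
#' Charlson weights. Hierarchies are handled by [compute_cci()]: diabetes
#' with complications supersedes uncomplicated diabetes, moderate/severe
#' liver disease supersedes mild, and metastatic solid tumour supersedes
#' any malignancy.
#'
#' @return data frame with columns `category`, `weight`, and a list column
#'   `prefixes`.
#' @export
cci_categories <- function() {
  cat <- list(
    myocardial_infarction = list(1L, c("I21", "I22", "I252")),
    congestive_heart_failure = list(1L, c("I099", "I110", "I130", "I132", "I255",
                                          "I420", "I425", "I426", "I427", "I428",
                                          "I429", "I43", "I50", "P290")),
    peripheral_vascular = list(1L, c("I70", "I71", "I731", "I738", "I739", "I771",
                                     "I790", "I792", "K551", "K558", "K559",
                                     "Z958", "Z959")),
    cerebrovascular = list(1L, c("G45", "G46", "H340", "I60", "I61", "I62", "I63",
                                 "I64", "I65", "I66", "I67", "I68", "I69")),
    dementia = list(1L, c("F00", "F01", "F02", "F03", "F051", "G30", "G311")),
    chronic_pulmonary = list(1L, c("I278", "I279", "J40", "J41", "J42", "J43",
                                   "J44", "J45", "J46", "J47", "J60", "J61",
                                   "J62", "J63", "J64", "J65", "J66", "J67",
                                   "J684", "J701", "J703")),
    rheumatic = list(1L, c("M05", "M06", "M315", "M32", "M33", "M34", "M351",
                           "M353", "M360")),
    peptic_ulcer = list(1L, c("K25", "K26", "K27", "K28")),
    mild_liver = list(1L, c("B18", "K700", "K701", "K702", "K703", "K709",
                            "K713", "K714", "K715", "K717", "K73", "K74",
                            "K760", "K762", "K763", "K764", "K768", "K769",
                            "Z944")),
    diabetes_uncomplicated = list(1L, c("E100", "E101", "E106", "E108", "E109",
                                        "E110", "E111", "E116", "E118", "E119",
                                        "E120", "E121", "E126", "E128", "E129",
                                        "E130", "E131", "E136", "E138", "E139",
                                        "E140", "E141", "E146", "E148", "E149")),
    diabetes_complicated = list(2L, c("E102", "E103", "E104", "E105", "E107",
                                      "E112", "E113", "E114", "E115", "E117",
                                      "E122", "E123", "E124", "E125", "E127",
                                      "E132", "E133", "E134", "E135", "E137",
                                      "E142", "E143", "E144", "E145", "E147")),
    hemiplegia_paraplegia = list(2L, c("G041", "G114", "G801", "G802", "G81",
                                       "G82", "G830", "G831", "G832", "G833",
                                       "G834", "G839")),
    renal = list(2L, c("I120", "I131", "N032", "N033", "N034", "N035", "N036",
                       "N037", "N052", "N053", "N054", "N055", "N056", "N057",
                       "N18", "N19", "N250", "Z490", "Z491", "Z492", "Z940",
                       "Z992")),
    any_malignancy = list(2L, c(paste0("C0", 0:9), paste0("C1", 0:9),
                                paste0("C2", 0:6), "C30", "C31", "C32", "C33",
                                "C34", "C37", "C38", "C39", "C40", "C41", "C43",
                                paste0("C4", 5:9), paste0("C5", 0:8),
                                paste0("C6", 0:9), paste0("C7", 0:6),
                                "C81", "C82", "C83", "C84", "C85", "C88",
                                paste0("C9", 0:7))),
    moderate_severe_liver = list(3L, c("I850", "I859", "I864", "I982", "K704",
                                       "K711", "K721", "K729", "K765", "K766",
                                       "K767")),
    metastatic_solid_tumour = list(6L, c("C77", "C78", "C79", "C80")),
    aids_hiv = list(6L, c("B20", "B21", "B22", "B24"))
  )
  data.frame(category = names(cat),
             weight = vapply(cat, function(x) x[[1L]], integer(1)),
             prefixes = I(lapply(cat, function(x) x[[2L]])),
             stringsAsFactors = FALSE)
}

#' Charlson comorbidity index from pre-index diagnoses
#'
#' Sum of original Charlson weights over the distinct categories present
#' among a patient's non-suspected pre-index diagnoses, using the
#' [cci_categories()] ICD-10 mapping. Within each severity hierarchy only
#' the more severe category is counted.
#'
#' @inheritParams flag_comorbidity
#' @param categories the category map (default [cci_categories()]).
#' @return non-negative integer score.
#' @export
compute_cci <- function(diagnoses, index_date, pre_days = 180L,
                        categories = cci_categories()) {
  if (nrow(diagnoses) == 0L) return(0L)
  day <- as.integer(as.Date(diagnoses$dx_date)) - as.integer(as.Date(index_date))
  ok <- !diagnoses$suspected_flag & day >= -pre_days & day < 0L
  codes <- normalize_icd10(diagnoses$icd10_code[ok])
  if (!length(codes)) return(0L)
  present <- vapply(categories$prefixes,
                    function(p) any(matches_prefix(codes, p)), logical(1))
  names(present) <- categories$category
  # severity hierarchies: count the graver member only
  if (present["diabetes_complicated"]) present["diabetes_uncomplicated"] <- FALSE
  if (present["moderate_severe_liver"]) present["mild_liver"] <- FALSE
  if (present["metastatic_solid_tumour"]) present["any_malignancy"] <- FALSE
  sum(categories$weight[present])
}

#' Baseline covariates for every cohort member
#'
#' Derives the baseline covariate vector from the 180-day pre-index window:
#' calendar year at index (as the 2018 indicator used in the factor
#' models), sex, fractional age at index, outpatient visit count and mean
#' inter-visit interval, number of concomitant drug classes, the six
#' comorbidity flags, and the Charlson comorbidity index. Only calendar
#' year, age and sex are index-date attributes; everything else is
#' measured strictly before the index date.
#'
#' @param cohort cohort data frame from [build_cohort()].
#' @param bundle the [claims_bundle()].
#' @param code_map code map as from [default_code_map()].
#' @param pre_days pre-index window length.
#' @return data frame with one row per cohort member.
#' @export
build_covariates <- function(cohort, bundle, code_map = default_code_map(),
                             pre_days = 180L) {
  stopifnot(inherits(bundle, "claims_bundle"))
  n <- nrow(cohort)
  comorb_names <- names(code_map$comorbidity)
  out <- data.frame(
    patient_id = cohort$patient_id,
    calendar_year_2018 = cohort$calendar_year == 2018L,
    sex_male = cohort$sex == "male",
    age_years = cohort$age_at_index,
    n_visits = integer(n),
    mean_visit_interval_days = numeric(n),
    n_concomitant_classes = integer(n),
    stringsAsFactors = FALSE)
  for (cm in comorb_names) out[[cm]] <- logical(n)
  out$cci <- integer(n)
  if (n == 0L) return(out)

  idx <- as.integer(cohort$index_date)

  # comorbidity flags and CCI from non-suspected pre-index diagnoses
  dx <- bundle$diagnoses
  dm <- match(dx$patient_id, cohort$patient_id)
  dday <- as.integer(dx$dx_date) - idx[dm]
  dkeep <- which(!is.na(dm) & !dx$suspected_flag & dday >= -pre_days & dday < 0L)
  dcodes <- normalize_icd10(dx$icd10_code[dkeep])
  dwho <- dm[dkeep]
  for (cm in comorb_names) {
    hit <- matches_prefix(dcodes, code_map$comorbidity[[cm]])
    flag <- logical(n); flag[dwho[hit]] <- TRUE
    out[[cm]] <- flag
  }
  categories <- cci_categories()
  pres <- matrix(FALSE, n, nrow(categories),
                 dimnames = list(NULL, categories$category))
  for (k in seq_len(nrow(categories))) {
    hit <- matches_prefix(dcodes, categories$prefixes[[k]])
    pres[dwho[hit], k] <- TRUE
  }
  pres[pres[, "diabetes_complicated"], "diabetes_uncomplicated"] <- FALSE
  pres[pres[, "moderate_severe_liver"], "mild_liver"] <- FALSE
  pres[pres[, "metastatic_solid_tumour"], "any_malignancy"] <- FALSE
  out$cci <- as.integer(pres %*% categories$weight)

  # concomitant drug classes from pre-index fills
  rx <- bundle$prescriptions
  rm_ <- match(rx$patient_id, cohort$patient_id)
  rday <- as.integer(rx$rx_date) - idx[rm_]
  rkeep <- which(!is.na(rm_) & rday >= -pre_days & rday < 0L)
  rcodes <- toupper(rx$atc_code[rkeep])
  rwho <- rm_[rkeep]
  n_classes <- integer(n)
  for (cl in names(code_map$drug_class)) {
    hit <- matches_prefix(rcodes, code_map$drug_class[[cl]])
    got <- logical(n); got[rwho[hit]] <- TRUE
    n_classes <- n_classes + got
  }
  out$n_concomitant_classes <- n_classes

  # visit count (all claims) and mean interval (distinct dates)
  vis <- bundle$visits
  vm <- match(vis$patient_id, cohort$patient_id)
  vday <- as.integer(vis$visit_date) - idx[vm]
  vkeep <- which(!is.na(vm) & vday >= -pre_days & vday < 0L)
  vwho <- vm[vkeep]; vd <- vday[vkeep]
  out$n_visits <- tabulate(vwho, nbins = n)
  if (any(out$n_visits < 2L)) {
    stop("build_covariates: patient(s) with fewer than two pre-index visits ",
         "(the cohort exclusion should have removed them): ",
         row_list(which(out$n_visits < 2L)))
  }
  dup <- duplicated(vwho * (pre_days + 1L) + (vd + pre_days))
  dwho2 <- vwho[!dup]; dd2 <- vd[!dup]
  f <- factor(dwho2, levels = seq_len(n))
  n_dist <- tabulate(dwho2, nbins = n)
  first <- as.numeric(tapply(dd2, f, min))
  last <- as.numeric(tapply(dd2, f, max))
  out$mean_visit_interval_days <- ifelse(n_dist > 1L, (last - first) / (n_dist - 1L), 0)
  out
}
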