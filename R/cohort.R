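#' Identify new users of SGLT2i monotherapy candidates
#'
#' Scans each patient's SGLT2 inhibitor (ATC prefix `A10P`) prescriptions in
#' date order and takes as index date the first fill for which (i) the
#' 180-day pre-index window `[index - 180, index)` contains no antidiabetic
#' (ATC prefix `A10`) prescription of any kind, and (ii) enrollment covers
#' the full pre-index and post-index windows `[index - 180, index + 365)`.
#' Patients with no qualifying fill are dropped, with the reason recorded.
#'
#' @param bundle a validated [claims_bundle()].
#' @param pre_days washout / covariate window length in days (default 180).
#' @param post_days follow-up window length in days (default 365).
#' @return a list with `candidates` (data frame: `patient_id`, `index_date`)
#'   and `excluded` (data frame: `patient_id`, `reason` in
#'   `no_sglt2i` / `prior_antidiabetic` / `insufficient_enrollment`).
#' @export
identify_new_users <- function(bundle, pre_days = 180L, post_days = 365L) {
  stopifnot(inherits(bundle, "claims_bundle"))
  enr <- bundle$enrollment
  rx <- bundle$prescriptions
  a10 <- rx[is_antidiabetic(rx$atc_code), , drop = FALSE]

  a10_by_pat <- split(as.integer(a10$rx_date), a10$patient_id)
  sglt_flag <- split(is_sglt2i(a10$atc_code), a10$patient_id)

  ids <- enr$patient_id
  index_date <- rep(as.Date(NA), length(ids))
  reason <- character(length(ids))
  for (i in seq_along(ids)) {
    dates <- a10_by_pat[[ids[i]]]
    if (is.null(dates)) { reason[i] <- "no_sglt2i"; next }
    sgl <- sglt_flag[[ids[i]]]
    ord <- order(dates)
    dates <- dates[ord]; sgl <- sgl[ord]
    cand <- sort(unique(dates[sgl]))
    if (!length(cand)) { reason[i] <- "no_sglt2i"; next }
    s <- as.integer(enr$obs_start[i]); e <- as.integer(enr$obs_end[i])
    found <- FALSE
    first_reason <- NA_character_
    for (d in cand) {
      fail <- if (any(dates >= d - pre_days & dates < d)) {
        "prior_antidiabetic"
      } else if (d - pre_days < s || d + post_days - 1L > e) {
        "insufficient_enrollment"
      } else NA_character_
      if (is.na(fail)) {
        index_date[i] <- as.Date(d, origin = "1970-01-01")
        found <- TRUE
        break
      }
      if (is.na(first_reason)) first_reason <- fail
    }
    if (!found) reason[i] <- first_reason
  }
  keep <- !is.na(index_date)
  list(candidates = data.frame(patient_id = ids[keep],
                               index_date = index_date[keep],
                               stringsAsFactors = FALSE),
       excluded = data.frame(patient_id = ids[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Apply the monotherapy exclusion cascade
#'
#' Sequentially excludes candidates who (1) have a prescription claim with a
#' missing date (data-quality stage; empty after reader validation),
#' (2) have only one SGLT2i prescription in the 365-day post-index window,
#' (3) start combination therapy — another antidiabetic agent prescribed on
#' the index date, (4) start on a fixed-dose combination SGLT2i tablet at
#' the index date, or (5) have fewer than two outpatient visits in the
#' 180-day pre-index window. Violation flags are computed independently of
#' order, so the *set* of excluded patients does not depend on the stage
#' sequence; the per-stage counts attribute each patient to the first stage
#' they violate.
#'
#' @param candidates data frame from [identify_new_users()] (`patient_id`,
#'   `index_date`).
#' @param bundle the [claims_bundle()].
#' @param pre_days,post_days window lengths in days.
#' @return a list with `cohort` (data frame of cohort records: `patient_id`,
#'   `index_date`, `calendar_year`, `age_at_index`, `sex`) and `flow`
#'   (a `flow_counts` data frame: `stage`, `n_excluded`, `n_remaining`, with
#'   the combined combination+fixed-dose count in
#'   `attr(., "combination_total")` for comparability with flow charts that
#'   pool the two).
#' @export
apply_exclusions <- function(candidates, bundle, pre_days = 180L, post_days = 365L) {
  stopifnot(inherits(bundle, "claims_bundle"))
  n0 <- nrow(candidates)
  rx <- bundle$prescriptions
  vis <- bundle$visits

  if (n0 == 0L) {
    flow <- flow_counts(data.frame(
      stage = c("candidates", "missing_rx_date", "single_sglt2i_prescription",
                "combination_at_index", "fixed_dose_combination_at_index",
                "fewer_than_two_visits", "final_cohort"),
      n_excluded = 0L, n_remaining = 0L, stringsAsFactors = FALSE))
    attr(flow, "combination_total") <- 0L
    return(list(cohort = empty_cohort(), flow = flow))
  }

  idx <- as.integer(candidates$index_date)
  pid <- candidates$patient_id

  rx_pat <- match(rx$patient_id, pid)
  in_scope <- !is.na(rx_pat)
  rxs <- rx[in_scope, , drop = FALSE]
  rxs_idx <- idx[rx_pat[in_scope]]
  day <- as.integer(rxs$rx_date) - rxs_idx
  sgl <- is_sglt2i(rxs$atc_code)
  a10 <- is_antidiabetic(rxs$atc_code)

  # violation flags, computed for every candidate before any exclusion
  viol_missing <- tabulate_flag(rxs$patient_id[is.na(rxs$rx_date)], pid)
  n_sglt_post <- tabulate_count(rxs$patient_id[sgl & day >= 0L & day < post_days], pid)
  viol_single <- n_sglt_post == 1L
  viol_combo <- tabulate_flag(rxs$patient_id[a10 & !sgl & day == 0L], pid)
  viol_fdc <- tabulate_flag(rxs$patient_id[sgl & rxs$fdc_flag & day == 0L], pid)
  vis_pat <- match(vis$patient_id, pid)
  vin <- !is.na(vis_pat)
  vday <- as.integer(vis$visit_date[vin]) - idx[vis_pat[vin]]
  n_vis_pre <- tabulate_count(vis$patient_id[vin][vday >= -pre_days & vday < 0L], pid)
  viol_visits <- n_vis_pre < 2L

  stages <- list(missing_rx_date = viol_missing,
                 single_sglt2i_prescription = viol_single,
                 combination_at_index = viol_combo,
                 fixed_dose_combination_at_index = viol_fdc,
                 fewer_than_two_visits = viol_visits)
  alive <- rep(TRUE, n0)
  rows <- data.frame(stage = "candidates", n_excluded = 0L, n_remaining = n0,
                     stringsAsFactors = FALSE)
  for (s in names(stages)) {
    drop <- alive & stages[[s]]
    alive <- alive & !drop
    rows <- rbind(rows, data.frame(stage = s, n_excluded = sum(drop),
                                   n_remaining = sum(alive), stringsAsFactors = FALSE))
  }
  rows <- rbind(rows, data.frame(stage = "final_cohort", n_excluded = 0L,
                                 n_remaining = sum(alive), stringsAsFactors = FALSE))
  flow <- flow_counts(rows)
  attr(flow, "combination_total") <-
    rows$n_excluded[rows$stage == "combination_at_index"] +
    rows$n_excluded[rows$stage == "fixed_dose_combination_at_index"]
  attr(flow, "excluded_ids") <- pid[!alive]

  enr <- bundle$enrollment[match(pid[alive], bundle$enrollment$patient_id), , drop = FALSE]
  idx_d <- candidates$index_date[alive]
  cohort <- data.frame(
    patient_id = pid[alive],
    index_date = idx_d,
    calendar_year = as.integer(format(idx_d, "%Y")),
    age_at_index = as.numeric(idx_d - enr$birth_ym) / 365.25,
    sex = enr$sex,
    stringsAsFactors = FALSE)
  rownames(cohort) <- NULL
  list(cohort = cohort, flow = flow)
}

empty_cohort <- function() {
  data.frame(patient_id = character(), index_date = as.Date(character()),
             calendar_year = integer(), age_at_index = numeric(),
             sex = character(), stringsAsFactors = FALSE)
}

tabulate_flag <- function(ids, universe) {
  universe %in% unique(ids)
}

tabulate_count <- function(ids, universe) {
  tab <- table(factor(ids, levels = universe))
  as.integer(tab)
}

#' Flow counts for the selection cascade
#'
#' Validates the stage-arithmetic invariant of a selection flow chart:
#' each stage's `n_remaining` equals the previous `n_remaining` minus that
#' stage's `n_excluded`, and all counts are non-negative.
#'
#' @param x data frame with columns `stage`, `n_excluded`, `n_remaining`.
#' @return `x` with class `flow_counts`.
#' @export
flow_counts <- function(x) {
  x <- check_columns(x, "flow_counts", c("stage", "n_excluded", "n_remaining"))
  x$n_excluded <- as.integer(x$n_excluded)
  x$n_remaining <- as.integer(x$n_remaining)
  if (any(x$n_excluded < 0L) || any(x$n_remaining < 0L)) {
    stop("flow_counts: negative counts")
  }
  if (nrow(x) > 1L) {
    prev <- x$n_remaining[-nrow(x)]
    ok <- x$n_remaining[-1L] == prev - x$n_excluded[-1L]
    if (!all(ok)) {
      stop("flow_counts: stage arithmetic violated at stage(s): ",
           paste(x$stage[-1L][!ok], collapse = ", "))
    }
  }
  class(x) <- c("flow_counts", "data.frame")
  x
}

#' @export
print.flow_counts <- function(x, ...) {
  cat("<flow_counts>\n")
  print.data.frame(x, row.names = FALSE)
  ct <- attr(x, "combination_total")
  if (!is.null(ct)) cat("combination + fixed-dose combined:", ct, "\n")
  invisible(x)
}

#' Build the analytic cohort from a claims bundle
#'
#' Convenience wrapper: [identify_new_users()] followed by
#' [apply_exclusions()], with the candidate-identification drop reasons
#' prepended to the flow.
#'
#' @inheritParams identify_new_users
#' @return list with `cohort` and `flow` as in [apply_exclusions()], plus
#'   `candidate_exclusions` (the pre-candidacy drop reasons).
#' @export
build_cohort <- function(bundle, pre_days = 180L, post_days = 365L) {
  nu <- identify_new_users(bundle, pre_days = pre_days, post_days = post_days)
  res <- apply_exclusions(nu$candidates, bundle, pre_days = pre_days, post_days = post_days)
  res$candidate_exclusions <- nu$excluded
  res
}
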