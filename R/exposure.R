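#' Gap policy for persistence measurement
#'
#' The permissible gap is the longest allowed interval between two
#' consecutive prescription dates before a discontinuation event is
#' declared (90 days primary; 30 days — the median days of supply — as the
#' sensitivity policy). The comparison is strict by default: a gap of
#' exactly `permissible_gap` days is allowed.
#'
#' @param permissible_gap maximum allowed gap in days (>= 1).
#' @param followup_days length of the post-index follow-up window.
#' @param strict logical; `TRUE` declares an event only when the gap
#'   *exceeds* `permissible_gap`, `FALSE` also at exact equality.
#' @return an object of class `gap_policy`.
#' @export
gap_policy <- function(permissible_gap = 90L, followup_days = 365L, strict = TRUE) {
  permissible_gap <- as.integer(permissible_gap)
  followup_days <- as.integer(followup_days)
  stopifnot(permissible_gap >= 1L, followup_days >= 1L, is.logical(strict))
  structure(list(permissible_gap = permissible_gap,
                 followup_days = followup_days,
                 strict = strict),
            class = "gap_policy")
}

#' Days covered by drug supply within the follow-up window
#'
#' Counts the days in `[0, followup_days)` covered by at least one
#' prescription, taking each fill as the half-open interval
#' `[fill_day, fill_day + days_supply)`. Overlapping supply from early
#' refills is counted once — no stockpiling carry-forward — which is the
#' numerator convention of the proportion of days covered (PDC).
#'
#' @param fill_days integer day offsets of fills from the index date.
#' @param days_supply days of supply per fill (same length).
#' @param followup_days window length (default 365).
#' @return integer count of covered days in `[0, followup_days)`.
#' @export
covered_days <- function(fill_days, days_supply, followup_days = 365L) {
  stopifnot(length(fill_days) == length(days_supply))
  if (length(fill_days) == 0L) return(0L)
  fill_days <- as.integer(fill_days)
  days_supply <- as.integer(days_supply)
  stopifnot(all(days_supply >= 1L))
  outside <- fill_days >= followup_days | fill_days + days_supply <= 0L
  if (any(outside)) {
    warning(sum(outside), " fill(s) entirely outside the follow-up window ignored")
    fill_days <- fill_days[!outside]
    days_supply <- days_supply[!outside]
    if (!length(fill_days)) return(0L)
  }
  start <- pmax(fill_days, 0L)
  end <- pmin(fill_days + days_supply, followup_days)
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]
  # sweep merged intervals
  total <- 0L
  cur_s <- start[1L]; cur_e <- end[1L]
  if (length(start) > 1L) {
    for (i in 2L:length(start)) {
      if (start[i] <= cur_e) {
        if (end[i] > cur_e) cur_e <- end[i]
      } else {
        total <- total + (cur_e - cur_s)
        cur_s <- start[i]; cur_e <- end[i]
      }
    }
  }
  total + (cur_e - cur_s)
}

#' Detect the first discontinuation event
#'
#' Scans consecutive SGLT2i prescription dates for the first pair whose
#' inter-fill gap violates the policy; the event day is then the supply
#' run-out of the earlier fill, `min(fill_day + days_supply, followup)`. A
#' trailing gap — no further fill and more than the permissible gap between
#' the last fill date and the end of follow-up — likewise triggers an event
#' at the last fill's run-out. The first prescription of a different
#' antidiabetic agent after the index date is a switch (combination
#' initiation) event at that fill's date. The earliest event wins (ties go
#' to the gap event); with no event the patient is persistent and censored
#' at `followup_days`.
#'
#' @param fill_days,days_supply SGLT2i fills as day offsets from index
#'   (day 0 fill required — cohort patients start therapy at index) and
#'   their supplies.
#' @param other_a10_days day offsets of non-SGLT2i antidiabetic fills after
#'   the index date (offsets <= 0 are ignored: same-day combination starts
#'   are a cohort exclusion, not an exposure event).
#' @param policy a [gap_policy()].
#' @return list with `persistence_days` (integer, `followup_days` if
#'   persistent), `discontinued` (logical) and `reason`
#'   (`"gap"`, `"switch"` or `"none"`).
#' @export
detect_discontinuation <- function(fill_days, days_supply,
                                   other_a10_days = integer(),
                                   policy = gap_policy()) {
  stopifnot(inherits(policy, "gap_policy"))
  if (length(fill_days) == 0L) {
    stop("detect_discontinuation: no SGLT2i fills; cohort precondition violated")
  }
  fu <- policy$followup_days
  gap <- policy$permissible_gap
  exceeds <- if (policy$strict) function(g) g > gap else function(g) g >= gap

  ord <- order(fill_days)
  d <- as.integer(fill_days)[ord]
  s <- as.integer(days_supply)[ord]

  gap_day <- NA_integer_
  if (length(d) > 1L) {
    gaps <- diff(d)
    hit <- which(vapply(gaps, exceeds, logical(1)))
    if (length(hit)) gap_day <- min(d[hit[1L]] + s[hit[1L]], fu)
  }
  if (is.na(gap_day) && exceeds(fu - d[length(d)])) {
    gap_day <- min(d[length(d)] + s[length(s)], fu)
  }
  switch_day <- NA_integer_
  oth <- as.integer(other_a10_days)
  oth <- oth[oth > 0L & oth < fu]
  if (length(oth)) switch_day <- min(oth)

  if (is.na(gap_day) && is.na(switch_day)) {
    return(list(persistence_days = fu, discontinued = FALSE, reason = "none"))
  }
  if (!is.na(gap_day) && (is.na(switch_day) || gap_day <= switch_day)) {
    list(persistence_days = gap_day, discontinued = TRUE, reason = "gap")
  } else {
    list(persistence_days = switch_day, discontinued = TRUE, reason = "switch")
  }
}

#' Did a gap discontinuer restart the index drug?
#'
#' A restarter is a patient with a gap discontinuation event who
#' subsequently receives at least one further SGLT2i prescription before
#' the end of follow-up. Restarters remain classified by their first
#' event — they are not re-indexed as new users.
#'
#' @param fill_days SGLT2i fill day offsets.
#' @param event_day the gap event day.
#' @param followup_days follow-up window length.
#' @return logical.
#' @export
detect_restart <- function(fill_days, event_day, followup_days = 365L) {
  if (is.na(event_day)) {
    stop("detect_restart: called for a patient without a discontinuation event")
  }
  any(as.integer(fill_days) > event_day & as.integer(fill_days) < followup_days)
}

#' Per-patient exposure: persistence, restart, PDC and adherence
#'
#' Assembles, for every cohort member, the persistence time and
#' discontinuation event from [detect_discontinuation()], the restart flag
#' from [detect_restart()] (evaluated for gap events only by default — a
#' switcher is still on antidiabetic therapy), and the adherence measures:
#' `covered_days` over the whole follow-up window regardless of any gap
#' event, `pdc = covered_days / followup_days`, and the adherent flag
#' (`pdc >= pdc_threshold`).
#'
#' @param cohort cohort data frame from [build_cohort()].
#' @param bundle the [claims_bundle()].
#' @param policy a [gap_policy()].
#' @param pdc_threshold adherence cut-off on the PDC scale (default 0.80).
#' @param restart_after_switch also evaluate restart for switch events
#'   (default `FALSE`).
#' @return data frame with one row per cohort member: `patient_id`,
#'   `persistence_days`, `discontinued`, `reason`, `restarted`,
#'   `covered_days`, `pdc`, `adherent`.
#' @export
compute_exposure <- function(cohort, bundle, policy = gap_policy(),
                             pdc_threshold = 0.80, restart_after_switch = FALSE) {
  stopifnot(inherits(bundle, "claims_bundle"), inherits(policy, "gap_policy"))
  n <- nrow(cohort)
  out <- data.frame(patient_id = character(n), persistence_days = integer(n),
                    discontinued = logical(n), reason = character(n),
                    restarted = logical(n), covered_days = integer(n),
                    pdc = numeric(n), adherent = logical(n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  fu <- policy$followup_days
  rx <- bundle$prescriptions
  keep <- rx$patient_id %in% cohort$patient_id & is_antidiabetic(rx$atc_code)
  rx <- rx[keep, , drop = FALSE]
  day <- as.integer(rx$rx_date) - as.integer(cohort$index_date[match(rx$patient_id, cohort$patient_id)])
  sgl <- is_sglt2i(rx$atc_code)

  in_win <- day >= 0L & day < fu
  sgl_day <- split(day[sgl & in_win], rx$patient_id[sgl & in_win])
  sgl_sup <- split(rx$days_supply[sgl & in_win], rx$patient_id[sgl & in_win])
  oth_day <- split(day[!sgl & day > 0L & day < fu], rx$patient_id[!sgl & day > 0L & day < fu])

  for (i in seq_len(n)) {
    pid <- cohort$patient_id[i]
    fd <- sgl_day[[pid]]
    sp <- sgl_sup[[pid]]
    if (is.null(fd) || length(fd) == 0L) {
      stop("compute_exposure: cohort patient ", pid,
           " has no SGLT2i fill in the follow-up window")
    }
    ev <- detect_discontinuation(fd, sp, oth_day[[pid]] %||% integer(), policy)
    restarted <- FALSE
    if (ev$discontinued &&
        (ev$reason == "gap" || (restart_after_switch && ev$reason == "switch"))) {
      restarted <- detect_restart(fd, ev$persistence_days, fu)
    }
    cd <- covered_days(fd, sp, fu)
    out$patient_id[i] <- pid
    out$persistence_days[i] <- ev$persistence_days
    out$discontinued[i] <- ev$discontinued
    out$reason[i] <- ev$reason
    out$restarted[i] <- restarted
    out$covered_days[i] <- cd
    out$pdc[i] <- cd / fu
    out$adherent[i] <- cd / fu >= pdc_threshold
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
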