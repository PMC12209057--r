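# Independent brute-force oracles and small bundle builders used across tests.

# day-by-day boolean-array count of covered days in [0, fu)
oracle_covered_days <- function(fill_days, days_supply, fu = 365L) {
  covered <- logical(fu)
  for (i in seq_along(fill_days)) {
    lo <- max(fill_days[i], 0L)
    hi <- min(fill_days[i] + days_supply[i], fu)
    if (hi > lo) covered[(lo + 1L):hi] <- TRUE
  }
  sum(covered)
}

# exhaustive day-walk: advance through follow-up one day at a time and
# trigger the gap event the first day the time since the most recent
# prescription exceeds the permissible gap - a different computational route
# from the consecutive-pair scan in the package. The switch day is the first
# other-agent fill; the earlier event day wins, ties going to the gap.
oracle_discontinuation <- function(fill_days, days_supply,
                                   other_days = integer(), gap = 90L, fu = 365L) {
  ord <- order(fill_days)
  d <- as.integer(fill_days)[ord]
  s <- as.integer(days_supply)[ord]
  gap_day <- NA_integer_
  if (d[1L] + 1L <= fu) {
    for (t in (d[1L] + 1L):fu) {
      prev <- max(which(d <= t - 1L))
      if (t - d[prev] > gap) {
        gap_day <- min(d[prev] + s[prev], fu)
        break
      }
    }
  }
  oth <- as.integer(other_days)
  oth <- oth[oth > 0L & oth < fu]
  switch_day <- if (length(oth)) min(oth) else NA_integer_
  if (is.na(gap_day) && is.na(switch_day)) {
    return(list(persistence_days = fu, discontinued = FALSE, reason = "none"))
  }
  if (!is.na(gap_day) && (is.na(switch_day) || gap_day <= switch_day)) {
    list(persistence_days = gap_day, discontinued = TRUE, reason = "gap")
  } else {
    list(persistence_days = switch_day, discontinued = TRUE, reason = "switch")
  }
}

# hand product-limit estimator: S(t) = prod over event times <= t of (1 - d/n)
oracle_km <- function(times, events, t_eval) {
  ut <- sort(unique(times[events]))
  s <- 1
  for (tt in ut) {
    if (tt > t_eval) break
    n_risk <- sum(times >= tt)
    d <- sum(times == tt & events)
    s <- s * (1 - d / n_risk)
  }
  s
}

# minimal well-formed bundle for plumbing tests (3 patients, editable parts)
tiny_bundle_tables <- function() {
  enr <- data.frame(
    patient_id = c("A", "B", "C"),
    birth_ym = as.Date(c("1970-05-15", "1980-02-15", "1965-11-15")),
    sex = c("male", "female", "male"),
    obs_start = as.Date("2017-10-01"),
    obs_end = as.Date("2020-09-30"),
    stringsAsFactors = FALSE)
  rx <- data.frame(
    patient_id = c("A", "A", "B"),
    rx_date = as.Date(c("2018-06-01", "2018-07-01", "2018-06-15")),
    atc_code = c("A10PA01", "A10PA01", "A10PA02"),
    days_supply = c(30L, 30L, 30L),
    fdc_flag = FALSE, stringsAsFactors = FALSE)
  dx <- data.frame(
    patient_id = "A",
    dx_date = as.Date("2018-05-01"),
    icd10_code = "E119",
    suspected_flag = FALSE, stringsAsFactors = FALSE)
  vis <- data.frame(
    patient_id = c("A", "A", "B", "C"),
    visit_date = as.Date(c("2018-04-01", "2018-05-01", "2018-06-01", "2018-01-10")),
    stringsAsFactors = FALSE)
  list(enrollment = enr, prescriptions = rx, diagnoses = dx, visits = vis)
}

tiny_bundle <- function() {
  tb <- tiny_bundle_tables()
  claims_bundle(tb$enrollment, tb$prescriptions, tb$diagnoses, tb$visits)
}
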