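#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (the convention used for the
#' report tables' percentages), rather than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  # small epsilon absorbs binary representation error just below .5
  floor(x * m + 0.5 + 1e-9) / m
}

#' Percentage of a count, rounded half-up to one decimal
#'
#' @param n numerator count.
#' @param d denominator count.
#' @param digits decimal places.
#' @return numeric percentage.
#' @export
pct <- function(n, d, digits = 1L) {
  round_half_up(100 * n / d, digits)
}

#' Render "n (p)" count-percentage cells
#'
#' @param n numerator count(s).
#' @param d denominator count.
#' @return character, e.g. `"1029 (77.5)"`; a zero count renders
#'   `"0 (0.0)"`.
#' @export
fmt_count_pct <- function(n, d) {
  p <- ifelse(d > 0, pct(n, d), 0)
  sprintf("%d (%s)", as.integer(n), formatC(p, format = "f", digits = 1))
}

fmt_mean_sd <- function(x, digits = 1L) {
  sprintf("%s (%s)",
          formatC(round_half_up(mean(x), digits), format = "f", digits = digits),
          formatC(round_half_up(stats::sd(x), digits), format = "f", digits = digits))
}

fmt_mean_sd_range <- function(x, digits = 1L) {
  sprintf("%s (%s-%s)", fmt_mean_sd(x, digits),
          formatC(round_half_up(min(x), digits), format = "f", digits = digits),
          formatC(round_half_up(max(x), digits), format = "f", digits = digits))
}

#' Baseline-characteristics table
#'
#' Renders the baseline covariates as a two-column table: `n (%)` for
#' categorical rows, `mean (SD)` (with range where conventional) for
#' continuous rows. Every count comes straight from the covariate table;
#' nothing is recomputed.
#'
#' @param covariates covariate data frame from [build_covariates()].
#' @return data frame with `variable` and `value` character columns.
#' @export
render_table1 <- function(covariates) {
  n <- nrow(covariates)
  if (n == 0L) stop("render_table1: empty covariate table")
  comorb <- setdiff(names(covariates),
                    c("patient_id", "calendar_year_2018", "sex_male", "age_years",
                      "n_visits", "mean_visit_interval_days",
                      "n_concomitant_classes", "cci"))
  rows <- list(
    c("n", as.character(n)),
    c("Calendar year 2018, n (%)", fmt_count_pct(sum(covariates$calendar_year_2018), n)),
    c("Calendar year 2019, n (%)", fmt_count_pct(sum(!covariates$calendar_year_2018), n)),
    c("Sex, male, n (%)", fmt_count_pct(sum(covariates$sex_male), n)),
    c("Age at index, years, mean (SD) (range)",
      fmt_mean_sd_range(covariates$age_years)),
    c("Outpatient visits, preceding 180 days, mean (SD)",
      fmt_mean_sd(covariates$n_visits)),
    c("Mean visit interval, preceding 180 days, days, mean (SD)",
      fmt_mean_sd(covariates$mean_visit_interval_days)),
    c("Concomitant drug classes, mean (SD)",
      fmt_mean_sd(covariates$n_concomitant_classes)))
  for (cm in comorb) {
    rows <- c(rows, list(c(sprintf("%s, n (%%)", cm),
                           fmt_count_pct(sum(covariates[[cm]]), n))))
  }
  rows <- c(rows, list(c("Charlson comorbidity index, mean (SD) (range)",
                         fmt_mean_sd_range(covariates$cci))))
  out <- data.frame(variable = vapply(rows, `[`, character(1), 1L),
                    value = vapply(rows, `[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  out
}

#' Factor table with group counts and odds ratios
#'
#' Renders an [or_analysis()] table in the layout of a factors-affecting-
#' outcome table: for binary covariates, the outcome / reference group
#' counts with row percentages (which sum to 100 across the row); for
#' continuous covariates, group means (SD); plus formatted crude and
#' adjusted OR (95% CI) columns.
#'
#' @param or_table an `or_table` from [or_analysis()].
#' @param outcome logical outcome vector used for the fit.
#' @param covariates the covariate data frame used for the fit.
#' @return data frame with character columns `term`, `reference_group`,
#'   `outcome_group`, `crude_or_ci`, `adjusted_or_ci`.
#' @export
render_or_table <- function(or_table, outcome, covariates) {
  fmt_or <- function(or, lo, hi) {
    ifelse(is.na(or), "not estimable",
           sprintf("%.3f (%.3f-%.3f)", or, lo, hi))
  }
  rows <- lapply(or_table$term, function(v) {
    x <- covariates[[v]]
    if (is.logical(x)) {
      n1 <- sum(x & outcome); n0 <- sum(x & !outcome)
      tot <- n1 + n0
      ref <- fmt_count_pct(n0, tot)
      out <- fmt_count_pct(n1, tot)
    } else {
      ref <- fmt_mean_sd(x[!outcome])
      out <- fmt_mean_sd(x[outcome])
    }
    data.frame(term = v, reference_group = ref, outcome_group = out,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$crude_or_ci <- fmt_or(or_table$crude_or, or_table$crude_lower, or_table$crude_upper)
  res$adjusted_or_ci <- fmt_or(or_table$adjusted_or, or_table$adjusted_lower,
                               or_table$adjusted_upper)
  res
}

#' Run the full persistence/adherence study pipeline
#'
#' Orchestrates cohort construction, exposure measurement under each gap
#' policy, covariate derivation, and the statistical layer: Kaplan-Meier
#' persistence, person-year incidence, restart rates, crude/adjusted
#' logistic odds ratios for non-persistence (under the primary gap policy)
#' and for poor adherence, multicollinearity screening, and the linear
#' regressions of PDC and follow-up time on age and visit interval.
#' Deterministic for a fixed input bundle.
#'
#' @param bundle a validated [claims_bundle()].
#' @param gap_days integer vector of permissible gaps; the first is the
#'   primary policy (default `c(90, 30)`).
#' @param pdc_threshold adherent cut-off on the PDC scale (default 0.80).
#' @param pre_days,followup_days study windows.
#' @param out_dir optional directory; when given, all result tables are
#'   written as CSV along with a plain-text run manifest.
#' @return a `study_result` list: `flow`, `cohort`, `covariates`,
#'   `exposure` (named list per gap), `km` (named list), `incidence`,
#'   `persistence_rate`, `restart_rate`, `or_persistence`, `or_adherence`,
#'   `vif`, `linear`, `table1`, `table_persistence`, `table_adherence`,
#'   `manifest`.
#' @export
run_study <- function(bundle, gap_days = c(90L, 30L), pdc_threshold = 0.80,
                      pre_days = 180L, followup_days = 365L, out_dir = NULL) {
  stopifnot(inherits(bundle, "claims_bundle"), length(gap_days) >= 1L)
  cb <- build_cohort(bundle, pre_days = pre_days, post_days = followup_days)
  cohort <- cb$cohort
  if (nrow(cohort) == 0L) stop("run_study: empty cohort after exclusions")
  covs <- build_covariates(cohort, bundle, pre_days = pre_days)

  gaps <- as.integer(gap_days)
  names(gaps) <- paste0("gap", gaps)
  exposure <- lapply(gaps, function(g)
    compute_exposure(cohort, bundle, gap_policy(g, followup_days),
                     pdc_threshold = pdc_threshold))
  km <- lapply(exposure, function(e)
    km_estimate(e$persistence_days, e$discontinued, followup_days))
  inc <- lapply(exposure, incidence)
  persistence_rate <- vapply(km, km_survival_at, numeric(1), t = followup_days)
  restart_rate <- vapply(exposure, function(e) {
    gd <- e$discontinued & e$reason == "gap"
    if (!any(gd)) NA_real_ else mean(e$restarted[gd])
  }, numeric(1))

  primary <- exposure[[1L]]
  or_pers <- or_analysis(primary$discontinued, covs, outcome_label = "non-persistence")
  or_adh <- or_analysis(!primary$adherent, covs, outcome_label = "poor adherence")
  vif <- check_multicollinearity(covs)

  linear <- list(
    pdc_vs_age = fit_linear(primary$pdc, covs$age_years),
    pdc_vs_visit_interval = fit_linear(primary$pdc, covs$mean_visit_interval_days),
    followup_vs_age = fit_linear(primary$persistence_days, covs$age_years),
    followup_vs_visit_interval = fit_linear(primary$persistence_days,
                                            covs$mean_visit_interval_days))

  manifest <- data.frame(
    key = c("package_version", "n_enrolled", "n_candidates", "n_cohort",
            "gap_days", "pdc_threshold", "pre_days", "followup_days",
            "n_prescriptions", "n_diagnoses", "n_visits"),
    value = c(as.character(utils::packageVersion("persistkit")),
              nrow(bundle$enrollment),
              cb$flow$n_remaining[cb$flow$stage == "candidates"],
              nrow(cohort), paste(gaps, collapse = ";"), pdc_threshold,
              pre_days, followup_days, nrow(bundle$prescriptions),
              nrow(bundle$diagnoses), nrow(bundle$visits)),
    stringsAsFactors = FALSE)

  res <- list(flow = cb$flow, candidate_exclusions = cb$candidate_exclusions,
              cohort = cohort, covariates = covs, exposure = exposure,
              km = km, incidence = inc,
              persistence_rate = persistence_rate, restart_rate = restart_rate,
              mean_pdc = mean(primary$pdc),
              adherent_share = mean(primary$adherent),
              or_persistence = or_pers, or_adherence = or_adh, vif = vif,
              linear = linear,
              table1 = render_table1(covs),
              table_persistence = render_or_table(or_pers, primary$discontinued, covs),
              table_adherence = render_or_table(or_adh, !primary$adherent, covs),
              manifest = manifest)
  class(res) <- "study_result"
  if (!is.null(out_dir)) write_study_result(res, out_dir)
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  cat(sprintf("  cohort: %d patients\n", nrow(x$cohort)))
  for (g in names(x$persistence_rate)) {
    cat(sprintf("  %s: persistence %.1f%%, restart %.1f%%, incidence %.1f /1000 PY\n",
                g, 100 * x$persistence_rate[[g]],
                100 * x$restart_rate[[g]], x$incidence[[g]]$rate_per_1000py))
  }
  cat(sprintf("  mean PDC %.1f%%, adherent %.1f%%\n",
              100 * x$mean_pdc, 100 * x$adherent_share))
  invisible(x)
}

write_study_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) utils::write.csv(as.data.frame(x),
                                          file.path(out_dir, paste0(name, ".csv")),
                                          row.names = FALSE)
  w(res$flow, "flow")
  coh <- res$cohort; coh$index_date <- format_claim_date(coh$index_date)
  w(coh, "cohort")
  w(res$covariates, "covariates")
  for (g in names(res$exposure)) {
    w(res$exposure[[g]], paste0("exposure_", g))
    w(res$km[[g]], paste0("km_", g))
  }
  w(res$or_persistence, "or_persistence")
  w(res$or_adherence, "or_adherence")
  w(res$vif, "vif")
  lin <- do.call(rbind, lapply(names(res$linear), function(nm)
    data.frame(model = nm, res$linear[[nm]], stringsAsFactors = FALSE)))
  w(lin, "linear_fits")
  w(res$table1, "table1")
  w(res$table_persistence, "table_persistence")
  w(res$table_adherence, "table_adherence")
  w(res$manifest, "manifest")
  invisible(out_dir)
}
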