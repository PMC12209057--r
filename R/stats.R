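#' Kaplan-Meier persistence curve
#'
#' Product-limit estimate of the persistence function over the follow-up
#' window. Patients still on therapy at the end of follow-up carry
#' `time = followup_days` and `event = FALSE` (censored persistent); ties
#' at a time point are processed together.
#'
#' @param times per-patient persistence days in `[0, followup_days]`.
#' @param events logical event indicators (TRUE = discontinuation).
#' @param followup_days window length (default 365).
#' @param conf_level level for the pointwise (log-transformed) confidence
#'   band (default 0.95).
#' @return an object of class `km_curve`: data frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, `lower`, `upper`.
#' @export
km_estimate <- function(times, events, followup_days = 365L, conf_level = 0.95) {
  if (length(times) == 0L) stop("km_estimate: empty input")
  if (length(times) != length(events)) stop("km_estimate: times/events length mismatch")
  times <- as.numeric(times)
  if (any(is.na(times)) || any(times < 0) || any(times > followup_days)) {
    stop("km_estimate: times must lie in [0, ", followup_days, "]")
  }
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.int = conf_level, conf.type = "log")
  out <- data.frame(time = fit$time,
                    n_risk = fit$n.risk,
                    n_event = fit$n.event,
                    n_censor = fit$n.censor,
                    survival = fit$surv,
                    lower = fit$lower,
                    upper = fit$upper)
  attr(out, "n") <- length(times)
  attr(out, "followup_days") <- followup_days
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", attr(x, "n"), "\n")
  s_end <- km_survival_at(x, attr(x, "followup_days"))
  cat(sprintf("  survival at day %d: %.3f\n", attr(x, "followup_days"), s_end))
  invisible(x)
}

#' Survival probability at a given time
#'
#' Step-function lookup on a [km_estimate()] curve: the survival just after
#' the last event time at or before `t` (1 before the first event).
#'
#' @param curve a `km_curve`.
#' @param t time in days.
#' @return numeric survival probability.
#' @export
km_survival_at <- function(curve, t) {
  idx <- which(curve$time <= t & curve$n_event > 0)
  if (!length(idx)) return(1)
  ev <- curve[curve$n_event > 0, , drop = FALSE]
  ev$survival[max(which(ev$time <= t))]
}

#' Incidence per 1000 person-years
#'
#' Events divided by summed at-risk time. Person-time is each patient's
#' persistence days divided by 365.
#'
#' @param exposure exposure data frame from [compute_exposure()].
#' @return list (`incidence_result`) with `events`, `person_years`,
#'   `rate_per_1000py`.
#' @export
incidence <- function(exposure) {
  events <- sum(exposure$discontinued)
  person_years <- sum(exposure$persistence_days) / 365
  if (person_years <= 0) stop("incidence: zero person-years of follow-up")
  structure(list(events = events,
                 person_years = person_years,
                 rate_per_1000py = 1000 * events / person_years),
            class = "incidence_result")
}

#' @export
print.incidence_result <- function(x, ...) {
  cat(sprintf("%d events / %.1f person-years = %.1f per 1000 PY\n",
              x$events, x$person_years, x$rate_per_1000py))
  invisible(x)
}

# covariate columns entered in the factor models, in reporting order
model_covariate_names <- function(covariates) {
  setdiff(names(covariates), "patient_id")
}

#' Logistic odds ratios for a binary study outcome
#'
#' Fits logistic models for a binary outcome (non-persistence or poor
#' adherence coded `TRUE`). In `"crude"` mode each covariate enters a
#' single-covariate model of its own; in `"adjusted"` mode all covariates
#' enter one joint model. Odds ratios are exponentiated coefficients with
#' Wald confidence intervals. A covariate whose fit fails (separation,
#' non-convergence, aliasing) is reported with `fit_ok = FALSE` and `NA`
#' estimates rather than aborting the table.
#'
#' @param outcome logical vector, one per patient.
#' @param covariates covariate data frame from [build_covariates()]
#'   (the `patient_id` column is ignored).
#' @param mode `"crude"` or `"adjusted"`.
#' @param conf_level Wald CI level (default 0.95).
#' @return data frame with `term`, `or`, `ci_lower`, `ci_upper`,
#'   `p_value`, `fit_ok`, `mode`.
#' @export
fit_logistic <- function(outcome, covariates, mode = c("adjusted", "crude"),
                         conf_level = 0.95) {
  mode <- match.arg(mode)
  outcome <- as.logical(outcome)
  if (length(outcome) != nrow(covariates)) {
    stop("fit_logistic: outcome length must match covariate rows")
  }
  if (!any(outcome) || all(outcome)) {
    stop("fit_logistic: outcome must contain both classes")
  }
  vars <- model_covariate_names(covariates)
  X <- covariates[vars]
  X[] <- lapply(X, function(col) if (is.logical(col)) as.numeric(col) else as.numeric(col))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  extract <- function(fit, terms) {
    cf <- summary(fit)$coefficients
    rows <- lapply(terms, function(tm) {
      if (!tm %in% rownames(cf) || is.na(cf[tm, 1L])) {
        return(data.frame(term = tm, or = NA_real_, ci_lower = NA_real_,
                          ci_upper = NA_real_, p_value = NA_real_,
                          fit_ok = FALSE, stringsAsFactors = FALSE))
      }
      b <- cf[tm, 1L]; se <- cf[tm, 2L]
      ok <- fit$converged && is.finite(se) && se < 1e3
      data.frame(term = tm, or = exp(b),
                 ci_lower = exp(b - z * se), ci_upper = exp(b + z * se),
                 p_value = cf[tm, 4L], fit_ok = ok, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  res <- if (mode == "adjusted") {
    dat <- cbind(.y = outcome, X)
    fit <- tryCatch(
      suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(term = vars, or = NA_real_, ci_lower = NA_real_,
                 ci_upper = NA_real_, p_value = NA_real_, fit_ok = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      extract(fit, vars)
    }
  } else {
    do.call(rbind, lapply(vars, function(v) {
      dat <- data.frame(.y = outcome, x = X[[v]])
      fit <- tryCatch(
        suppressWarnings(stats::glm(.y ~ x, data = dat, family = stats::binomial())),
        error = function(e) NULL)
      if (is.null(fit)) {
        return(data.frame(term = v, or = NA_real_, ci_lower = NA_real_,
                          ci_upper = NA_real_, p_value = NA_real_,
                          fit_ok = FALSE, stringsAsFactors = FALSE))
      }
      r <- extract(fit, "x"); r$term <- v; r
    }))
  }
  res$mode <- mode
  rownames(res) <- NULL
  res
}

#' Crude and adjusted odds-ratio table
#'
#' Runs [fit_logistic()] in both modes and merges the results into one
#' table per covariate, with the outcome and reference group sizes.
#'
#' @inheritParams fit_logistic
#' @param outcome_label label for the outcome (e.g. `"non-persistence"`).
#' @return data frame (`or_table`) with `term`, `crude_or`, `crude_lower`,
#'   `crude_upper`, `adjusted_or`, `adjusted_lower`, `adjusted_upper`,
#'   `crude_p`, `adjusted_p`; attributes `outcome_label`, `n_outcome`,
#'   `n_reference`.
#' @export
or_analysis <- function(outcome, covariates, outcome_label = "outcome",
                        conf_level = 0.95) {
  crude <- fit_logistic(outcome, covariates, mode = "crude", conf_level = conf_level)
  adj <- fit_logistic(outcome, covariates, mode = "adjusted", conf_level = conf_level)
  out <- data.frame(term = crude$term,
                    crude_or = crude$or, crude_lower = crude$ci_lower,
                    crude_upper = crude$ci_upper, crude_p = crude$p_value,
                    adjusted_or = adj$or, adjusted_lower = adj$ci_lower,
                    adjusted_upper = adj$ci_upper, adjusted_p = adj$p_value,
                    stringsAsFactors = FALSE)
  attr(out, "outcome_label") <- outcome_label
  attr(out, "n_outcome") <- sum(outcome)
  attr(out, "n_reference") <- sum(!outcome)
  class(out) <- c("or_table", "data.frame")
  out
}

#' @export
print.or_table <- function(x, digits = 3, ...) {
  cat(sprintf("<or_table> outcome: %s (%d vs %d reference)\n",
              attr(x, "outcome_label"), attr(x, "n_outcome"), attr(x, "n_reference")))
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors for the adjusted model design
#'
#' For each covariate, regresses it on all the others and reports
#' `VIF = 1 / (1 - R^2)`. Constant columns are reported as degenerate
#' (`NA` VIF); perfectly collinear columns yield infinite VIF. Covariates
#' with `VIF > threshold` are flagged.
#'
#' @param covariates covariate data frame ([build_covariates()] output or
#'   any numeric/logical design).
#' @param threshold flag level (default 10).
#' @return data frame with `term`, `vif`, `degenerate`, `flagged`.
#' @export
check_multicollinearity <- function(covariates, threshold = 10) {
  vars <- model_covariate_names(covariates)
  X <- covariates[vars]
  X[] <- lapply(X, as.numeric)
  X <- as.matrix(X)
  out <- data.frame(term = vars, vif = NA_real_, degenerate = FALSE,
                    flagged = FALSE, stringsAsFactors = FALSE)
  const <- apply(X, 2L, function(c) stats::var(c) == 0 || !is.finite(stats::var(c)))
  out$degenerate <- const
  for (j in seq_along(vars)) {
    if (const[j]) next
    others <- X[, -j, drop = FALSE]
    others <- others[, !const[-j], drop = FALSE]
    if (ncol(others) == 0L) { out$vif[j] <- 1; next }
    fit <- stats::lm.fit(cbind(1, others), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    out$vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out$flagged <- !out$degenerate & out$vif > threshold
  out
}

#' Simple linear regression of an outcome on one predictor
#'
#' Ordinary least squares with a Wald confidence interval on the slope,
#' used for the age / visit-interval versus PDC / follow-up analyses.
#'
#' @param response numeric response vector (e.g. PDC, persistence days).
#' @param predictor numeric predictor vector (e.g. age).
#' @param conf_level CI level (default 0.95).
#' @return list with `slope`, `ci_lower`, `ci_upper`, `p_value`,
#'   `intercept`, `n`.
#' @export
fit_linear <- function(response, predictor, conf_level = 0.95) {
  ok <- is.finite(response) & is.finite(predictor)
  response <- response[ok]; predictor <- predictor[ok]
  n <- length(response)
  if (n < 3L) stop("fit_linear: need at least 3 complete observations")
  if (stats::var(predictor) == 0) stop("fit_linear: predictor has zero variance")
  fit <- stats::lm(response ~ predictor)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit, "predictor", level = conf_level)
  list(slope = unname(cf["predictor", 1L]),
       ci_lower = unname(ci[1L]), ci_upper = unname(ci[2L]),
       p_value = unname(cf["predictor", 4L]),
       intercept = unname(cf["(Intercept)", 1L]),
       n = n)
}
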