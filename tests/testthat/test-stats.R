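test_that("the product-limit estimate matches hand-computed values", {
  km <- km_estimate(c(100, 100, 200, 365, 365), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(km_survival_at(km, 100), 0.6)
  expect_equal(km_survival_at(km, 200), 0.4)
  expect_equal(km_survival_at(km, 365), 0.4)
  expect_equal(km_survival_at(km, 50), 1)
  # no events: survival identically one
  km0 <- km_estimate(rep(365, 10), rep(FALSE, 10))
  expect_equal(km_survival_at(km0, 365), 1)
  # all events on day 1: survival drops to zero and stays there
  km1 <- km_estimate(rep(1, 5), rep(TRUE, 5))
  expect_equal(km_survival_at(km1, 1), 0)
  expect_equal(km_survival_at(km1, 365), 0)
  expect_error(km_estimate(numeric(), logical()), "empty")
  expect_error(km_estimate(c(10, 400), c(TRUE, TRUE)), "lie in")
})

test_that("survival is non-increasing and matches the hand product-limit on random data", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(5:40, 1L)
    times <- sample(1:365, n, replace = TRUE)
    events <- runif(n) < 0.7
    times[!events] <- 365
    km <- km_estimate(times, events)
    expect_true(all(diff(km$survival) <= 1e-12))
    for (tt in sample(1:365, 3L)) {
      expect_equal(km_survival_at(km, tt), oracle_km(times, events, tt))
    }
  }
})

test_that("incidence is events over person-years, per 1000", {
  # 10 events over 10 * 18250 / 365 = 500 person-years
  e <- data.frame(discontinued = c(rep(TRUE, 10), rep(FALSE, 5)),
                  persistence_days = c(rep(18250, 10), rep(0, 5)))
  inc <- incidence(e)
  expect_equal(inc$person_years, 500)
  expect_equal(inc$rate_per_1000py, 20)
  e0 <- data.frame(discontinued = FALSE, persistence_days = 365)
  expect_equal(incidence(e0)$rate_per_1000py, 0)
  expect_error(incidence(data.frame(discontinued = logical(),
                                    persistence_days = numeric())),
               "person-years")
})

test_that("a crude OR on a 2x2 table equals the cross-product ratio", {
  outcome <- c(rep(TRUE, 20), rep(FALSE, 80), rep(TRUE, 10), rep(FALSE, 90))
  covs <- data.frame(patient_id = sprintf("p%03d", 1:200),
                     exposed = c(rep(TRUE, 100), rep(FALSE, 100)))
  fit <- fit_logistic(outcome, covs, mode = "crude")
  expect_equal(fit$or, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_true(fit$fit_ok)
})

test_that("a covariate with no effect gives a near-null crude OR", {
  set.seed(43)
  n <- 10000L
  covs <- data.frame(patient_id = as.character(1:n), x = runif(n) < 0.5)
  outcome <- runif(n) < 0.5
  fit <- fit_logistic(outcome, covs, mode = "crude")
  expect_gt(fit$or, 0.9)
  expect_lt(fit$or, 1.1)
})

test_that("degenerate fits are reported, not fatal", {
  set.seed(47)
  n <- 200L
  covs <- data.frame(patient_id = as.character(1:n),
                     x1 = rnorm(n))
  covs$x2 <- covs$x1                     # aliased column
  outcome <- runif(n) < plogis(covs$x1)
  fit <- fit_logistic(outcome, covs, mode = "adjusted")
  expect_false(fit$fit_ok[fit$term == "x2"])
  expect_true(is.na(fit$or[fit$term == "x2"]))
  expect_true(fit$fit_ok[fit$term == "x1"])
  expect_error(fit_logistic(rep(TRUE, n), covs), "both classes")
})

test_that("variance inflation factors match the independent implementation", {
  set.seed(53)
  n <- 500L
  covs <- data.frame(patient_id = as.character(1:n),
                     a = rnorm(n), b = rnorm(n), c = rnorm(n))
  v <- check_multicollinearity(covs)
  expect_true(all(abs(v$vif - 1) < 0.1))
  expect_false(any(v$flagged))
  # cross-check against car::vif on a strongly collinear design
  covs$d <- covs$a + rnorm(n, sd = 0.1)
  v2 <- check_multicollinearity(covs)
  y <- rnorm(n)
  ref <- car::vif(lm(y ~ a + b + c + d, data = covs))
  expect_equal(v2$vif, unname(ref[v2$term]), tolerance = 1e-6)
  expect_true(v2$flagged[v2$term == "a"])  # VIF ~ 1/(1-R^2) >> 10
})

test_that("perfect collinearity and constant columns are flagged as degenerate", {
  n <- 100L
  covs <- data.frame(patient_id = as.character(1:n), a = rnorm(n))
  covs$dup <- covs$a
  covs$const <- 1
  v <- check_multicollinearity(covs)
  expect_equal(v$vif[v$term %in% c("a", "dup")], c(Inf, Inf))
  expect_true(all(v$flagged[v$term %in% c("a", "dup")]))
  expect_true(v$degenerate[v$term == "const"])
  expect_true(is.na(v$vif[v$term == "const"]))
})

test_that("simple linear regression recovers exact and planted slopes", {
  x <- 1:20
  # a noiseless line makes summary.lm warn about the perfect fit
  fit <- suppressWarnings(fit_linear(2 * x, x))
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_lt(fit$ci_upper - fit$ci_lower, 1e-8)

  set.seed(59)
  x <- rnorm(1000)
  y <- 0.5 * x + rnorm(1000)
  fit <- fit_linear(y, x)
  expect_lt(fit$ci_lower, 0.5)
  expect_gt(fit$ci_upper, 0.5)

  y0 <- rnorm(1000)
  fit0 <- fit_linear(y0, x)
  expect_lt(fit0$ci_lower, 0)
  expect_gt(fit0$ci_upper, 0)

  expect_error(fit_linear(1:10, rep(1, 10)), "zero variance")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})
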