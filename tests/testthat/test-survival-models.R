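constant_hazard_followups <- function(n, h, cmax, seed) {
  set.seed(seed)
  tt <- rexp(n, h)
  cc <- runif(n, 0, cmax)
  data.frame(time_to_event = pmin(tt, cc), event = as.integer(tt <= cc),
             sex = sample(c("M", "F"), n, replace = TRUE),
             age = runif(n, 55, 84), asa_grade = 2L, bmi = rnorm(n, 31, 5),
             patella_replaced = 0L, antibiotic_cement = 1L,
             senior_surgeon = rbinom(n, 1, 0.8),
             treatment_centre = rbinom(n, 1, 0.1))
}

test_that("zero internal knots recover the exponential limit", {
  d <- constant_hazard_followups(20000, 0.05, 12, 81)
  fit <- fit_rcs_hazard(d, covariates = NULL, n_internal_knots = 0)
  # log H linear in log t with slope 1
  expect_lt(abs(fit$gamma[["gamma1"]] - 1), 0.05)
  # H(t) ~ h*t
  for (tt in c(1, 5, 10)) {
    expect_lt(abs(predict_cumulative_revision(fit, tt) -
                    (1 - exp(-0.05 * tt))), 0.006)
  }
})

test_that("annual transition probabilities match the constant-hazard form", {
  d <- constant_hazard_followups(20000, 0.05, 12, 82)
  fit <- fit_rcs_hazard(d, covariates = NULL, n_internal_knots = 0)
  p <- annual_transition_probs(fit, horizon = 45)
  expect_length(p, 45)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(p - (1 - exp(-0.05)))), 0.01)
})

test_that("transition probabilities are internally consistent with the
          cumulative prediction", {
  fit <- small_fits()$fits$spline_models[["PFC Sigma"]]
  for (sx in c("M", "F")) {
    p <- annual_transition_probs(fit, sex = sx, age = 70, horizon = 45)
    S <- cumprod(1 - p)
    cum <- predict_cumulative_revision(fit, 1:45, sex = sx, age = 70)
    expect_lt(max(abs((1 - S) - cum)), 1e-10)
  }
})

test_that("a null covariate effect is estimated near zero", {
  # senior_surgeon carries no effect in the generator truth
  d <- generate_revision_survival(
    registry_config(n_revision_patients = 60000), seed = 83)$records
  db <- d[d$brand == "PFC Sigma", ]
  fit <- fit_rcs_hazard(db)
  se <- sqrt(diag(fit$cov))
  expect_lt(abs(fit$beta[["senior_surgeon"]]),
            3 * se[["senior_surgeon"]])
})

test_that("deviance is non-increasing in the number of knots", {
  d <- constant_hazard_followups(5000, 0.08, 10, 84)
  ll <- vapply(0:3, function(k) {
    fit_rcs_hazard(d, covariates = NULL, n_internal_knots = k)$loglik
  }, numeric(1))
  expect_true(all(diff(ll) > -1e-4))   # -2logLik non-increasing
})

test_that("extrapolated cumulative incidence is monotone to 45 years", {
  for (fit in small_fits()$fits$spline_models) {
    cum <- predict_cumulative_revision(fit, 1:45, sex = "F", age = 70)
    expect_true(all(diff(cum) >= -1e-12))
    expect_true(all(cum >= 0 & cum <= 1))
  }
})

test_that("prediction guards and fitting preconditions hold", {
  fit <- small_fits()$fits$spline_models[["Nexgen"]]
  expect_error(predict_cumulative_revision(fit, 0), "> 0")
  expect_error(predict_cumulative_revision(fit, -1), "> 0")
  expect_lt(predict_cumulative_revision(fit, 1e-6), 1e-4)
  few <- data.frame(time_to_event = c(1, 2, 3, 10, 11),
                    event = c(1, 1, 0, 0, 0))
  expect_error(fit_rcs_hazard(few, covariates = NULL,
                              n_internal_knots = 3), "distinct uncensored")
})

test_that("piecewise re-revision rates are the person-years MLE", {
  # hand-constructed single-piece data: events only inside year 1
  d <- data.frame(time_to_event = c(0.5, 0.25, 1.0, 0.8, 0.9),
                  event = c(1, 1, 1, 0, 0))
  expect_warning(fit <- fit_piecewise_rerevision(d), "no events")
  expect_equal(fit$rates[["year1"]], 3 / sum(c(0.5, 0.25, 1.0, 0.8, 0.9)))
  expect_equal(fit$rates[["later"]], 0)

  # all censored
  d2 <- data.frame(time_to_event = c(2, 3, 4), event = c(0, 0, 0))
  expect_warning(f2 <- fit_piecewise_rerevision(d2), "no events")
  expect_equal(unname(f2$rates), c(0, 0))
})

test_that("the general piecewise model nests the exponential", {
  set.seed(85)
  n <- 30000
  tt <- rexp(n, 0.06)
  cc <- runif(n, 0, 8)
  d <- data.frame(time_to_event = pmin(tt, cc), event = as.integer(tt <= cc))
  fit <- fit_piecewise_hazard(d, cuts = 1:7)
  expect_lt(max(abs(fit$rates - 0.06)), 0.015)
  p <- annual_transition_probs_piecewise(fit, horizon = 45)
  expect_length(p, 45)
  # rate carried forward beyond the last cut
  expect_equal(p[20], p[45])
  H <- -log(cumprod(1 - p))
  expect_lt(abs(H[10] / 10 - 0.06), 0.01)
})
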