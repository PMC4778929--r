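test_that("coefficients agree with a hand-computed normal-equations fit", {
  set.seed(11)
  n <- 4000
  d <- data.frame(
    brand = sample(tkr_brands(), n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = runif(n, 55, 84),
    preop_eq5d = rnorm(n, 0.4, 0.3)
  )
  d$postop_eq5d <- 0.6 + 0.3 * d$preop_eq5d + rnorm(n, 0, 0.2)
  fit <- fit_postop_qol(d, covariates = c("sex", "age_c", "preop_eq5d"))
  # independent oracle: normal equations on the same design
  X <- cbind(1,
             outer(d$brand, setdiff(tkr_brands(), "AGC Biomet")[
               order(match(setdiff(tkr_brands(), "AGC Biomet"),
                           tkr_brands()))], "==") * 1,
             d$sex == "F", d$age - 70, d$preop_eq5d)
  beta <- ols_by_hand(X, d$postop_eq5d)
  expect_equal(unname(fit$coefficients["preop_eq5d"]),
               beta[nrow(beta), 1], tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["(Intercept)"]), beta[1, 1],
               tolerance = 1e-10)
})

test_that("null and calibrated brand effects are recovered", {
  # null case: all offsets zero
  cfg0 <- registry_config(
    n_patients = 20000,
    brand_utility_effects = setNames(rep(0, 5), tkr_brands()))
  d0 <- generate_proms_cohort(cfg0, seed = 51)$records
  ct0 <- brand_contrasts(fit_postop_qol(d0))
  expect_true(all(abs(ct0$estimate) < 3 * ct0$se))

  # calibrated case: Nexgen +0.02 vs AGC Biomet recovered within 3 SE
  d1 <- generate_proms_cohort(registry_config(n_patients = 50000),
                              seed = 52)$records
  fit1 <- fit_postop_qol(d1)
  ct1 <- brand_contrasts(fit1)
  nex <- ct1[ct1$brand == "Nexgen", ]
  expect_lt(abs(nex$estimate - 0.02), 3 * nex$se)
  # registry-scale contrast standard errors
  expect_gt(nex$se, 0.002)
  expect_lt(nex$se, 0.008)

  # subgroup predictions sit near the configured adjusted means
  pr <- predict_subgroup_qol(fit1, c("Nexgen", "Genesis 2"), "M", 70)
  expect_lt(abs(pr$fit[1] - 0.74), 0.015)
  expect_lt(abs(pr$fit[2] - 0.71), 0.015)
})

test_that("provider adjustment moves brand contrasts toward the truth", {
  d <- generate_proms_cohort(registry_config(n_patients = 150000),
                             seed = 53)$records
  with_prov <- brand_contrasts(fit_postop_qol(d))
  no_prov <- brand_contrasts(fit_postop_qol(
    d, covariates = setdiff(default_qol_covariates(),
                            c("senior_surgeon", "treatment_centre"))))
  truth <- c("PFC Sigma" = 0.01, "Nexgen" = 0.02, "Genesis 2" = -0.01,
             "Triathlon" = 0)
  err_with <- abs(with_prov$estimate - truth[with_prov$brand])
  err_without <- abs(no_prov$estimate - truth[no_prov$brand])
  # PFC Sigma and Triathlon are the provider-confounded brands (treatment
  # centres carry a positive outcome effect)
  expect_lt(sum(err_with[with_prov$brand %in% c("PFC Sigma", "Triathlon")]),
            sum(err_without[no_prov$brand %in% c("PFC Sigma",
                                                 "Triathlon")]))
})

test_that("subgroup predictions behave under nulls and recoding", {
  f <- small_fits()$fits$qol_fit
  # zeroed brand coefficients -> identical predictions across brands
  f0 <- f
  bc <- grepl("^brand", names(f0$coefficients))
  f0$coefficients[bc] <- 0
  pr <- predict_subgroup_qol(f0, tkr_brands(), "F", 70)
  expect_lt(diff(range(pr$fit)), 1e-12)

  # affine recoding of a covariate leaves predictions unchanged
  d <- small_fits()$data$proms
  d <- d[!is.na(d$postop_eq5d), ]
  fit_a <- fit_postop_qol(d, covariates = c("sex", "age_c", "bmi"))
  d2 <- d
  d2$bmi <- (d$bmi - 30) / 5
  fit_b <- fit_postop_qol(d2, covariates = c("sex", "age_c", "bmi"))
  pa <- predict_subgroup_qol(fit_a, "Nexgen", "M", 70)
  pb <- predict_subgroup_qol(fit_b, "Nexgen", "M", 70)
  expect_equal(pa$fit, pb$fit, tolerance = 1e-8)

  expect_error(predict_subgroup_qol(f, "Nexgen", "M", 65), "60, 70, 80")
  expect_silent(predict_subgroup_qol(f, "Nexgen", "M", 65,
                                     allow_any_age = TRUE))
})

test_that("missing values are rejected before imputation", {
  d <- small_fits()$data$proms
  expect_error(fit_postop_qol(d), "impute")
})

test_that("revision-state QOL models recover the generator truth", {
  rq <- generate_revision_qol(registry_config(), seed = 61)$records
  pre <- fit_state_qol(rq, "pre_revision")
  post <- fit_state_qol(rq, "post_revision")
  p_pre <- predict_state_qol(pre, 70, "M")
  p_post <- predict_state_qol(post, 70, "M")
  expect_lt(abs(p_pre$fit - 0.45), 3 * p_pre$se)
  expect_lt(abs(p_post$fit - 0.62), 3 * p_post$se)
  # sex effect is zero in the truth
  expect_lt(abs(pre$coefficients[["sexF"]]),
            3 * sqrt(diag(pre$vcov)[["sexF"]]))
  expect_error(fit_state_qol(rq[1:10, ], "pre_revision"), "minimum")
})

test_that("aging decline follows the quadratic schedule with a floor", {
  expect_equal(aging_decline(70), 0.004)
  expect_equal(aging_decline(0), 0)
  expect_equal(aging_decline(80), 0.004 * (80 / 70)^2)
  expect_equal(apply_aging_decline(0.7, 70), 0.7 - 0.004)
  expect_equal(apply_aging_decline(-0.5935, 80), -0.594)
})
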