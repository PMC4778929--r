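test_that("configuration invariants are enforced", {
  expect_error(registry_config(n_patients = 0), "positive")
  expect_error(registry_config(brand_shares = setNames(rep(0.3, 5),
                                                       tkr_brands())),
               "sum to 1")
  expect_error(registry_config(missing_postop_rate = 1.3), "\\[0, 1\\]")
  expect_error(registry_config(
    brand_utility_effects = setNames(c(2, 0, 0, 0, 0), tkr_brands())),
    "\\[-1, 1\\]")
  tg <- registry_config()$hazard_targets
  tg$p10_f[1] <- tg$p5_f[1] / 2          # 10-year below 5-year
  expect_error(registry_config(hazard_targets = tg), "10-year")
  tg2 <- registry_config()$hazard_targets
  tg2$p10_m[2] <- 1.2
  expect_error(registry_config(hazard_targets = tg2), "< 1")
})

test_that("regenerating with the same seed reproduces identical records", {
  cfg <- registry_config(n_patients = 2000, n_revision_patients = 2000,
                         n_rerevision_patients = 2000)
  a <- generate_proms_cohort(cfg, seed = 7)
  b <- generate_proms_cohort(cfg, seed = 7)
  expect_identical(a$records, b$records)
  c <- generate_proms_cohort(cfg, seed = 8)
  expect_false(identical(a$records, c$records))
  expect_identical(generate_revision_survival(cfg, seed = 7)$records,
                   generate_revision_survival(cfg, seed = 7)$records)
})

test_that("case-mix marginals match the registry targets", {
  cohort <- generate_proms_cohort(registry_config(n_patients = 20000),
                                  seed = 21)
  d <- cohort$records
  by_brand <- split(d, d$brand)
  for (b in names(by_brand)) {
    db <- by_brand[[b]]
    expect_gt(mean(db$age), 69.3)
    expect_lt(mean(db$age), 71.1)
    expect_gt(mean(db$sex == "M"), 0.40)
    expect_lt(mean(db$sex == "M"), 0.48)
    expect_gt(mean(db$bmi), 30.4)
    expect_lt(mean(db$bmi), 32.0)
  }
  # provider confounding: PFC Sigma and Triathlon dominated by treatment
  # centres relative to Nexgen
  istc <- tapply(d$treatment_centre, d$brand, mean)
  expect_gt(istc[["PFC Sigma"]], istc[["Nexgen"]] + 0.03)
  expect_gt(istc[["Triathlon"]], istc[["Nexgen"]] + 0.03)
  expect_true(all(d$age >= 55 & d$age <= 84))
  expect_true(all(d$preop_oks >= 0 & d$preop_oks <= 48))
  expect_true(all(d$postop_eq5d <= 1 & d$postop_eq5d >= -0.594))
})

test_that("null brand offsets remove the brand effect from the truth", {
  cfg <- registry_config(
    n_patients = 30000,
    brand_utility_effects = setNames(rep(0, 5), tkr_brands()))
  sim <- generate_proms_cohort(cfg, seed = 5)
  # the latent offsets collapse to zero exactly
  expect_equal(unname(sim$truth$latent_brand_offsets), rep(0, 5),
               tolerance = 1e-10)
  # marginal means still differ slightly through the (intentionally)
  # brand-specific case mix and provider layer, but only slightly
  means <- tapply(sim$records$postop_eq5d, sim$records$brand, mean)
  expect_lt(diff(range(means)), 0.03)
})

test_that("missingness injection hits the target rate and mechanism", {
  cohort <- generate_proms_cohort(registry_config(n_patients = 20000),
                                  seed = 31)
  d0 <- inject_missingness(cohort$records, rate = 0)
  expect_identical(sum(is.na(d0$postop_eq5d)), 0L)

  n <- nrow(cohort$records)
  d <- inject_missingness(cohort$records, rate = 0.17, mechanism = "MCAR",
                          seed = 32)
  expect_lt(abs(sum(is.na(d$postop_eq5d)) - 0.17 * n),
            3 * sqrt(n * 0.17 * 0.83))

  dm <- inject_missingness(cohort$records, rate = 0.17, mechanism = "MAR",
                           seed = 33)
  expect_lt(abs(mean(is.na(dm$postop_eq5d)) - 0.17), 0.02)
  # missingness depends on age ...
  miss <- is.na(dm$postop_eq5d)
  fit <- glm(miss ~ scale(dm$age) + scale(dm$preop_eq5d),
             family = binomial())
  z_age <- coef(summary(fit))[2, 3]
  expect_gt(z_age, 4)
  # ... but not on the unobserved outcome residual given covariates
  res <- residuals(lm(postop_eq5d ~ age + preop_eq5d + preop_oks + brand,
                      data = cohort$records))
  fit2 <- glm(miss ~ scale(dm$age) + scale(dm$preop_eq5d) + res,
              family = binomial())
  expect_lt(abs(coef(summary(fit2))["res", 3]), 3)

  expect_error(inject_missingness(cohort$records, rate = 0.1,
                                  mechanism = "weird"))
})

test_that("zero revision hazard yields only censored records", {
  tg <- registry_config()$hazard_targets
  tg[, c("p5_m", "p10_m", "p5_f", "p10_f")] <- 0
  cfg <- registry_config(n_revision_patients = 2000, hazard_targets = tg)
  r <- generate_revision_survival(cfg, seed = 3)$records
  expect_identical(sum(r$event), 0L)
  expect_true(all(r$time_to_event > 0))
})

test_that("constant-hazard calibration matches the closed form", {
  # p5/p10 from a constant hazard make the two-piece truth degenerate
  h <- 0.02
  tg <- registry_config()$hazard_targets
  tg$p5_m <- tg$p5_f <- 1 - exp(-5 * h)
  tg$p10_m <- tg$p10_f <- 1 - exp(-10 * h)
  cfg <- registry_config(n_revision_patients = 60000, hazard_targets = tg,
                         hazard_covariate_effects = c(age = 0, asa3 = 0,
                                                      bmi = 0, patella = 0,
                                                      cement = 0))
  r <- generate_revision_survival(cfg, seed = 9)$records
  km <- survival::survfit(survival::Surv(time_to_event, event) ~ 1,
                          data = r)
  for (tt in c(2, 5)) {
    i <- max(which(km$time <= tt))
    expect_lt(abs((1 - km$surv[i]) - (1 - exp(-h * tt))),
              3 * km$std.err[i] * km$surv[i] + 1e-4)
  }
})

test_that("revision truth hits the published 5- and 10-year anchors", {
  cfg <- registry_config(n_revision_patients = 150000)
  sim <- generate_revision_survival(cfg, seed = 12)
  # truth is exact by construction
  h <- sim$truth$hazard_women["Nexgen", ]
  expect_equal(1 - exp(-(h[["year1"]] + 4 * h[["later"]])), 0.016)
  expect_equal(1 - exp(-(h[["year1"]] + 9 * h[["later"]])), 0.025)
  expect_gt(h[["year1"]], h[["later"]])   # early-failure elevation
  # Kaplan-Meier on the generated women records agrees at 10 years
  r <- sim$records
  rw <- r[r$sex == "F" & r$brand == "Nexgen", ]
  km <- survival::survfit(survival::Surv(time_to_event, event) ~ 1,
                          data = rw)
  i <- max(which(km$time <= 10))
  expect_lt(abs((1 - km$surv[i]) - 0.025),
            3 * km$std.err[i] * km$surv[i] + 1e-4)
})

test_that("re-revision generator matches its closed form and recovers", {
  cfg <- registry_config(n_rerevision_patients = 50000)
  sim <- generate_rerevision(cfg, seed = 14)
  r <- sim$records
  # 1-year cumulative incidence ~ 1 - exp(-rate1) among those observable
  at_risk <- r$time_to_event >= 1 | r$event == 1
  km <- survival::survfit(survival::Surv(time_to_event, event) ~ 1,
                          data = r)
  i <- max(which(km$time <= 1))
  expect_lt(abs((1 - km$surv[i]) - (1 - exp(-0.04))), 0.004)
  fit <- fit_piecewise_rerevision(r)
  expect_lt(abs(fit$rates[["year1"]] - 0.04),
            3 * 0.04 * fit$se_log[["year1"]])
  expect_lt(abs(fit$rates[["later"]] - 0.015),
            3 * 0.015 * fit$se_log[["later"]])
})

test_that("registry files round-trip losslessly through CSV", {
  cfg <- small_config()
  cfg$registry$n_patients <- 500
  cfg$registry$n_revision_patients <- 500
  cfg$registry$n_rerevision_patients <- 500
  reg <- cmd_simulate(cfg, seed = 77)
  dir <- withr::local_tempdir()
  write_registry(reg, dir)
  back <- read_registry(dir)
  for (nm in c("proms", "revisions", "rerevisions", "revision_qol")) {
    orig <- reg[[nm]]$records
    attr(orig, "missing") <- NULL
    got <- back[[nm]]
    got$brand <- if ("brand" %in% names(got)) got$brand
    for (col in names(orig)) {
      if (is.factor(orig[[col]])) {
        expect_identical(as.character(got[[col]]),
                         as.character(orig[[col]]))
      } else {
        expect_identical(got[[col]], orig[[col]])
      }
    }
  }
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "data_dictionary.csv")))
  tr <- back$truth
  expect_equal(tr$proms$brand_utility_effects$Nexgen, 0.02)
})
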