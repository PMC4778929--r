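test_that("discounted QALYs reach the geometric-series limit", {
  # unit utility, no deaths, no revisions, aging decline disabled
  mi <- test_model_inputs(
    utility_primary = 1, utility_revision_year = 1,
    utility_post_revision = 1,
    revision_probs = rep(0, 45),
    rerevision_probs = c(year1 = 0, later = 0),
    op_mortality = 0, mortality_probs = rep(0, 45),
    apply_aging = FALSE
  )
  out <- run_cohort(mi)
  expect_equal(out$result$qalys, sum(1.035^-(0:44)), tolerance = 1e-12)
  # closed-form annuity value of 45 cycles discounted at 3.5%
  v <- 1 / 1.035
  expect_equal(sum(1.035^-(0:44)), (1 - v^45) / (1 - v), tolerance = 1e-12)
  expect_equal(round(sum(1.035^-(0:44)), 3), 23.283)

  mi0 <- test_model_inputs(
    utility_primary = 1, utility_revision_year = 1,
    utility_post_revision = 1,
    revision_probs = rep(0, 45),
    rerevision_probs = c(year1 = 0, later = 0),
    op_mortality = 0, mortality_probs = rep(0, 45),
    apply_aging = FALSE, discount_rate = 0
  )
  expect_equal(run_cohort(mi0)$result$qalys, 45)
})

test_that("the trace conserves probability and death is absorbing", {
  out <- run_cohort(test_model_inputs())
  tr <- out$trace
  occ <- tr[, c("post_tkr", "revision_year", "post_revision", "dead")]
  expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
  expect_true(all(diff(tr$dead) >= -1e-15))
  expect_true(all(as.matrix(occ) >= 0))
})

test_that("initial cost assembles price, theatre and bed days", {
  mi <- test_model_inputs(prosthesis_price = 0, los_days = 0)
  expect_equal(initial_cost(mi), 2022)
  ref <- brand_reference()
  agc <- test_model_inputs(prosthesis_price = 1150,
                           los_days = ref$los_m[ref$brand == "AGC Biomet"])
  expect_equal(initial_cost(agc), 4574)
  expect_error(test_model_inputs(los_days = -1), "negative")
})

test_that("operative mortality propagates to the cycle-0 death mass", {
  out <- run_cohort(test_model_inputs(op_mortality = 0.002))
  expect_equal(out$trace$dead[1], 0.002)
  expect_equal(out$trace$post_tkr[1], 0.998)
})

test_that("lifetime proportion revised matches the no-death closed form", {
  p <- c(rep(0.01, 10), rep(0.004, 35))
  mi <- test_model_inputs(revision_probs = p, op_mortality = 0,
                          mortality_probs = rep(0, 45),
                          rerevision_probs = c(year1 = 0, later = 0))
  out <- run_cohort(mi)
  expect_equal(lifetime_proportion_revised(out$trace),
               1 - prod(1 - p), tolerance = 1e-12)
  out0 <- run_cohort(test_model_inputs(revision_probs = rep(0, 45)))
  expect_equal(lifetime_proportion_revised(out0$trace), 0)
})

test_that("more revision means weakly more cost and fewer QALYs", {
  base <- run_cohort(test_model_inputs())$result
  worse <- run_cohort(test_model_inputs(
    revision_probs = rep(0.012, 45)))$result
  expect_gt(worse$cost, base$cost)
  expect_lt(worse$qalys, base$qalys)
  expect_gt(worse$proportion_revised, base$proportion_revised)
})

test_that("results do not depend on the brand label", {
  a <- run_cohort(test_model_inputs(brand = "Nexgen"))$result
  b <- run_cohort(test_model_inputs(brand = "Triathlon"))$result
  expect_equal(a$qalys, b$qalys)
  expect_equal(a$cost, b$cost)
})

test_that("input validation rejects out-of-range parameters", {
  expect_error(test_model_inputs(revision_probs = rep(1.5, 45)),
               "\\[0, 1\\]")
  expect_error(test_model_inputs(utility_primary = 1.2), "exceed 1")
  expect_error(test_model_inputs(revision_probs = rep(0.01, 10)),
               "length")
})

test_that("an independent microsimulation reproduces the cohort model", {
  mi <- test_model_inputs()
  cohort <- run_cohort(mi)$result
  micro <- microsim_cohort(mi, n = 100000, seed = 91)
  expect_lt(abs(cohort$qalys - micro$qalys), 3 * micro$qalys_se)
  expect_lt(abs(cohort$cost - micro$cost), 3 * micro$cost_se)
  expect_lt(abs(cohort$proportion_revised - micro$proportion_revised),
            3 * micro$proportion_revised_se)
})
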