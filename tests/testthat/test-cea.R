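printed_table3_men <- function() {
  data.frame(
    brand = tkr_brands(),
    cost = c(5900, 5226, 5721, 5799, 5600),
    qalys = c(7.57, 7.50, 7.72, 7.38, 7.50)
  )
}

test_that("net monetary benefit is the WTP-valued QALY surplus", {
  expect_equal(nmb(7.5, 5226, 0), -5226)
  expect_equal(nmb(7.72, 5721, 20000), 20000 * 7.72 - 5721)  # 148679
  expect_equal(nmb(7.72, 5721, 20000), 148679)
  # the NMB difference between two options is linear in lambda
  l <- c(0, 10000, 20000, 40000)
  d <- nmb(7.72, 5721, l) - nmb(7.50, 5226, l)
  expect_equal(diff(d) / diff(l), rep(7.72 - 7.50, 3))
  expect_error(nmb(7.5, 5000, -1), ">= 0")
})

test_that("the ICER ladder reproduces the published dominance pattern", {
  tab <- icer_ladder(printed_table3_men())
  status <- setNames(tab$status, tab$brand)
  expect_identical(status[["AGC Biomet"]], "base")
  expect_identical(status[["Genesis 2"]], "dominated")
  expect_identical(status[["Triathlon"]], "dominated")
  expect_identical(status[["PFC Sigma"]], "dominated")
  nex <- tab[tab$brand == "Nexgen", ]
  expect_false(nex$status %in% c("dominated", "extended dominated"))
  expect_equal(nex$icer, (5721 - 5226) / (7.72 - 7.50))  # ~2250
  expect_lt(abs(nex$icer - 2250), 1)
  # dominated options carry no ICER
  expect_true(all(is.na(tab$icer[tab$status == "dominated"])))
})

test_that("simple and extended dominance follow their definitions", {
  # equal QALYs, different costs: the costlier option is dominated
  two <- data.frame(brand = c("A", "B"), cost = c(100, 90),
                    qalys = c(1, 1))
  t2 <- icer_ladder(two)
  expect_identical(t2$status[t2$brand == "A"], "dominated")
  expect_identical(t2$status[t2$brand == "B"], "base")

  # middle option extendedly dominated: the ICER jumps the gap
  three <- data.frame(brand = c("A", "B", "C"), cost = c(0, 10, 12),
                      qalys = c(0, 1, 3))
  t3 <- icer_ladder(three)
  expect_identical(t3$status[t3$brand == "B"], "extended dominated")
  expect_equal(t3$icer[t3$brand == "C"], 4)   # (12-0)/(3-0)

  # exact ties broken by brand-name order
  tie <- data.frame(brand = c("B", "A"), cost = c(5, 5), qalys = c(1, 1))
  expect_message(tt <- icer_ladder(tie), "brand-name order")
  expect_identical(tt$status[tt$brand == "A"], "base")
  expect_identical(tt$status[tt$brand == "B"], "dominated")
})

test_that("the ICER equals the WTP at which mean NMBs cross", {
  tab <- icer_ladder(printed_table3_men())
  nex <- tab[tab$brand == "Nexgen", ]
  agc <- tab[tab$brand == "AGC Biomet", ]
  lambda_star <- nex$icer
  expect_equal(nmb(nex$qalys, nex$cost, lambda_star),
               nmb(agc$qalys, agc$cost, lambda_star), tolerance = 1e-9)
})

# build a degenerate psa_results object by hand
fake_psa <- function(qalys, cost, n_draws = 4) {
  df <- do.call(rbind, lapply(seq_len(n_draws), function(d) {
    data.frame(draw = d, brand = factor(tkr_brands(),
                                        levels = tkr_brands()),
               qalys = qalys, cost = cost)
  }))
  attr(df, "sex") <- "M"
  attr(df, "age") <- 70
  attr(df, "n_sims") <- n_draws
  class(df) <- c("psa_results", "data.frame")
  df
}

test_that("degenerate PSA gives 0/1 frontier probabilities", {
  t3 <- printed_table3_men()
  psa <- fake_psa(t3$qalys, t3$cost)
  p <- prob_most_cost_effective(psa, 20000)
  expect_true(all(p %in% c(0, 1)))
  expect_equal(sum(p), 1)
  expect_equal(unname(p[["Nexgen"]]), 1)

  fr <- acceptability_frontier(psa, lambda_grid = c(0, 20000, 50000))
  # at lambda = 0 the cheapest brand leads the frontier
  expect_identical(fr$brand[fr$lambda == 0], "AGC Biomet")
  expect_identical(fr$brand[fr$lambda == 20000], "Nexgen")
  expect_true(all(fr$probability >= 0 & fr$probability <= 1))
  expect_error(acceptability_frontier(psa, lambda_grid = numeric(0)),
               "empty")
})

test_that("frontier probabilities across brands always sum to one", {
  psa <- run_psa(small_setup(), "M", 70, n_sims = 40, seed = 401)
  for (l in c(0, 5000, 20000, 50000)) {
    expect_equal(sum(prob_most_cost_effective(psa, l)), 1)
  }
})

test_that("the PSA is deterministic under a fixed seed", {
  a <- run_psa(small_setup(), "M", 70, n_sims = 10, seed = 402)
  b <- run_psa(small_setup(), "M", 70, n_sims = 10, seed = 402)
  expect_equal(as.data.frame(a), as.data.frame(b))
  c <- run_psa(small_setup(), "M", 70, n_sims = 10, seed = 403)
  expect_false(identical(a$qalys, c$qalys))
})

test_that("PSA means agree with the point estimates within MC error", {
  psa <- run_psa(small_setup(), "M", 70, n_sims = 300, seed = 404)
  pe <- point_estimates(small_setup(), "M", 70)
  m <- psa_means(psa)
  for (b in tkr_brands()) {
    dq <- psa$qalys[psa$brand == b]
    se <- sd(dq) / sqrt(length(dq))
    expect_lt(abs(m$qalys[m$brand == b] - pe$qalys[pe$brand == b]),
              4 * se + 0.02)
  }
})

test_that("scenario analyses modify the pipeline as specified", {
  su <- small_setup()
  expect_error(run_scenario(7, su, "M", 70), "unknown scenario")

  # scenario 5: equal prices compress the cost spread
  base <- run_psa(su, "M", 70, n_sims = 60, seed = 405)
  s5 <- run_scenario(5, su, "M", 70, n_sims = 60, seed = 405)
  expect_lt(diff(range(psa_means(s5$psa)$cost)),
            diff(range(psa_means(base)$cost)))

  # scenario 1: brand QOL differences only in year one narrow the QALY
  # spread between brands
  s1 <- run_scenario(1, su, "M", 70, n_sims = 60, seed = 406)
  expect_lt(diff(range(psa_means(s1$psa)$qalys)),
            diff(range(psa_means(base)$qalys)))

  # scenarios 2 and 3 refit the QOL model and still produce a full table
  s2 <- run_scenario(2, su, "M", 70, n_sims = 20, seed = 407)
  expect_identical(nrow(s2$cea_table), 5L)
  s3 <- run_scenario(3, su, "M", 70, n_sims = 20, seed = 408)
  expect_identical(nrow(s3$cea_table), 5L)

  # scenario 4 swaps in the piecewise hazard model
  s4 <- run_scenario(4, su, "M", 70, n_sims = 20, seed = 409)
  expect_identical(nrow(s4$cea_table), 5L)
  expect_equal(sum(s4$prob_most_cost_effective), 1)
})

test_that("spline and piecewise revision models agree on constant-hazard
          data", {
  set.seed(410)
  n <- 40000
  tt <- rexp(n, 0.03)
  cc <- runif(n, 0, 10)
  d <- data.frame(time_to_event = pmin(tt, cc),
                  event = as.integer(tt <= cc),
                  sex = sample(c("M", "F"), n, TRUE),
                  age = runif(n, 55, 84), asa_grade = 2L,
                  bmi = rnorm(n, 31, 5), patella_replaced = 0L,
                  antibiotic_cement = 1L, senior_surgeon = 0L,
                  treatment_centre = 0L)
  spline <- fit_rcs_hazard(d, covariates = NULL)
  pw <- fit_piecewise_hazard(d)
  ps <- annual_transition_probs(spline, horizon = 45)
  pp <- annual_transition_probs_piecewise(pw, horizon = 45)
  # both nest the exponential: near-identical annual probabilities
  expect_lt(max(abs(ps - pp)), 0.004)
})
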