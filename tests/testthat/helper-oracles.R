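# Independent oracles used to cross-check the implementation.

# Individual-level microsimulation of the same decision process as
# run_cohort(): simulates n patients through the annual cycles and returns
# Monte-Carlo means with standard errors. Written directly from the state
# definitions (not from the cohort code) so it is an independent check.
microsim_cohort <- function(inputs, n = 100000, seed = 1) {
  set.seed(seed)
  hz <- inputs$horizon
  disc <- (1 + inputs$discount_rate)^-(0:hz)
  u_prim <- rep_len(inputs$utility_primary, hz + 1)
  decline <- if (isTRUE(inputs$apply_aging)) {
    c(0, cumsum(aging_decline(inputs$age_at_surgery + 0:(hz - 1))))
  } else {
    numeric(hz + 1)
  }
  floor_u <- -0.594
  # states: 1 primary, 2 revision year, 3 post-rev year 1, 4 post-rev later,
  # 5 dead
  state <- ifelse(runif(n) < inputs$op_mortality, 5L, 1L)
  qalys <- numeric(n)
  cost <- rep(inputs$prosthesis_price + inputs$theatre_cost +
                inputs$los_days * inputs$bed_day_cost, n)
  ever_revised <- logical(n)
  uq <- function(u, t) pmax(u - decline[t + 1], floor_u)
  qalys <- qalys + (state != 5L) * uq(u_prim[1], 0)
  for (t in 1:hz) {
    alive <- state != 5L
    dies <- alive & (runif(n) < inputs$mortality_probs[t])
    state[dies] <- 5L
    new_state <- state
    isP <- state == 1L
    rev <- isP & (runif(n) < inputs$revision_probs[t])
    new_state[rev] <- 2L
    new_state[state == 2L] <- 3L
    rr1 <- state == 3L & (runif(n) < inputs$rerevision_probs[["year1"]])
    new_state[state == 3L & !rr1] <- 4L
    new_state[rr1] <- 2L
    rr2 <- state == 4L & (runif(n) < inputs$rerevision_probs[["later"]])
    new_state[rr2] <- 2L
    state <- new_state
    ever_revised <- ever_revised | rev
    new_rev <- rev | rr1 | rr2
    if (t < hz) {
      u <- c(uq(u_prim[t + 1], t), uq(inputs$utility_revision_year, t),
             uq(inputs$utility_post_revision, t),
             uq(inputs$utility_post_revision, t), 0)
      qalys <- qalys + u[state] * disc[t + 1]
      cost <- cost + inputs$revision_cost * new_rev * disc[t + 1]
    }
  }
  list(qalys = mean(qalys), qalys_se = sd(qalys) / sqrt(n),
       cost = mean(cost), cost_se = sd(cost) / sqrt(n),
       proportion_revised = mean(ever_revised),
       proportion_revised_se = sd(ever_revised) / sqrt(n))
}

# ordinary-least-squares coefficients computed from the normal equations
# (independent of stats::lm)
ols_by_hand <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}
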