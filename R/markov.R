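# The 4-state annual-cycle Markov cohort model:
# PostTKR -> RevisionYear -> PostRevision (-> RevisionYear ...), Dead
# absorbing. 45 cycles, costs and QALYs discounted at 3.5% per year.

#' Assemble the inputs of one brand x subgroup Markov run
#'
#' @param brand prosthesis brand label.
#' @param sex `"M"` or `"F"`.
#' @param age_at_surgery age at the primary TKR (60, 70 or 80 in the
#'   reported subgroups; any age within the life table is accepted).
#' @param utility_primary post-operative EQ-5D-3L in the primary-TKR state.
#'   Either a single value (held, subject to aging decline, until revision
#'   or death) or a vector of length `horizon + 1` giving the value per
#'   cycle (used by the scenario in which brand differences last one year).
#' @param utility_revision_year,utility_post_revision EQ-5D-3L in the year
#'   of revision and in subsequent post-revision years.
#' @param revision_probs annual first-revision probabilities, length
#'   `horizon`.
#' @param rerevision_probs named vector `c(year1=, later=)`: annual
#'   re-revision probabilities in the first post-revision year vs later.
#' @param op_mortality immediate operative mortality at cycle 0.
#' @param mortality_probs annual adjusted death probabilities for cycles
#'   `1..horizon` (see [adjusted_mortality()]).
#' @param prosthesis_price,los_days unit price (GBP) and length of stay.
#' @param theatre_cost,bed_day_cost,revision_cost,discount_rate care-pathway
#'   unit costs and the annual discount rate.
#' @param horizon number of annual cycles (default 45).
#' @param apply_aging apply the aging-related utility decline
#'   ([aging_decline()]) each cycle (default `TRUE`; disable to study the
#'   undeclined model).
#' @return Object of class `model_inputs`.
#' @export
model_inputs <- function(brand, sex, age_at_surgery,
                         utility_primary, utility_revision_year,
                         utility_post_revision,
                         revision_probs, rerevision_probs,
                         op_mortality, mortality_probs,
                         prosthesis_price, los_days,
                         theatre_cost = unit_costs()$theatre,
                         bed_day_cost = unit_costs()$bed_day,
                         revision_cost = unit_costs()$revision,
                         discount_rate = unit_costs()$discount_rate,
                         horizon = 45, apply_aging = TRUE) {
  if (length(revision_probs) != horizon) {
    stop("revision_probs must have length ", horizon)
  }
  if (length(mortality_probs) != horizon) {
    stop("mortality_probs must have length ", horizon)
  }
  probs <- c(revision_probs, rerevision_probs, op_mortality, mortality_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(utility_primary, utility_revision_year,
            utility_post_revision) > 1)) {
    stop("utilities cannot exceed 1")
  }
  if (los_days < 0) stop("negative length of stay")
  if (any(c(prosthesis_price, theatre_cost, bed_day_cost,
            revision_cost) < 0)) {
    stop("costs must be >= 0")
  }
  structure(list(
    brand = brand, sex = sex, age_at_surgery = age_at_surgery,
    utility_primary = utility_primary,
    utility_revision_year = utility_revision_year,
    utility_post_revision = utility_post_revision,
    revision_probs = revision_probs,
    rerevision_probs = rerevision_probs,
    op_mortality = op_mortality,
    mortality_probs = mortality_probs,
    prosthesis_price = prosthesis_price, los_days = los_days,
    theatre_cost = theatre_cost, bed_day_cost = bed_day_cost,
    revision_cost = revision_cost, discount_rate = discount_rate,
    horizon = horizon, apply_aging = apply_aging
  ), class = "model_inputs")
}

#' Initial cost of the primary replacement
#'
#' Prosthesis price + operating theatre + length of stay x bed-day cost.
#'
#' @param inputs a [model_inputs()] object.
#' @return Cost in GBP.
#' @export
initial_cost <- function(inputs) {
  stopifnot(inherits(inputs, "model_inputs"))
  inputs$prosthesis_price + inputs$theatre_cost +
    inputs$los_days * inputs$bed_day_cost
}

#' Run the Markov cohort model
#'
#' Cycle 0 applies operative mortality and the initial cost; each subsequent
#' cycle applies, in order, death (healthy-patient-adjusted mortality at the
#' attained age), then revision and re-revision transitions among survivors.
#' The revision-year state lasts exactly one cycle before moving to the
#' post-revision state, whose first year carries the year-1 re-revision
#' probability and later years the subsequent-years probability (re-revision
#' returns the patient to the revision-year state; re-revision cycles are
#' unlimited). Each of the 45 cycles accrues
#' `sum(occupancy x state utility)` QALYs, with every state utility reduced
#' by the cumulative aging decline, and revision costs for the mass newly
#' entering the revision-year state; both discounted at the annual rate.
#'
#' @param inputs a [model_inputs()] object.
#' @return List of class `cohort_result` with `trace` (a `cohort_trace`
#'   data.frame: occupancy of the four states per cycle `0..horizon`,
#'   per-cycle discounted QALY and cost increments, cumulative first-revision
#'   incidence) and `result` (class `lifetime_result`: mean lifetime QALYs,
#'   mean lifetime cost, lifetime proportion revised).
#' @export
run_cohort <- function(inputs) {
  stopifnot(inherits(inputs, "model_inputs"))
  hz <- inputs$horizon
  age0 <- inputs$age_at_surgery
  disc <- (1 + inputs$discount_rate)^-(0:hz)
  u_prim <- rep_len(inputs$utility_primary, hz + 1)
  # cumulative aging decline: none at entry, then one reduction per cycle
  decline <- if (isTRUE(inputs$apply_aging)) {
    c(0, cumsum(aging_decline(age0 + 0:(hz - 1))))
  } else {
    numeric(hz + 1)
  }
  floor_u <- eq5d_min()
  p_rr1 <- inputs$rerevision_probs[["year1"]]
  p_rr2 <- inputs$rerevision_probs[["later"]]

  # internal states: P (primary TKR), R (revision year), Q1 (first
  # post-revision year), Q2 (later post-revision), D (dead)
  P <- 1 - inputs$op_mortality
  R <- Q1 <- Q2 <- 0
  D <- inputs$op_mortality

  occ <- matrix(0, hz + 1, 4,
                dimnames = list(NULL, c("post_tkr", "revision_year",
                                        "post_revision", "dead")))
  qaly <- cost <- new_rev <- numeric(hz + 1)
  cum_first <- numeric(hz + 1)

  occ[1, ] <- c(P, 0, 0, D)
  qaly[1] <- P * pmax(u_prim[1] - decline[1], floor_u)
  cost[1] <- initial_cost(inputs)

  first <- 0
  for (t in seq_len(hz)) {
    q <- inputs$mortality_probs[t]
    D <- D + q * (P + R + Q1 + Q2)
    P <- P * (1 - q); R <- R * (1 - q)
    Q1 <- Q1 * (1 - q); Q2 <- Q2 * (1 - q)

    newR_P <- P * inputs$revision_probs[t]
    rr1 <- Q1 * p_rr1
    rr2 <- Q2 * p_rr2
    P <- P - newR_P
    R_prev <- R
    Q2 <- Q2 - rr2 + (Q1 - rr1)
    Q1 <- R_prev
    R <- newR_P + rr1 + rr2

    first <- first + newR_P
    occ[t + 1, ] <- c(P, R, Q1 + Q2, D)
    cum_first[t + 1] <- first
    new_rev[t + 1] <- R
    if (t < hz) {          # accrual covers cycles 0..horizon-1
      u <- pmax(c(u_prim[t + 1], inputs$utility_revision_year,
                  inputs$utility_post_revision) - decline[t + 1], floor_u)
      qaly[t + 1] <- (P * u[1] + R * u[2] + (Q1 + Q2) * u[3]) * disc[t + 1]
      cost[t + 1] <- inputs$revision_cost * R * disc[t + 1]
    }
  }

  trace <- data.frame(cycle = 0:hz, occ, qaly = qaly, cost = cost,
                      new_revisions = new_rev,
                      cum_first_revision = cum_first)
  class(trace) <- c("cohort_trace", "data.frame")
  result <- structure(list(brand = inputs$brand, sex = inputs$sex,
                           age_at_surgery = age0,
                           qalys = sum(qaly), cost = sum(cost),
                           proportion_revised = first),
                      class = "lifetime_result")
  structure(list(trace = trace, result = result), class = "cohort_result")
}

#' Lifetime proportion of the cohort ever revised
#'
#' Cumulative mass that entered the revision-year state from the primary-TKR
#' state (first revisions only).
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @return Proportion in `[0, 1]`.
#' @export
lifetime_proportion_revised <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  max(trace$cum_first_revision)
}

#' @export
print.lifetime_result <- function(x, ...) {
  cat(sprintf("%s, %s aged %d: %.3f QALYs, cost %.0f GBP, %.2f%% revised\n",
              x$brand, if (x$sex == "M") "men" else "women",
              x$age_at_surgery, x$qalys, x$cost,
              100 * x$proportion_revised))
  invisible(x)
}

#' @export
print.cohort_result <- function(x, ...) {
  print(x$result)
  invisible(x)
}
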