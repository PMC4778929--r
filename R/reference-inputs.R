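#' The five compared prosthesis brands
#'
#' Canonical brand names, in the column order used throughout the package.
#' AGC Biomet is the reference brand for regression contrasts and the ICER
#' base (it is the lowest-cost brand).
#'
#' @return Character vector of length 5.
#' @export
tkr_brands <- function() {
  c("PFC Sigma", "AGC Biomet", "Nexgen", "Genesis 2", "Triathlon")
}

#' Published brand-level reference inputs
#'
#' One row per brand with the study-condition anchors used to calibrate the
#' synthetic registry and to parameterize the decision model:
#' \describe{
#'   \item{price}{prosthesis unit price (GBP, 2011-12; includes components
#'     and instrumentation at negotiated NHS prices).}
#'   \item{share}{market share among the five brands in the QOL cohort.}
#'   \item{eq5d_m, eq5d_f}{case-mix-adjusted post-operative EQ-5D-3L index at
#'     6 months, men / women aged 70.}
#'   \item{oks_m, oks_f}{adjusted post-operative Oxford Knee Score.}
#'   \item{init_cost_m, init_cost_f}{mean cost of the primary replacement
#'     (prosthesis + theatre + bed days).}
#'   \item{los_m, los_f}{length of stay (days) back-computed from the initial
#'     cost as (initial cost - price - theatre) / bed-day cost, so that cost
#'     assembly reproduces the published initial costs exactly.}
#'   \item{rev5_m, rev5_f, rev10_m, rev10_f}{cumulative revision probability
#'     at 5 and 10 years, men / women aged 70.}
#'   \item{max_followup}{maximum registry observation period (years). Only
#'     the two endpoints are published (11.1 PFC Sigma, 6.7 Triathlon);
#'     intermediate brands follow their market-introduction order.}
#' }
#'
#' @return A data.frame with 5 rows, one per brand.
#' @export
#' @examples
#' brand_reference()
brand_reference <- function() {
  b <- tkr_brands()
  price <- c(1835, 1150, 1676, 1294, 1325)
  init_m <- c(5414, 4574, 5233, 5229, 5006)
  init_f <- c(5491, 4651, 5311, 5306, 5084)
  data.frame(
    brand = b,
    price = price,
    share = c(13635, 5005, 3364, 4187, 3585) / 29776,
    eq5d_m = c(0.73, 0.72, 0.74, 0.71, 0.72),
    eq5d_f = c(0.72, 0.71, 0.73, 0.70, 0.71),
    oks_m = c(35.4, 35.4, 36.0, 34.2, 35.3),
    oks_f = c(33.9, 33.8, 34.4, 32.6, 33.7),
    init_cost_m = init_m,
    init_cost_f = init_f,
    los_m = (init_m - price - 2022) / 332,
    los_f = (init_f - price - 2022) / 332,
    rev5_m = c(0.021, 0.028, 0.021, 0.024, 0.025),
    rev5_f = c(0.016, 0.022, 0.016, 0.019, 0.020),
    rev10_m = c(0.031, 0.042, 0.031, 0.037, 0.038),
    rev10_f = c(0.025, 0.033, 0.025, 0.029, 0.030),
    max_followup = c(11.1, 11.0, 10.8, 10.2, 6.7),
    stringsAsFactors = FALSE
  )
}

#' Unit costs of the TKR care pathway
#'
#' GBP at 2011-12 prices: operating theatre for a primary TKR, one hospital
#' bed day, one revision episode, and the annual discount rate applied to
#' costs and outcomes.
#'
#' @return Named list with elements `theatre`, `bed_day`, `revision`,
#'   `discount_rate`.
#' @export
unit_costs <- function() {
  list(theatre = 2022, bed_day = 332, revision = 8429, discount_rate = 0.035)
}

#' Table 1-style case-mix marginals used by the generator
#'
#' Per-brand marginal distributions of the pre-operative case mix the
#' synthetic cohort emulates: mean age, proportion male, mean BMI, proportion
#' in the most deprived IMD fifth, proportion with two or more comorbidities,
#' proportion ASA grade 3+, proportion operated at an independent-sector
#' treatment centre, proportion operated by a consultant, and mean (SD)
#' pre-operative OKS and EQ-5D-3L.
#'
#' @return data.frame with 5 rows (one per brand).
#' @keywords internal
case_mix_reference <- function() {
  data.frame(
    brand = tkr_brands(),
    age_mean = c(69.9, 70.5, 69.8, 70.1, 69.9),
    age_sd = 7.3,
    male = c(0.45, 0.44, 0.45, 0.44, 0.43),
    bmi_mean = c(31.3, 31.4, 31.4, 31.3, 31.0),
    bmi_sd = c(5.5, 5.7, 5.6, 5.5, 5.6),
    deprived = c(0.20, 0.16, 0.21, 0.22, 0.23),
    comorb2 = c(0.30, 0.29, 0.30, 0.29, 0.28),
    asa3 = c(0.16, 0.17, 0.18, 0.16, 0.18),
    istc = c(0.10, 0.02, 0.00, 0.01, 0.14),
    consultant = c(0.84, 0.79, 0.76, 0.77, 0.82),
    preop_oks_mean = c(18.5, 19.0, 18.6, 19.0, 18.8),
    preop_oks_sd = c(7.6, 7.7, 7.4, 7.6, 7.7),
    preop_eq5d_mean = c(0.38, 0.41, 0.39, 0.41, 0.40),
    preop_eq5d_sd = 0.31,
    stringsAsFactors = FALSE
  )
}

# EQ-5D-3L UK tariff support
eq5d_min <- function() -0.594
eq5d_max <- function() 1
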