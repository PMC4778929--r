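# Per-cycle death probabilities: operative mortality, then population
# mortality adjusted for a decaying healthy-patient effect.

#' Gompertz life table
#'
#' Annual death probabilities `q(a) = 1 - exp(-B * exp(theta * a))` for ages
#' 55-110, by sex; `q` at age 110 is 1 (the table absorbs all survivors).
#'
#' @param B_male,B_female,theta Gompertz parameters. The defaults are
#'   calibrated so that remaining life expectancy at age 70 is about 14
#'   years for men and 16 years for women.
#' @param ages age range of the table.
#' @return data.frame with columns `age`, `sex` (`"M"`/`"F"`), `qx`.
#' @export
gompertz_life_table <- function(B_male = 2.196346e-05,
                                B_female = 1.651901e-05,
                                theta = 0.10, ages = 55:110) {
  mk <- function(B, sex) {
    q <- 1 - exp(-B * exp(theta * ages))
    q[ages >= 110] <- 1
    data.frame(age = ages, sex = sex, qx = pmin(q, 1),
               stringsAsFactors = FALSE)
  }
  rbind(mk(B_male, "M"), mk(B_female, "F"))
}

#' @rdname gompertz_life_table
#' @export
default_life_table <- function() gompertz_life_table()

#' Read a life table from CSV
#'
#' Expects columns `age`, `sex` (`M`/`F`), `qx` with `qx` in `[0, 1]`.
#'
#' @param path CSV path.
#' @return Validated life-table data.frame.
#' @export
read_life_table <- function(path) {
  lt <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "sex", "qx") %in% names(lt))) {
    stop("life table must have columns age, sex, qx")
  }
  if (any(lt$qx < 0 | lt$qx > 1)) stop("qx must lie in [0, 1]")
  lt
}

# remaining life expectancy at a given age (used for calibration checks)
life_expectancy <- function(life_table, age, sex) {
  lt <- life_table[life_table$sex == sex & life_table$age >= age, ]
  lt <- lt[order(lt$age), ]
  sum(cumprod(1 - lt$qx)) + 0.5
}

#' The decaying healthy-patient mortality effect
#'
#' Patients electively operated for osteoarthritis have lower short-term
#' mortality than the general population. The effect is a relative risk
#' `RR(t) = 1 - (1 - RR0(age)) * exp(-t / tau)` that starts at
#' `RR0(age) = 1 - 0.7 * (age - 40) / 40` (clamped to `[0.3, 1]`, so 0.3 at
#' age 80 and larger effects for older patients) and decays exponentially to
#' 1 over the decade following surgery (`tau = 2.35` gives `RR(10) > 0.99`).
#'
#' @param tau decay time constant in years.
#' @param slope,anchor_age,floor parameters of the initial relative risk
#'   schedule `RR0(a) = 1 - slope * (a - 40) / 40`, clamped to
#'   `[floor, 1]`.
#' @return Object of class `healthy_patient_effect`.
#' @export
healthy_patient_effect <- function(tau = 2.35, slope = 0.7,
                                   anchor_age = 40, floor = 0.3) {
  stopifnot(tau > 0, floor > 0, floor <= 1)
  structure(list(tau = tau, slope = slope, anchor_age = anchor_age,
                 floor = floor),
            class = "healthy_patient_effect")
}

#' Initial relative risk of the healthy-patient effect
#'
#' @param effect a [healthy_patient_effect()].
#' @param age age at surgery.
#' @return `RR0(age)` in `[floor, 1]`.
#' @export
initial_relative_risk <- function(effect, age) {
  stopifnot(inherits(effect, "healthy_patient_effect"))
  pmin(pmax(1 - effect$slope * (age - effect$anchor_age) / 40,
            effect$floor), 1)
}

#' Relative mortality risk t years after surgery
#'
#' @inheritParams initial_relative_risk
#' @param age_at_surgery age when the primary TKR was performed.
#' @param years_since_surgery time since surgery (years, `>= 0`).
#' @return `RR(t) = 1 - (1 - RR0) * exp(-t / tau)`, non-decreasing in `t`
#'   and bounded by 1.
#' @export
relative_risk <- function(effect, age_at_surgery, years_since_surgery) {
  rr0 <- initial_relative_risk(effect, age_at_surgery)
  1 - (1 - rr0) * exp(-years_since_surgery / effect$tau)
}

#' Adjusted annual death probability
#'
#' Life-table mortality at the attained age, multiplied by the decaying
#' healthy-patient relative risk and capped to `[0, 1]`. Attained ages past
#' the end of the table are treated as certain death.
#'
#' @param life_table a life table ([default_life_table()] format).
#' @param effect a [healthy_patient_effect()] (or `NULL` for none).
#' @param age_at_surgery age at the primary operation.
#' @param sex `"M"` or `"F"`.
#' @param years_since_surgery vector of elapsed years (`>= 0`).
#' @return Adjusted death probabilities, one per element of
#'   `years_since_surgery`.
#' @export
adjusted_mortality <- function(life_table, effect, age_at_surgery, sex,
                               years_since_surgery) {
  lt <- life_table[life_table$sex == sex, ]
  if (age_at_surgery < min(lt$age)) {
    stop("age ", age_at_surgery, " below the start of the life table")
  }
  ages <- age_at_surgery + years_since_surgery
  q <- lt$qx[match(pmin(ages, max(lt$age)), lt$age)]
  q[ages >= max(lt$age)] <- 1
  rr <- if (is.null(effect)) 1 else {
    relative_risk(effect, age_at_surgery, years_since_surgery)
  }
  pmin(pmax(q * rr, 0), 1)
}

#' Operative mortality after primary TKR
#'
#' The probability of death in the immediate post-operative period. No
#' difference across prosthesis brands was found, so a single configurable
#' constant applies to every brand.
#'
#' @param brand ignored (kept in the signature to document brand
#'   independence).
#' @param value the probability (default 0.002).
#' @return `value`, for any brand.
#' @export
operative_mortality <- function(brand = NULL, value = 0.002) {
  stopifnot(value >= 0, value <= 1)
  value
}
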