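# Revision-hazard models: restricted cubic spline on the log cumulative
# hazard (flexible parametric / Royston-Parmar, via flexsurv) with case-mix
# adjustment and extrapolation; piecewise-constant models for re-revisions
# and for the piecewise sensitivity scenario.

default_survival_covariates <- function() {
  c("sex", "age_c", "asa3", "bmi_c", "patella_replaced", "antibiotic_cement",
    "senior_surgeon", "treatment_centre")
}

prepare_survival_data <- function(d) {
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, levels = c("M", "F"))
  if ("age" %in% names(d)) d$age_c <- d$age - 70
  if ("asa_grade" %in% names(d)) d$asa3 <- as.numeric(d$asa_grade == 3)
  if ("bmi" %in% names(d)) d$bmi_c <- d$bmi - mean(d$bmi)
  d
}

#' Fit the restricted-cubic-spline revision-hazard model
#'
#' Maximum-likelihood fit of a flexible parametric survival model: the log
#' cumulative revision hazard is a restricted cubic spline in log time plus
#' linear covariate effects (proportional hazards). Beyond the boundary
#' knots the spline continues linearly in log time, which provides the
#' extrapolation of revision rates past the observed follow-up.
#'
#' Internal knots are placed at evenly spaced quantiles of the uncensored
#' log event times spanning the 10th to 90th percentile (so three internal
#' knots sit at the 10th/50th/90th).
#'
#' @param followups data.frame with columns `time_to_event`, `event` and the
#'   covariates (`sex`, `age`, `asa_grade`, `bmi`, `patella_replaced`,
#'   `antibiotic_cement`, `senior_surgeon`, `treatment_centre`).
#' @param covariates covariate terms after preparation (`age_c` is age - 70,
#'   `bmi_c` is centered BMI, `asa3` the ASA-3 indicator). Use `NULL` for an
#'   unadjusted fit.
#' @param n_internal_knots number of internal knots (default 3).
#' @return Object of class `rcs_hazard` with the spline coefficients
#'   (`gamma`), covariate log hazard ratios (`beta`), the joint covariance,
#'   knot locations on log time, covariate means used for reference
#'   predictions, and the underlying flexsurv fit.
#' @export
fit_rcs_hazard <- function(followups,
                           covariates = default_survival_covariates(),
                           n_internal_knots = 3) {
  d <- prepare_survival_data(followups)
  # drop covariates without variation, and binary covariates whose events
  # all fall in one level (separation: the log hazard ratio diverges)
  bad <- vapply(covariates, function(v) {
    x <- d[[v]]
    if (length(unique(x)) < 2) return(TRUE)
    if (length(unique(x)) == 2) {
      return(length(unique(x[d$event == 1])) < 2)
    }
    FALSE
  }, logical(1))
  if (any(bad)) {
    message("dropping covariate(s) without variation or with separated ",
            "events: ", paste(covariates[bad], collapse = ", "))
    covariates <- covariates[!bad]
  }
  ut <- d$time_to_event[d$event == 1]
  if (length(unique(ut)) < n_internal_knots + 2) {
    stop("need at least ", n_internal_knots + 2,
         " distinct uncensored event times")
  }
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  form <- as.formula(paste("survival::Surv(time_to_event, event) ~", rhs))
  knots <- if (n_internal_knots > 0) {
    quantile(log(ut), probs = seq(0.1, 0.9,
                                  length.out = n_internal_knots))
  } else {
    NULL
  }
  fit <- flexsurv::flexsurvspline(form, data = d, knots = knots,
                                  scale = "hazard")
  if (!is.null(fit$opt$convergence) && fit$opt$convergence != 0) {
    stop("spline hazard model did not converge")
  }
  np <- n_internal_knots + 2
  co <- coef(fit)
  mm <- if (length(covariates)) {
    model.matrix(as.formula(paste("~", rhs)), d)[, -1, drop = FALSE]
  } else {
    matrix(numeric(0), nrow(d), 0)
  }
  obj <- structure(list(
    gamma = co[seq_len(np)],
    beta = if (length(co) > np) co[-seq_len(np)] else numeric(0),
    cov = fit$cov,
    knots = fit$knots,
    k = n_internal_knots,
    covariates = covariates,
    mm_means = if (ncol(mm)) colMeans(mm) else numeric(0),
    max_followup = max(d$time_to_event),
    loglik = fit$loglik,
    n = nrow(d), n_events = sum(d$event),
    fit = fit
  ), class = "rcs_hazard")
  # warn if the fitted cumulative hazard is non-monotone within follow-up
  tt <- seq(0.05, obj$max_followup, length.out = 200)
  H <- spline_cumhaz(obj, tt)
  if (any(diff(H) < -1e-9)) {
    warning("fitted log cumulative hazard is non-monotone within the ",
            "observed range")
  }
  obj
}

# covariate row for a reference prediction: everything at its observed mean,
# sex and age overridden
rcs_covariate_row <- function(model, sex, age) {
  x <- model$mm_means
  if ("sexF" %in% names(x)) x["sexF"] <- as.numeric(sex == "F")
  if ("age_c" %in% names(x)) x["age_c"] <- age - 70
  x
}

# cumulative hazard H(t | x) from the spline parameters (pars optionally
# replaces c(gamma, beta), as in PSA draws)
spline_cumhaz <- function(model, t, sex = NULL, age = NULL, pars = NULL) {
  np <- model$k + 2
  if (is.null(pars)) pars <- c(model$gamma, model$beta)
  gamma <- pars[seq_len(np)]
  beta <- if (length(pars) > np) pars[-seq_len(np)] else numeric(0)
  eta <- drop(flexsurv::basis(model$knots, log(t)) %*% gamma)
  if (length(beta)) {
    x <- if (is.null(sex)) model$mm_means else rcs_covariate_row(model, sex,
                                                                 age)
    eta <- eta + sum(x * beta)
  }
  exp(eta)
}

#' Predicted cumulative revision probability
#'
#' `1 - S(t | x)` from a fitted [fit_rcs_hazard()] model, with covariates at
#' their observed means and sex/age as requested. Times beyond the last
#' boundary knot use the linear-tail extrapolation of the restricted spline.
#'
#' @param model an `rcs_hazard` fit.
#' @param t time(s) in years, `> 0`.
#' @param sex `"M"` or `"F"`.
#' @param age age at surgery in years.
#' @param pars optional replacement parameter vector `c(gamma, beta)` (PSA).
#' @return Cumulative revision probabilities, same length as `t`.
#' @export
predict_cumulative_revision <- function(model, t, sex = "F", age = 70,
                                        pars = NULL) {
  stopifnot(inherits(model, "rcs_hazard"))
  if (any(t <= 0)) stop("t must be > 0")
  1 - exp(-spline_cumhaz(model, t, sex, age, pars))
}

#' Annual revision transition probabilities for the Markov model
#'
#' Converts the fitted revision-free survival curve into per-cycle
#' conditional revision probabilities
#' `p_t = (S(t-1) - S(t)) / S(t-1)` for `t = 1..horizon`.
#'
#' @inheritParams predict_cumulative_revision
#' @param horizon number of annual cycles (default 45).
#' @return Numeric vector of length `horizon`, all values in `[0, 1]`.
#' @export
annual_transition_probs <- function(model, sex = "F", age = 70,
                                    horizon = 45, pars = NULL) {
  stopifnot(inherits(model, "rcs_hazard"))
  H <- spline_cumhaz(model, seq_len(horizon), sex, age, pars)
  S <- c(1, exp(-H))
  p <- ifelse(S[-length(S)] > 0, 1 - S[-1] / S[-length(S)], 1)
  pmin(pmax(p, 0), 1)
}

#' @export
print.rcs_hazard <- function(x, ...) {
  cat("Restricted-cubic-spline revision hazard model\n")
  cat("  n =", x$n, "(", x$n_events, "events ), internal knots:", x$k, "\n")
  cat("  max follow-up:", round(x$max_followup, 2), "years\n")
  if (length(x$beta)) {
    cat("  log hazard ratios:\n")
    print(round(x$beta, 3))
  }
  invisible(x)
}

#' Fit the piecewise-constant re-revision model
#'
#' Maximum-likelihood piecewise-exponential rates differentiating only the
#' first year after revision from all subsequent years:
#' `rate_k = events_k / person-years_k`.
#'
#' @param followups data.frame with `time_to_event` (years since revision)
#'   and `event`.
#' @return Object of class `piecewise_rerevision` with the two rates, event
#'   counts, person-years, and standard errors of the log rates.
#' @export
fit_piecewise_rerevision <- function(followups) {
  t <- followups$time_to_event
  e <- followups$event
  py <- c(year1 = sum(pmin(t, 1)), later = sum(pmax(t - 1, 0)))
  ev <- c(year1 = sum(e[t <= 1]), later = sum(e[t > 1]))
  if (py["year1"] <= 0) stop("zero person-years in year 1")
  rates <- c(year1 = unname(ev["year1"] / py["year1"]),
             later = if (py["later"] > 0) {
               unname(ev["later"] / py["later"])
             } else {
               0
             })
  if (any(ev == 0)) {
    warning("no events in piece(s): ",
            paste(names(ev)[ev == 0], collapse = ", "), "; rate set to 0")
  }
  structure(list(rates = rates, events = ev, person_years = py,
                 se_log = ifelse(ev > 0, 1 / sqrt(ev), NA_real_)),
            class = "piecewise_rerevision")
}

#' @export
print.piecewise_rerevision <- function(x, ...) {
  cat("Piecewise-constant re-revision model\n")
  print(data.frame(piece = names(x$rates), rate = round(x$rates, 5),
                   events = as.integer(x$events),
                   person_years = round(x$person_years, 1),
                   row.names = NULL))
  invisible(x)
}

#' Fit a general piecewise-constant revision hazard
#'
#' Piecewise-exponential rates on intervals defined by `cuts` (upper bounds
#' of each piece except the last, which extends to infinity: the rate of the
#' final observed interval is carried forward for extrapolation). Used by
#' the piecewise sensitivity scenario in place of the spline model.
#'
#' @param followups data.frame with `time_to_event`, `event`.
#' @param cuts increasing vector of interval boundaries (years); default
#'   integer years up to the maximum observed follow-up.
#' @return Object of class `piecewise_hazard`.
#' @export
fit_piecewise_hazard <- function(followups, cuts = NULL) {
  t <- followups$time_to_event
  e <- followups$event
  if (is.null(cuts)) cuts <- seq_len(max(1, floor(max(t))))
  lo <- c(0, cuts)
  hi <- c(cuts, Inf)
  py <- ev <- numeric(length(lo))
  for (i in seq_along(lo)) {
    py[i] <- sum(pmin(pmax(t - lo[i], 0), hi[i] - lo[i]))
    ev[i] <- sum(e[t > lo[i] & t <= hi[i]])
  }
  rates <- ifelse(py > 0, ev / py, 0)
  structure(list(cuts = cuts, rates = rates, events = ev, person_years = py,
                 se_log = ifelse(ev > 0, 1 / sqrt(ev), NA_real_)),
            class = "piecewise_hazard")
}

# cumulative hazard of a piecewise_hazard at times t (carry last rate)
piecewise_cumhaz <- function(model, t, rates = NULL) {
  if (is.null(rates)) rates <- model$rates
  lo <- c(0, model$cuts)
  hi <- c(model$cuts, Inf)
  vapply(t, function(tt) {
    sum(rates * pmin(pmax(tt - lo, 0), hi - lo))
  }, numeric(1))
}

#' Annual transition probabilities from a piecewise-constant model
#'
#' @param model a [fit_piecewise_hazard()] result.
#' @param horizon number of annual cycles.
#' @param rates optional replacement rate vector (PSA).
#' @return Numeric vector of length `horizon`.
#' @export
annual_transition_probs_piecewise <- function(model, horizon = 45,
                                              rates = NULL) {
  stopifnot(inherits(model, "piecewise_hazard"))
  H <- piecewise_cumhaz(model, 0:horizon, rates)
  S <- exp(-H)
  p <- ifelse(S[-length(S)] > 0, 1 - S[-1] / S[-length(S)], 1)
  pmin(pmax(p, 0), 1)
}
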