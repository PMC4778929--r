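# Synthetic registry generator: linked PROMs-style QOL records and NJR-style
# revision follow-up with a serializable ground truth for parameter recovery.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# E[clamp(N(mu, s), L, U)], closed form
clamped_normal_mean <- function(mu, s, L = eq5d_min(), U = eq5d_max()) {
  a <- (L - mu) / s
  b <- (U - mu) / s
  L * pnorm(a) + U * (1 - pnorm(b)) +
    mu * (pnorm(b) - pnorm(a)) - s * (dnorm(b) - dnorm(a))
}

# invert the clamped-normal mean: latent mu such that E[clamp(N(mu,s))] = target
latent_mean_for <- function(target, s, L = eq5d_min(), U = eq5d_max()) {
  vapply(target, function(tg) {
    uniroot(function(mu) clamped_normal_mean(mu, s, L, U) - tg,
            c(L - 4 * s, U + 4 * s), tol = 1e-12)$root
  }, numeric(1))
}

# Two-piece hazard (year 1 elevated, then constant) hitting cumulative
# incidence p5 at 5y and p10 at 10y exactly.
twopiece_from_targets <- function(p5, p10) {
  if (any(p10 >= 1) || any(p5 >= 1)) {
    stop("cumulative incidence targets must be < 1")
  }
  if (any(p10 < p5)) stop("10-year target must be >= 5-year target")
  H5 <- -log(1 - p5)
  H10 <- -log(1 - p10)
  h2 <- (H10 - H5) / 5
  h1 <- H5 - 4 * h2
  cbind(year1 = h1, later = h2)
}

# cumulative hazard of the two-piece model, with multiplier r
twopiece_cumhaz <- function(t, h1, h2) {
  h1 * pmin(t, 1) + h2 * pmax(t - 1, 0)
}

# inverse-transform sampling of an event time from the two-piece hazard
twopiece_sample <- function(n, h1, h2, r = 1) {
  Ht <- -log(runif(n)) / r
  h1 <- rep_len(h1, n)
  h2 <- rep_len(h2, n)
  tt <- Ht / h1                       # Inf when h1 == 0 (no events)
  late <- is.finite(Ht) & Ht > h1
  tt[late] <- ifelse(h2[late] > 0,
                     1 + (Ht[late] - h1[late]) / h2[late], Inf)
  tt
}

#' Configuration of the synthetic registry generator
#'
#' Bundles every parameter of the synthetic data-generating process. The
#' defaults are the study conditions the pipeline is calibrated to: a QOL
#' cohort of 53 126 patients across five brands with near-identical case mix,
#' brand effects on 6-month EQ-5D-3L of 0.01-0.04 relative to the reference
#' brand (AGC Biomet), brand- and sex-specific revision hazards hitting the
#' published 5- and 10-year cumulative revision rates exactly in the truth,
#' 17% missing post-operative outcomes, and a two-piece re-revision hazard.
#'
#' Brand assignment operates through a provider layer: each synthetic
#' hospital uses predominantly one brand (`brand_loyalty` of its patients),
#' and provider characteristics (independent-sector treatment centre,
#' consultant-led surgery) depend on the hospital's primary brand. Brand is
#' therefore correlated with provider flags but independent of patient case
#' mix given the provider, which makes confounding-by-provider estimable.
#'
#' @param n_patients QOL cohort size.
#' @param n_revision_patients revision-survival cohort size.
#' @param n_rerevision_patients re-revision cohort size.
#' @param n_revision_qol named vector: records informing the revision-year
#'   state (pre-operative data before a revision) and the post-revision state
#'   (6-month post-operative data after a revision).
#' @param brand_shares market shares over the five brands; must sum to 1.
#' @param brand_utility_effects observed-scale adjusted-mean EQ-5D-3L offsets
#'   per brand relative to AGC Biomet, in `[-1, 1]`.
#' @param utility_level adjusted post-operative EQ-5D-3L for the reference
#'   brand, men aged 70.
#' @param utility_sex_effect additive shift for women.
#' @param brand_oks_effects,oks_level,oks_sex_effect same structure for the
#'   Oxford Knee Score (reported in parallel; does not feed the Markov model).
#' @param noise_sd residual SD of the post-operative EQ-5D-3L around the
#'   case-mix linear predictor (before clamping to the instrument support).
#' @param oks_noise_sd residual SD of the post-operative OKS.
#' @param hazard_targets data.frame with columns `brand`, `p5_m`, `p10_m`,
#'   `p5_f`, `p10_f`, `max_followup`: cumulative revision targets by sex and
#'   the brand-specific administrative follow-up limit.
#' @param hazard_covariate_effects named log-hazard-ratio vector for the
#'   revision model case mix (centered covariates, so the brand x sex
#'   baselines are untouched).
#' @param missing_postop_rate proportion of post-operative PROMs set missing.
#' @param missing_mechanism `"MCAR"` or `"MAR"` (on observed covariates).
#' @param rerevision_rates named vector `c(year1=, later=)`: true re-revision
#'   hazards (per person-year) in the first year after revision vs later.
#' @param rerevision_max_followup administrative censoring for re-revisions.
#' @param state_utilities named vector: true EQ-5D-3L at age 70 in the
#'   revision-year and post-revision health states.
#' @param state_utility_age_slope,state_utility_sex_effect,state_noise_sd
#'   age slope (per year, centered at 70), additive effect for women, and
#'   residual SD of the state-utility records.
#' @param brand_loyalty probability a patient receives the hospital's primary
#'   brand (two thirds of English hospitals use a single brand for most
#'   patients).
#' @param hospital_size expected patients per synthetic hospital.
#' @param seed default seed used by the generator functions when they are not
#'   given one explicitly.
#'
#' @return An object of class `registry_config`.
#' @export
registry_config <- function(n_patients = 53126,
                            n_revision_patients = 239945,
                            n_rerevision_patients = 54134,
                            n_revision_qol = c(pre_revision = 6128,
                                               post_revision = 3912),
                            brand_shares = NULL,
                            brand_utility_effects = NULL,
                            utility_level = 0.72,
                            utility_sex_effect = -0.01,
                            brand_oks_effects = NULL,
                            oks_level = 35.4,
                            oks_sex_effect = -1.6,
                            noise_sd = 0.30,
                            oks_noise_sd = 6,
                            hazard_targets = NULL,
                            hazard_covariate_effects = c(age = -0.03,
                                                         asa3 = 0.15,
                                                         bmi = 0.01,
                                                         patella = -0.05,
                                                         cement = -0.10),
                            missing_postop_rate = 0.17,
                            missing_mechanism = "MAR",
                            rerevision_rates = c(year1 = 0.04, later = 0.015),
                            rerevision_max_followup = 15,
                            state_utilities = c(revision_year = 0.45,
                                                post_revision = 0.62),
                            state_utility_age_slope = -0.003,
                            state_utility_sex_effect = 0,
                            state_noise_sd = 0.28,
                            brand_loyalty = 0.85,
                            hospital_size = 300,
                            seed = NULL) {
  ref <- brand_reference()
  brands <- ref$brand
  if (is.null(brand_shares)) brand_shares <- setNames(ref$share, brands)
  if (is.null(brand_utility_effects)) {
    brand_utility_effects <- setNames(ref$eq5d_m - ref$eq5d_m[2], brands)
  }
  if (is.null(brand_oks_effects)) {
    brand_oks_effects <- setNames(ref$oks_m - ref$oks_m[2], brands)
  }
  if (is.null(hazard_targets)) {
    hazard_targets <- data.frame(
      brand = brands, p5_m = ref$rev5_m, p10_m = ref$rev10_m,
      p5_f = ref$rev5_f, p10_f = ref$rev10_f,
      max_followup = ref$max_followup, stringsAsFactors = FALSE
    )
  }

  if (length(n_patients) != 1 || n_patients <= 0) {
    stop("n_patients must be a positive count")
  }
  if (abs(sum(brand_shares) - 1) > 1e-8) stop("brand_shares must sum to 1")
  if (any(brand_utility_effects < -1 | brand_utility_effects > 1)) {
    stop("brand utility offsets must lie in [-1, 1]")
  }
  if (missing_postop_rate < 0 || missing_postop_rate > 1) {
    stop("missing_postop_rate must lie in [0, 1]")
  }
  if (!missing_mechanism %in% c("MCAR", "MAR")) {
    stop("unknown missingness mechanism: ", missing_mechanism)
  }
  if (any(rerevision_rates < 0)) stop("re-revision rates must be >= 0")
  # validates 5y/10y ordering and < 1
  invisible(twopiece_from_targets(
    c(hazard_targets$p5_m, hazard_targets$p5_f),
    c(hazard_targets$p10_m, hazard_targets$p10_f)
  ))

  structure(list(
    n_patients = as.integer(n_patients),
    n_revision_patients = as.integer(n_revision_patients),
    n_rerevision_patients = as.integer(n_rerevision_patients),
    n_revision_qol = n_revision_qol,
    brands = brands,
    brand_shares = brand_shares,
    brand_utility_effects = brand_utility_effects,
    utility_level = utility_level,
    utility_sex_effect = utility_sex_effect,
    brand_oks_effects = brand_oks_effects,
    oks_level = oks_level,
    oks_sex_effect = oks_sex_effect,
    noise_sd = noise_sd,
    oks_noise_sd = oks_noise_sd,
    hazard_targets = hazard_targets,
    hazard_covariate_effects = hazard_covariate_effects,
    missing_postop_rate = missing_postop_rate,
    missing_mechanism = missing_mechanism,
    rerevision_rates = rerevision_rates,
    rerevision_max_followup = rerevision_max_followup,
    state_utilities = state_utilities,
    state_utility_age_slope = state_utility_age_slope,
    state_utility_sex_effect = state_utility_sex_effect,
    state_noise_sd = state_noise_sd,
    brand_loyalty = brand_loyalty,
    hospital_size = hospital_size,
    seed = seed
  ), class = "registry_config")
}

#' @export
print.registry_config <- function(x, ...) {
  cat("Synthetic TKR registry configuration\n")
  cat("  QOL cohort:       ", x$n_patients, "patients,",
      round(100 * x$missing_postop_rate), "% post-op PROMs missing (",
      x$missing_mechanism, ")\n")
  cat("  Revision cohort:  ", x$n_revision_patients, "patients\n")
  cat("  Re-revision cohort:", x$n_rerevision_patients, "patients\n")
  cat("  Brands:           ", paste(x$brands, collapse = ", "), "\n")
  invisible(x)
}

# provider layer shared by the cohort generators
sample_providers <- function(n, config) {
  cm <- case_mix_reference()
  n_hosp <- max(25L, as.integer(round(n / config$hospital_size)))
  primary <- sample(config$brands, n_hosp, replace = TRUE,
                    prob = config$brand_shares)
  idx <- match(primary, cm$brand)
  hosp_istc <- rbinom(n_hosp, 1, cm$istc[idx])
  hosp_consultant <- clamp(rnorm(n_hosp, cm$consultant[idx], 0.05), 0.05, 0.99)
  hospital <- sample.int(n_hosp, n, replace = TRUE)
  loyal <- runif(n) < config$brand_loyalty
  brand <- ifelse(loyal, primary[hospital],
                  sample(config$brands, n, replace = TRUE,
                         prob = config$brand_shares))
  list(hospital = hospital, brand = brand,
       istc = hosp_istc[hospital],
       consultant = rbinom(n, 1, hosp_consultant[hospital]))
}

# case-mix block shared by the QOL and revision cohorts
sample_case_mix <- function(brand, cm) {
  n <- length(brand)
  i <- match(brand, cm$brand)
  age <- clamp(rnorm(n, cm$age_mean[i], cm$age_sd), 55, 84)
  sex <- ifelse(runif(n) < cm$male[i], "M", "F")
  bmi <- clamp(rnorm(n, cm$bmi_mean[i], cm$bmi_sd[i]), 15, 60)
  comorbidity_count <- rpois(n, 1.07)
  asa_grade <- ifelse(runif(n) < cm$asa3[i], 3L,
                      ifelse(runif(n) < 0.18, 1L, 2L))
  # quintile 5 = most deprived, matched to the per-brand deprived share
  p5 <- cm$deprived[i]
  u <- runif(n)
  imd_quintile <- as.integer(pmin(
    ifelse(u < p5, 5, 1 + floor((u - p5) / (1 - p5) * 4)), 5))
  preop_eq5d <- clamp(rnorm(n, cm$preop_eq5d_mean[i], cm$preop_eq5d_sd),
                      eq5d_min(), eq5d_max())
  preop_oks <- as.integer(round(clamp(rnorm(n, cm$preop_oks_mean[i],
                                            cm$preop_oks_sd[i]), 0, 48)))
  data.frame(age = age, sex = sex, comorbidity_count = comorbidity_count,
             asa_grade = asa_grade, bmi = bmi, imd_quintile = imd_quintile,
             patella_replaced = rbinom(n, 1, 0.35),
             disability = rbinom(n, 1, 0.25),
             surgical_position = rbinom(n, 1, 0.10),
             preop_eq5d = preop_eq5d, preop_oks = preop_oks,
             stringsAsFactors = FALSE)
}

# latent case-mix coefficients of the post-operative EQ-5D-3L truth
qol_truth_coefs <- function() {
  c(age = -0.003, preop_eq5d = 0.35, preop_oks = 0.012, bmi = -0.002,
    comorbidity_count = -0.015, asa3 = -0.03, asa1 = 0.01,
    imd_quintile = -0.008, patella_replaced = 0, disability = -0.04,
    surgical_position = 0, treatment_centre = 0.06, senior_surgeon = 0.02)
}

oks_truth_coefs <- function() {
  c(age = -0.05, preop_eq5d = 3.0, preop_oks = 0.35, bmi = -0.05,
    comorbidity_count = -0.3, asa3 = -0.8, asa1 = 0.2,
    imd_quintile = -0.2, patella_replaced = 0, disability = -1.0,
    surgical_position = 0, treatment_centre = 1.0, senior_surgeon = 0.3)
}

# centered case-mix linear predictor; returns the lp and the centering means
case_mix_lp <- function(d, coefs) {
  X <- cbind(preop_eq5d = d$preop_eq5d, preop_oks = d$preop_oks, bmi = d$bmi,
             comorbidity_count = d$comorbidity_count,
             asa3 = as.numeric(d$asa_grade == 3),
             asa1 = as.numeric(d$asa_grade == 1),
             imd_quintile = d$imd_quintile,
             patella_replaced = d$patella_replaced,
             disability = d$disability,
             surgical_position = d$surgical_position,
             treatment_centre = d$treatment_centre,
             senior_surgeon = d$senior_surgeon)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  list(lp = drop(Xc %*% coefs[colnames(X)]), means = mu)
}

#' Generate the synthetic PROMs-style QOL cohort
#'
#' Draws a cohort of patient records (case mix, provider flags, pre- and
#' post-operative EQ-5D-3L and OKS, length of stay) whose statistical
#' structure matches the study conditions: near-identical case mix across
#' brands, brand assignment driven by a provider layer, and post-operative
#' outcomes equal to a case-mix linear predictor plus Gaussian noise clamped
#' to the instrument support.
#'
#' Because the outcome is clamped, latent brand offsets are obtained by
#' inverting the clamped-normal mean at the total linear-predictor SD, so
#' that the *observed-scale* adjusted means and brand contrasts match the
#' configured targets (the published tables print observed-scale values).
#'
#' @param config a [registry_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return A list of class `proms_cohort` with elements `records`
#'   (data.frame, one row per patient) and `truth` (class `synthetic_truth`).
#' @export
generate_proms_cohort <- function(config = registry_config(), seed = NULL) {
  stopifnot(inherits(config, "registry_config"))
  seed <- if (is.null(seed)) config$seed else seed
  if (!is.null(seed)) set.seed(seed)

  n <- config$n_patients
  cm <- case_mix_reference()
  prov <- sample_providers(n, config)
  d <- sample_case_mix(prov$brand, cm)
  d$brand <- factor(prov$brand, levels = config$brands)
  d$hospital_id <- prov$hospital
  d$treatment_centre <- prov$istc
  d$senior_surgeon <- prov$consultant
  d$patient_id <- seq_len(n)
  female <- as.numeric(d$sex == "F")

  # EQ-5D-3L: calibrate latent offsets on the clamped-mean scale
  co <- qol_truth_coefs()
  cmx <- case_mix_lp(d, co)
  age_lp <- co["age"] * (d$age - 70)
  s_tot <- sqrt(config$noise_sd^2 + var(cmx$lp) + var(age_lp))
  mu_ref <- latent_mean_for(config$utility_level, s_tot)
  latent_offsets <- latent_mean_for(
    config$utility_level + config$brand_utility_effects, s_tot) - mu_ref
  latent_sex <- latent_mean_for(
    config$utility_level + config$utility_sex_effect, s_tot) - mu_ref
  lp <- mu_ref + latent_offsets[as.integer(d$brand)] + latent_sex * female +
    age_lp + cmx$lp
  d$postop_eq5d <- clamp(lp + rnorm(n, 0, config$noise_sd),
                         eq5d_min(), eq5d_max())

  # OKS: same structure, clamp [0, 48] (no latent correction: clamping is
  # negligible 1.7+ SD from both bounds)
  ko <- oks_truth_coefs()
  kmx <- case_mix_lp(d, ko)
  lp_oks <- config$oks_level + config$brand_oks_effects[as.integer(d$brand)] +
    config$oks_sex_effect * female + ko["age"] * (d$age - 70) + kmx$lp
  d$postop_oks <- as.integer(round(clamp(lp_oks +
                                           rnorm(n, 0, config$oks_noise_sd),
                                         0, 48)))

  # length of stay around the brand x sex reference means
  ref <- brand_reference()
  los_mean <- ifelse(d$sex == "M", ref$los_m, ref$los_f)[as.integer(d$brand)]
  d$los_days <- stats::rgamma(n, shape = 8, rate = 8 / los_mean)

  truth <- structure(list(
    brand_utility_effects = config$brand_utility_effects,
    latent_brand_offsets = setNames(latent_offsets, config$brands),
    utility_level = config$utility_level,
    utility_sex_effect = config$utility_sex_effect,
    latent_sex_effect = unname(latent_sex),
    qol_coefs = co,
    oks_coefs = ko,
    brand_oks_effects = config$brand_oks_effects,
    noise_sd = config$noise_sd,
    total_lp_sd = unname(s_tot),
    case_mix_means = cmx$means,
    state_utilities = config$state_utilities,
    state_utility_age_slope = config$state_utility_age_slope,
    state_utility_sex_effect = config$state_utility_sex_effect,
    rerevision_rates = config$rerevision_rates,
    missing_postop_rate = config$missing_postop_rate,
    missing_mechanism = config$missing_mechanism,
    seed = seed
  ), class = "synthetic_truth")

  cols <- c("patient_id", "hospital_id", "brand", "age", "sex",
            "comorbidity_count", "asa_grade", "bmi", "imd_quintile",
            "patella_replaced", "disability", "surgical_position",
            "senior_surgeon", "treatment_centre", "preop_eq5d", "preop_oks",
            "postop_eq5d", "postop_oks", "los_days")
  structure(list(records = d[, cols], truth = truth), class = "proms_cohort")
}

#' Set post-operative outcomes missing
#'
#' Marks post-operative EQ-5D-3L and OKS missing for a fraction of patients,
#' either completely at random (MCAR) or depending on observed covariates
#' (MAR: older age and lower pre-operative EQ-5D-3L increase the odds of a
#' missing 6-month questionnaire; the intercept is solved so the expected
#' missing fraction equals `rate`).
#'
#' @param records a `proms_cohort` records data.frame.
#' @param rate target missing proportion in `[0, 1]`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param seed optional integer seed.
#' @return The records with `postop_eq5d`/`postop_oks` set `NA`; the realized
#'   missing indicator is returned in attribute `"missing"`.
#' @export
inject_missingness <- function(records, rate = 0.17,
                               mechanism = c("MAR", "MCAR"), seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  if (rate == 0) {
    attr(records, "missing") <- rep(FALSE, n)
    return(records)
  }
  if (mechanism == "MCAR") {
    p <- rep(rate, n)
  } else {
    eta <- 0.4 * as.numeric(scale(records$age)) -
      0.3 * as.numeric(scale(records$preop_eq5d))
    a <- uniroot(function(a) mean(plogis(a + eta)) - rate, c(-20, 20),
                 tol = 1e-10)$root
    p <- plogis(a + eta)
  }
  miss <- runif(n) < p
  records$postop_eq5d[miss] <- NA_real_
  records$postop_oks[miss] <- NA_integer_
  attr(records, "missing") <- miss
  records
}

#' Generate synthetic revision-survival follow-up
#'
#' Draws NJR-style time-to-first-revision records. The true hazard is
#' two-piece within follow-up (an elevated early-failure rate in year 1, then
#' constant), stratified by brand and sex and solved so that the cumulative
#' revision incidence at 5 and 10 years equals the configured targets exactly
#' for a reference patient (age 70, other case mix at its mean). Case-mix
#' covariates act proportionally on the hazard. Censoring is administrative:
#' uniform accrual over the brand-specific maximum observation period.
#'
#' @inheritParams generate_proms_cohort
#' @return A list of class `revision_survival` with `records` (columns
#'   `patient_id`, `brand`, case mix, `antibiotic_cement`, `time_to_event`,
#'   `event`) and `truth` (two-piece rates per brand x sex, covariate
#'   effects, centering means).
#' @export
generate_revision_survival <- function(config = registry_config(),
                                       seed = NULL) {
  stopifnot(inherits(config, "registry_config"))
  seed <- if (is.null(seed)) config$seed else seed
  if (!is.null(seed)) set.seed(seed)

  n <- config$n_revision_patients
  cm <- case_mix_reference()
  prov <- sample_providers(n, config)
  d <- sample_case_mix(prov$brand, cm)
  d$brand <- factor(prov$brand, levels = config$brands)
  d$treatment_centre <- prov$istc
  d$senior_surgeon <- prov$consultant
  d$antibiotic_cement <- rbinom(n, 1, 0.85)
  d$patient_id <- seq_len(n)

  tg <- config$hazard_targets
  hm <- twopiece_from_targets(tg$p5_m, tg$p10_m)
  hf <- twopiece_from_targets(tg$p5_f, tg$p10_f)
  rownames(hm) <- rownames(hf) <- tg$brand

  eff <- config$hazard_covariate_effects
  X <- cbind(asa3 = as.numeric(d$asa_grade == 3), bmi = d$bmi,
             patella = d$patella_replaced, cement = d$antibiotic_cement)
  mu <- colMeans(X)
  lp <- eff["age"] * (d$age - 70) +
    drop(sweep(X, 2, mu) %*% eff[colnames(X)])
  r <- exp(lp)

  bi <- as.integer(d$brand)
  male <- d$sex == "M"
  h1 <- ifelse(male, hm[bi, "year1"], hf[bi, "year1"])
  h2 <- ifelse(male, hm[bi, "later"], hf[bi, "later"])
  T <- twopiece_sample(n, h1, h2, r)
  C <- runif(n, 0, tg$max_followup[bi])
  d$time_to_event <- pmin(T, C)
  d$event <- as.integer(T <= C)

  truth <- structure(list(
    hazard_men = hm, hazard_women = hf,
    hazard_targets = tg,
    covariate_effects = eff,
    covariate_means = mu,
    seed = seed
  ), class = "synthetic_truth")

  cols <- c("patient_id", "brand", "age", "sex", "asa_grade", "bmi",
            "patella_replaced", "antibiotic_cement", "senior_surgeon",
            "treatment_centre", "time_to_event", "event")
  structure(list(records = d[, cols], truth = truth),
            class = "revision_survival")
}

#' Generate synthetic re-revision follow-up
#'
#' Time from first revision to re-revision under a two-piece constant hazard
#' (first year vs all subsequent years), with uniform administrative
#' censoring.
#'
#' @inheritParams generate_proms_cohort
#' @return List of class `rerevision_survival` with `records` (`patient_id`,
#'   `time_to_event`, `event`) and `truth`.
#' @export
generate_rerevision <- function(config = registry_config(), seed = NULL) {
  stopifnot(inherits(config, "registry_config"))
  seed <- if (is.null(seed)) config$seed else seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_rerevision_patients
  r <- config$rerevision_rates
  T <- twopiece_sample(n, r["year1"], r["later"])
  C <- runif(n, 0, config$rerevision_max_followup)
  records <- data.frame(patient_id = seq_len(n),
                        time_to_event = pmin(T, C),
                        event = as.integer(T <= C))
  truth <- structure(list(rerevision_rates = r, seed = seed),
                     class = "synthetic_truth")
  structure(list(records = records, truth = truth),
            class = "rerevision_survival")
}

#' Generate synthetic revision-episode QOL records
#'
#' EQ-5D-3L observations informing the two revision health states: records
#' taken *before* a revision operation (parameterizing QOL in the year of
#' revision) and records taken six months *after* a revision (parameterizing
#' QOL in the post-revision state). Outcomes depend linearly on age and sex.
#'
#' @inheritParams generate_proms_cohort
#' @return List of class `revision_qol` with `records` (columns `timing`
#'   in `{pre_revision, post_revision}`, `age`, `sex`, `eq5d`) and `truth`.
#' @export
generate_revision_qol <- function(config = registry_config(), seed = NULL) {
  stopifnot(inherits(config, "registry_config"))
  seed <- if (is.null(seed)) config$seed else seed
  if (!is.null(seed)) set.seed(seed)
  mk <- function(n, timing) {
    age <- clamp(rnorm(n, 72, 8), 55, 95)
    female <- rbinom(n, 1, 0.56)
    mu <- config$state_utilities[[if (timing == "pre_revision")
      "revision_year" else "post_revision"]]
    eq5d <- clamp(mu + config$state_utility_age_slope * (age - 70) +
                    config$state_utility_sex_effect * female +
                    rnorm(n, 0, config$state_noise_sd),
                  eq5d_min(), eq5d_max())
    data.frame(timing = timing, age = age,
               sex = ifelse(female == 1, "F", "M"), eq5d = eq5d,
               stringsAsFactors = FALSE)
  }
  records <- rbind(mk(config$n_revision_qol[["pre_revision"]], "pre_revision"),
                   mk(config$n_revision_qol[["post_revision"]],
                      "post_revision"))
  truth <- structure(list(
    state_utilities = config$state_utilities,
    age_slope = config$state_utility_age_slope,
    sex_effect = config$state_utility_sex_effect,
    seed = seed
  ), class = "synthetic_truth")
  structure(list(records = records, truth = truth), class = "revision_qol")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth (", paste(names(x), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}
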