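# Case-mix-adjusted post-operative QOL by brand, QOL in the revision states,
# and the aging-related utility decline.

default_qol_covariates <- function() {
  c("sex", "age_c", "preop_eq5d", "preop_oks", "bmi", "comorbidity_count",
    "asa_grade", "imd_quintile", "patella_replaced", "disability",
    "surgical_position", "senior_surgeon", "treatment_centre")
}

# common data preparation: reference coding, centered age, FP columns
prepare_qol_data <- function(d, reference, fp = NULL) {
  d$brand <- stats::relevel(factor(d$brand, levels = tkr_brands()),
                            ref = reference)
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, levels = c("M", "F"))
  if ("asa_grade" %in% names(d)) d$asa_grade <- factor(d$asa_grade)
  if ("age" %in% names(d)) d$age_c <- d$age - 70
  if (!is.null(fp)) {
    for (v in names(fp)) {
      sel <- fp[[v]]
      if (sel$chosen %in% c("linear", "omit")) next
      tm <- fp_transform(sel, d[[v]])
      for (j in seq_len(ncol(tm))) d[[colnames(tm)[j]]] <- tm[, j]
    }
  }
  d
}

# covariate list after substituting FP basis columns
apply_fp_to_covariates <- function(covariates, fp) {
  if (is.null(fp)) return(covariates)
  for (v in names(fp)) {
    sel <- fp[[v]]
    if (sel$chosen %in% c("linear", "omit")) next
    nb <- if (sel$chosen == "quadratic" || length(sel$powers) == 2) 2 else 1
    covariates <- setdiff(covariates, c(v, if (v == "age") "age_c"))
    covariates <- c(covariates, paste0(v, "..", seq_len(nb)))
  }
  covariates
}

fit_qol_single <- function(d, outcome, covariates, reference, fp,
                           extra_terms) {
  d <- prepare_qol_data(d, reference, fp)
  novar <- vapply(intersect(covariates, names(d)), function(v) {
    length(unique(d[[v]])) < 2
  }, logical(1))
  if (any(novar)) {
    message("dropping covariate(s) without variation: ",
            paste(names(novar)[novar], collapse = ", "))
    covariates <- setdiff(covariates, names(novar)[novar])
  }
  covariates <- apply_fp_to_covariates(covariates, fp)
  rhs <- paste(c("brand", covariates, extra_terms), collapse = " + ")
  form <- as.formula(paste(outcome, "~", rhs))
  mf <- model.frame(form, d)
  mm <- model.matrix(form, mf)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- lm(form, data = d)
  list(coef = coef(fit), vcov = vcov(fit),
       sigma = summary(fit)$sigma, df = fit$df.residual,
       mm_means = colMeans(mm), n = nrow(mm))
}

#' Fit the case-mix-adjusted post-operative QOL model
#'
#' Ordinary least squares of a post-operative outcome (EQ-5D-3L index by
#' default; the OKS in parallel for reporting) on prosthesis brand and the
#' pre-operative case mix and provider characteristics. When given an
#' [impute_chained()] result, the model is fitted on every completed dataset
#' and coefficients and covariance are pooled by Rubin's rules.
#'
#' @param data data.frame without missing values in the modelled columns, or
#'   an `imputation_set`.
#' @param outcome outcome column (default `"postop_eq5d"`).
#' @param covariates adjustment terms; `age_c` is age centered at 70 (added
#'   automatically).
#' @param reference reference brand for contrasts (default AGC Biomet, the
#'   lowest-cost brand).
#' @param fp optional named list of [select_fractional_polynomial()] results;
#'   chosen non-linear transforms replace the corresponding linear terms.
#' @param extra_terms additional formula terms, e.g.
#'   `c("brand:age_c", "brand:sex")` for the interaction scenario.
#' @return Object of class `qol_fit` with pooled `coefficients`, `vcov`,
#'   residual `sigma`, the model-matrix column means (used to hold other
#'   covariates at their observed means when predicting subgroups), and the
#'   number of imputations pooled (`m`).
#' @export
fit_postop_qol <- function(data, outcome = "postop_eq5d",
                           covariates = default_qol_covariates(),
                           reference = "AGC Biomet", fp = NULL,
                           extra_terms = NULL) {
  if (inherits(data, "imputation_set")) {
    fits <- lapply(data$imputations, fit_qol_single, outcome = outcome,
                   covariates = covariates, reference = reference, fp = fp,
                   extra_terms = extra_terms)
    est <- do.call(rbind, lapply(fits, `[[`, "coef"))
    pooled <- pool_rubin(est, lapply(fits, `[[`, "vcov"))
    f1 <- fits[[1]]
    out <- list(coefficients = pooled$estimate, vcov = pooled$variance,
                sigma = mean(vapply(fits, `[[`, numeric(1), "sigma")),
                df = f1$df,
                mm_means = colMeans(do.call(rbind,
                                            lapply(fits, `[[`, "mm_means"))),
                n = f1$n, m = data$m)
  } else {
    if (anyNA(data[, intersect(c(outcome, "age", covariates), names(data))])) {
      stop("missing values in modelled columns; impute first ",
           "(impute_chained) or subset to complete cases")
    }
    f1 <- fit_qol_single(data, outcome, covariates, reference, fp,
                         extra_terms)
    out <- list(coefficients = f1$coef, vcov = f1$vcov, sigma = f1$sigma,
                df = f1$df, mm_means = f1$mm_means, n = f1$n, m = 1L)
  }
  out$outcome <- outcome
  out$reference <- reference
  out$fp <- fp
  out$brands <- tkr_brands()
  structure(out, class = "qol_fit")
}

#' @export
print.qol_fit <- function(x, ...) {
  cat("Case-mix-adjusted QOL model (", x$outcome, "), n = ", x$n,
      if (x$m > 1) paste0(", pooled over ", x$m, " imputations"), "\n",
      sep = "")
  ct <- brand_contrasts(x)
  print(round(ct, 4))
  invisible(x)
}

#' Brand contrasts of a fitted QOL model
#'
#' @param fit a `qol_fit`.
#' @return data.frame with the estimated outcome contrast of every non-
#'   reference brand against the reference, and its standard error.
#' @export
brand_contrasts <- function(fit) {
  stopifnot(inherits(fit, "qol_fit"))
  nm <- names(fit$coefficients)
  bc <- nm[startsWith(nm, "brand") & !grepl(":", nm)]
  data.frame(
    brand = sub("^brand", "", bc),
    estimate = unname(fit$coefficients[bc]),
    se = sqrt(diag(fit$vcov)[bc]),
    row.names = NULL
  )
}

# model-matrix row for a given brand/sex/age with every other covariate held
# at its observed mean (factor columns at their observed shares)
subgroup_row <- function(fit, brand, sex, age) {
  x <- fit$mm_means
  nm <- names(x)
  base <- nm[!grepl(":", nm)]
  bcols <- base[startsWith(base, "brand")]
  x[bcols] <- 0
  if (brand != fit$reference) {
    bc <- paste0("brand", brand)
    if (!bc %in% nm) stop("unknown brand: ", brand)
    x[bc] <- 1
  }
  if ("sexF" %in% nm) x["sexF"] <- as.numeric(sex == "F")
  if ("age_c" %in% nm) x["age_c"] <- age - 70
  if (!is.null(fit$fp) && "age" %in% names(fit$fp) &&
      !fit$fp[["age"]]$chosen %in% c("linear", "omit")) {
    tm <- fp_transform(fit$fp[["age"]], age)
    x[colnames(tm)] <- tm[1, ]
  }
  for (cn in nm[grepl(":", nm)]) {     # rebuild interaction columns
    parts <- strsplit(cn, ":", fixed = TRUE)[[1]]
    if (all(parts %in% nm)) x[cn] <- prod(x[parts])
  }
  x
}

#' Predict post-operative QOL for a patient subgroup
#'
#' Point prediction and standard error for a given brand, sex and age at
#' surgery, with all other covariates held at their observed means (the
#' subgroup-profile prediction used to populate the decision model).
#'
#' @param fit a [fit_postop_qol()] result.
#' @param brand,sex,age vectors (recycled); ages outside \{60, 70, 80\}
#'   require `allow_any_age = TRUE`.
#' @param allow_any_age permit ages outside the three reporting ages.
#' @return data.frame with columns `brand`, `sex`, `age`, `fit`, `se`.
#' @export
predict_subgroup_qol <- function(fit, brand, sex, age,
                                 allow_any_age = FALSE) {
  stopifnot(inherits(fit, "qol_fit"))
  k <- max(length(brand), length(sex), length(age))
  brand <- rep_len(brand, k); sex <- rep_len(sex, k); age <- rep_len(age, k)
  if (!allow_any_age && !all(age %in% c(60, 70, 80))) {
    stop("age must be one of 60, 70, 80 (set allow_any_age = TRUE to ",
         "override)")
  }
  X <- t(vapply(seq_len(k),
                function(i) subgroup_row(fit, brand[i], sex[i], age[i]),
                numeric(length(fit$mm_means))))
  est <- drop(X %*% fit$coefficients)
  se <- sqrt(rowSums((X %*% fit$vcov) * X))
  data.frame(brand = brand, sex = sex, age = age, fit = est, se = se,
             stringsAsFactors = FALSE)
}

#' Fit the QOL model for a revision health state
#'
#' Linear regression of the EQ-5D-3L index on age and sex among revision
#' episodes: records taken before the revision operation parameterize QOL in
#' the year of revision (`timing = "pre_revision"`); 6-month post-operative
#' records after a revision parameterize the post-revision state
#' (`timing = "post_revision"`).
#'
#' @param revision_records data.frame with columns `timing`, `age`, `sex`,
#'   `eq5d`.
#' @param timing which state to fit.
#' @param min_n minimum number of records required.
#' @return Object of class `state_qol_fit`.
#' @export
fit_state_qol <- function(revision_records,
                          timing = c("pre_revision", "post_revision"),
                          min_n = 50) {
  timing <- match.arg(timing)
  d <- revision_records[revision_records$timing == timing, , drop = FALSE]
  if (nrow(d) < min_n) {
    stop("only ", nrow(d), " records for timing '", timing,
         "' (minimum ", min_n, ")")
  }
  d$sex <- factor(d$sex, levels = c("M", "F"))
  d$age_c <- d$age - 70
  fit <- lm(eq5d ~ age_c + sex, data = d)
  structure(list(coefficients = coef(fit), vcov = vcov(fit),
                 sigma = summary(fit)$sigma, n = nrow(d), timing = timing),
            class = "state_qol_fit")
}

#' Predict a revision-state utility by age and sex
#'
#' @param fit a [fit_state_qol()] result.
#' @param age,sex vectors (recycled).
#' @param coefficients optional replacement coefficient vector (used by the
#'   probabilistic sensitivity analysis).
#' @return data.frame with `age`, `sex`, `fit`, `se`.
#' @export
predict_state_qol <- function(fit, age, sex, coefficients = NULL) {
  stopifnot(inherits(fit, "state_qol_fit"))
  k <- max(length(age), length(sex))
  age <- rep_len(age, k); sex <- rep_len(sex, k)
  X <- cbind(1, age - 70, as.numeric(sex == "F"))
  beta <- if (is.null(coefficients)) fit$coefficients else coefficients
  est <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% fit$vcov) * X))
  data.frame(age = age, sex = sex, fit = est, se = se,
             stringsAsFactors = FALSE)
}

#' @export
print.state_qol_fit <- function(x, ...) {
  cat("Revision-state QOL model (", x$timing, "), n = ", x$n, "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Per-cycle aging-related utility reduction
#'
#' The annual decline in the EQ-5D-3L tariff grows quadratically with age and
#' equals 0.004 at age 70: `decline(a) = 0.004 * (a / 70)^2`.
#'
#' @param age age in years.
#' @return The utility reduction applied over one model cycle at that age.
#' @export
aging_decline <- function(age) 0.004 * (age / 70)^2

#' Apply one cycle of aging-related utility decline
#'
#' Subtracts [aging_decline()] at the given age and floors the result at the
#' EQ-5D-3L instrument minimum (-0.594).
#'
#' @param utility current utility value(s).
#' @param age age in years.
#' @return Utility for the next cycle.
#' @export
apply_aging_decline <- function(utility, age) {
  pmax(utility - aging_decline(age), eq5d_min())
}
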