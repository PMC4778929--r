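# End-to-end orchestration: simulate -> fit -> evaluate, with a single
# configuration object, seeds recorded in every manifest, and JSON
# serialization of the fitted models.

#' Default run configuration
#'
#' A single editable list holding every pipeline default: registry sizes,
#' imputation settings, fractional-polynomial candidates, PSA settings, the
#' reported subgroups, and mortality/cost constants.
#'
#' @param ... named overrides of top-level entries.
#' @return Object of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 20160304,
    registry = list(),        # overrides passed to registry_config()
    imputation = list(m = 20, maxit = 10),
    fp_covariates = c("age", "bmi", "preop_oks"),
    psa = list(n_sims = 1000, lambda = 20000,
               lambda_grid = list(from = 0, to = 50000, by = 500)),
    subgroups = list(sex = c("M", "F"), age = c(60, 70, 80)),
    op_mortality = 0.002,
    costs = unit_costs(),
    scenarios = integer(0)
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), cfg$imputation$m >= 1,
            cfg$psa$n_sims >= 1,
            all(cfg$subgroups$sex %in% c("M", "F")))
  if (cfg$psa$lambda < 0) stop("willingness-to-pay must be >= 0")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(utils::modifyList(unclass(default_run_config()),
                                        yaml::read_yaml(path)))
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate a complete synthetic registry
#'
#' Generates the PROMs cohort (with missing post-operative outcomes
#' injected), the revision and re-revision follow-up and the
#' revision-episode QOL records, and optionally writes them (plus truth and
#' data dictionary) as delimited text.
#'
#' @param config a [default_run_config()].
#' @param outdir optional output directory for [write_registry()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return List with `proms`, `revisions`, `rerevisions`, `revision_qol`
#'   generator outputs (each carrying its `truth`).
#' @export
cmd_simulate <- function(config = default_run_config(), outdir = NULL,
                         seed = config$seed) {
  rc <- do.call(registry_config, config$registry)
  proms <- generate_proms_cohort(rc, seed = seed)
  proms$records <- inject_missingness(proms$records,
                                      rate = rc$missing_postop_rate,
                                      mechanism = rc$missing_mechanism)
  registry <- list(
    proms = proms,
    revisions = generate_revision_survival(rc, seed = seed + 1L),
    rerevisions = generate_rerevision(rc, seed = seed + 2L),
    revision_qol = generate_revision_qol(rc, seed = seed + 3L)
  )
  if (!is.null(outdir)) write_registry(registry, outdir)
  registry
}

#' Fit every input model of the decision analysis
#'
#' Runs multiple imputation (skipped with a notice when nothing is
#' missing), fractional-polynomial selection for the configured continuous
#' covariates, the pooled case-mix-adjusted QOL models (EQ-5D-3L feeding
#' the decision model, OKS in parallel for reporting), the revision-state
#' QOL models, the per-brand restricted-cubic-spline revision models, and
#' the piecewise-constant re-revision model.
#'
#' @param data list with data.frames `proms`, `revisions`, `rerevisions`,
#'   `revision_qol` (as from [read_registry()], or the `records` elements of
#'   [cmd_simulate()] output).
#' @param config a [default_run_config()].
#' @param seed integer seed for the imputation draws.
#' @return List of class `tkr_fits`.
#' @export
cmd_fit <- function(data, config = default_run_config(),
                    seed = config$seed) {
  proms <- data$proms
  n_miss <- sum(is.na(proms$postop_eq5d))
  if (n_miss == 0) {
    message("no missing post-operative outcomes; imputation skipped")
    qol_data <- proms
    fp_data <- proms
  } else {
    message(sprintf("imputing %d missing post-operative records (m = %d)",
                    n_miss, config$imputation$m))
    qol_data <- impute_chained(proms, m = config$imputation$m,
                               maxit = config$imputation$maxit, seed = seed)
    fp_data <- proms[!is.na(proms$postop_eq5d), ]
  }

  fp <- lapply(config$fp_covariates, function(v) {
    select_fractional_polynomial(fp_data, "postop_eq5d", v,
                                 adjust = setdiff(c("preop_eq5d",
                                                    "preop_oks"), v))
  })
  names(fp) <- config$fp_covariates
  for (v in names(fp)) {
    message("fractional polynomial for ", v, ": ", fp[[v]]$chosen,
            if (!is.null(fp[[v]]$powers)) {
              paste0(" (powers ", paste(fp[[v]]$powers, collapse = ", "),
                     ")")
            } else {
              ""
            })
  }

  covs <- default_qol_covariates()
  novar <- vapply(setdiff(covs, "age_c"), function(v) {
    length(unique(proms[[v]])) < 2
  }, logical(1))
  if (any(novar)) {
    message("dropping covariate(s) without variation: ",
            paste(names(novar)[novar], collapse = ", "))
    covs <- setdiff(covs, names(novar)[novar])
  }
  qol_fit <- fit_postop_qol(qol_data, covariates = covs, fp = fp)
  oks_fit <- fit_postop_qol(qol_data, outcome = "postop_oks",
                            covariates = covs)

  state_fits <- list(
    revision_year = fit_state_qol(data$revision_qol, "pre_revision"),
    post_revision = fit_state_qol(data$revision_qol, "post_revision")
  )

  spline_models <- lapply(tkr_brands(), function(b) {
    fit_rcs_hazard(data$revisions[data$revisions$brand == b, ])
  })
  names(spline_models) <- tkr_brands()

  rerevision <- fit_piecewise_rerevision(data$rerevisions)

  structure(list(qol_fit = qol_fit, oks_fit = oks_fit,
                 state_fits = state_fits, spline_models = spline_models,
                 rerevision = rerevision, fp = fp,
                 qol_data = qol_data, revision_records = data$revisions,
                 seed = seed),
            class = "tkr_fits")
}

#' Evaluate the cost-effectiveness analysis for every subgroup
#'
#' For each configured subgroup (sex x age at surgery) this reports:
#' initial outcomes per brand (post-operative EQ-5D-3L and OKS, initial
#' cost, predicted 5- and 10-year revision rates), lifetime point estimates
#' and PSA means with the ICER ladder and NMB, the probability each brand is
#' most cost-effective at the configured willingness-to-pay, the
#' acceptability frontier, and any requested scenario analyses.
#'
#' @param fits a [cmd_fit()] result.
#' @param config a [default_run_config()].
#' @param outdir optional directory; when given, per-subgroup CSV reports,
#'   frontier data and a JSON run manifest are written.
#' @param seed integer seed for the PSA.
#' @return List of class `cea_report` with one entry per subgroup.
#' @export
cmd_evaluate <- function(fits, config = default_run_config(), outdir = NULL,
                         seed = config$seed) {
  stopifnot(inherits(fits, "tkr_fits"))
  setup <- build_cea_setup(
    qol_fit = fits$qol_fit, state_fits = fits$state_fits,
    spline_models = fits$spline_models, rerevision = fits$rerevision,
    op_mortality = config$op_mortality, costs = config$costs,
    qol_data = fits$qol_data, revision_records = fits$revision_records
  )
  lg <- config$psa$lambda_grid
  lambda_grid <- seq(lg$from, lg$to, lg$by)
  subgroups <- expand.grid(sex = config$subgroups$sex,
                           age = config$subgroups$age,
                           stringsAsFactors = FALSE)

  report <- lapply(seq_len(nrow(subgroups)), function(i) {
    sex <- subgroups$sex[i]
    age <- subgroups$age[i]
    initial <- initial_outcomes_table(fits, setup, sex, age)
    pe <- point_estimates(setup, sex, age)
    psa <- run_psa(setup, sex, age, n_sims = config$psa$n_sims,
                   seed = seed + i)
    m <- psa_means(psa)
    ladder <- icer_ladder(m)
    ladder$nmb <- nmb(ladder$qalys, ladder$cost, config$psa$lambda)
    pr <- pe$proportion_revised[match(ladder$brand, pe$brand)]
    ladder <- cbind(ladder[, "brand", drop = FALSE],
                    proportion_revised = pr,
                    ladder[, c("cost", "qalys", "nmb", "status", "icer")])
    class(ladder) <- c("cea_table", "data.frame")
    scen <- lapply(config$scenarios, function(s) {
      run_scenario(s, setup, sex, age, n_sims = config$psa$n_sims,
                   seed = seed + 100 * s + i, lambda = config$psa$lambda)
    })
    list(sex = sex, age = age, initial = initial, point = pe,
         cea_table = ladder,
         prob_most_cost_effective =
           prob_most_cost_effective(psa, config$psa$lambda),
         frontier = acceptability_frontier(psa, lambda_grid),
         scenarios = scen)
  })
  names(report) <- paste0(subgroups$sex, subgroups$age)
  out <- structure(list(subgroups = report, lambda = config$psa$lambda,
                        seed = seed),
                   class = "cea_report")
  if (!is.null(outdir)) write_cea_report(out, config, outdir)
  out
}

initial_outcomes_table <- function(fits, setup, sex, age) {
  eq <- predict_subgroup_qol(fits$qol_fit, tkr_brands(), sex, age,
                             allow_any_age = TRUE)
  oks <- predict_subgroup_qol(fits$oks_fit, tkr_brands(), sex, age,
                              allow_any_age = TRUE)
  rev <- t(vapply(tkr_brands(), function(b) {
    predict_cumulative_revision(setup$spline_models[[b]], c(5, 10), sex,
                                age)
  }, numeric(2)))
  init <- vapply(tkr_brands(), function(b) {
    initial_cost(brand_model_inputs(setup, b, sex, age))
  }, numeric(1))
  data.frame(brand = tkr_brands(), sex = sex, age = age,
             postop_eq5d = eq$fit, postop_eq5d_se = eq$se,
             postop_oks = oks$fit,
             initial_cost = init,
             revision_5y = rev[, 1], revision_10y = rev[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

write_cea_report <- function(report, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$subgroups)) {
    r <- report$subgroups[[nm]]
    write.csv(r$initial,
              file.path(outdir, paste0("initial_outcomes_", nm, ".csv")),
              row.names = FALSE)
    write.csv(as.data.frame(r$cea_table),
              file.path(outdir, paste0("cea_table_", nm, ".csv")),
              row.names = FALSE)
    write.csv(as.data.frame(r$frontier),
              file.path(outdir, paste0("frontier_", nm, ".csv")),
              row.names = FALSE)
    if (length(r$scenarios)) {
      pt <- do.call(rbind, lapply(r$scenarios, function(s) {
        data.frame(scenario = s$scenario, t(s$prob_most_cost_effective))
      }))
      write.csv(pt, file.path(outdir, paste0("scenarios_", nm, ".csv")),
                row.names = FALSE)
    }
  }
  manifest <- list(seed = report$seed, lambda = report$lambda,
                   config = unclass(config),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   package_version =
                     as.character(utils::packageVersion("kneecea")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(outdir)
}

#' @export
print.cea_report <- function(x, ...) {
  for (nm in names(x$subgroups)) {
    r <- x$subgroups[[nm]]
    cat("==", if (r$sex == "M") "Men" else "Women", "aged", r$age, "==\n")
    print(r$cea_table)
    cat("P(most cost-effective) at", x$lambda, "GBP/QALY:\n")
    print(round(r$prob_most_cost_effective, 3))
    cat("\n")
  }
  invisible(x)
}

# ---- JSON serialization of fitted models -------------------------------

fit_to_list <- function(f) {
  if (inherits(f, "rcs_hazard")) {
    f$fit <- NULL     # drop the flexsurv object; parameters suffice
  }
  f$fp <- NULL
  lapply(unclass(f), function(x) {
    if (is.matrix(x)) {
      list(.matrix = TRUE, data = as.vector(x), nrow = nrow(x),
           rn = rownames(x), cn = colnames(x))
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)      # keep names (JSON drops names of atomic vectors)
    } else {
      x
    }
  })
}

list_to_fit <- function(l, cls) {
  l <- lapply(l, function(x) {
    if (is.list(x) && isTRUE(x$.matrix)) {
      m <- matrix(unlist(x$data), nrow = x$nrow)
      dimnames(m) <- list(x$rn, x$cn)
      m
    } else if (is.list(x) && length(x) &&
               all(vapply(x, function(e) is.atomic(e) && length(e) == 1,
                          logical(1)))) {
      unlist(x)       # named vector serialized as an object
    } else {
      x
    }
  })
  structure(l, class = cls)
}

#' Serialize fitted models to JSON
#'
#' Writes the coefficient vectors, covariance matrices, knots and metadata
#' of every fitted model (sufficient for prediction and PSA; the raw
#' flexsurv object is not retained). [read_fits()] restores the model
#' objects.
#'
#' @param fits a [cmd_fit()] result.
#' @param path JSON file path.
#' @export
write_fits <- function(fits, path) {
  stopifnot(inherits(fits, "tkr_fits"))
  obj <- list(
    qol_fit = fit_to_list(fits$qol_fit),
    oks_fit = fit_to_list(fits$oks_fit),
    state_fits = lapply(fits$state_fits, fit_to_list),
    spline_models = lapply(fits$spline_models, fit_to_list),
    rerevision = fit_to_list(fits$rerevision),
    seed = fits$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_fits
#' @return [read_fits()] returns a `tkr_fits` list (without the training
#'   data, so the data-refitting scenarios are unavailable from a JSON
#'   round trip).
#' @export
read_fits <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  qf <- list_to_fit(obj$qol_fit, "qol_fit")
  of <- list_to_fit(obj$oks_fit, "qol_fit")
  sf <- lapply(obj$state_fits, list_to_fit, cls = "state_qol_fit")
  sm <- lapply(obj$spline_models, list_to_fit, cls = "rcs_hazard")
  rr <- list_to_fit(obj$rerevision, "piecewise_rerevision")
  structure(list(qol_fit = qf, oks_fit = of, state_fits = sf,
                 spline_models = sm, rerevision = rr, fp = NULL,
                 qol_data = NULL, revision_records = NULL,
                 seed = obj$seed),
            class = "tkr_fits")
}
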