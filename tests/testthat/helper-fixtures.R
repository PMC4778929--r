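# Shared fixtures, cached across test files within one run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small registry + fits for structural / smoke tests
small_config <- function(...) {
  default_run_config(
    registry = list(n_patients = 6000, n_revision_patients = 30000,
                    n_rerevision_patients = 10000),
    imputation = list(m = 3, maxit = 3),
    psa = list(n_sims = 50, lambda = 20000,
               lambda_grid = list(from = 0, to = 50000, by = 10000)),
    subgroups = list(sex = "M", age = 70),
    ...
  )
}

small_fits <- function() {
  fixture("small_fits", {
    cfg <- small_config()
    reg <- cmd_simulate(cfg, seed = 301)
    data <- list(proms = reg$proms$records,
                 revisions = reg$revisions$records,
                 rerevisions = reg$rerevisions$records,
                 revision_qol = reg$revision_qol$records)
    suppressMessages(fits <- cmd_fit(data, cfg, seed = 302))
    list(cfg = cfg, registry = reg, data = data, fits = fits)
  })
}

small_setup <- function() {
  fixture("small_setup", {
    f <- small_fits()
    build_cea_setup(
      qol_fit = f$fits$qol_fit, state_fits = f$fits$state_fits,
      spline_models = f$fits$spline_models,
      rerevision = f$fits$rerevision,
      qol_data = f$fits$qol_data,
      revision_records = f$fits$revision_records
    )
  })
}

# study-scale calibrated pipeline, used by the acceptance checks
study_fits <- function() {
  fixture("study_fits", {
    cfg <- default_run_config(subgroups = list(sex = c("M", "F"), age = 70))
    reg <- cmd_simulate(cfg, seed = 42)
    data <- list(proms = reg$proms$records,
                 revisions = reg$revisions$records,
                 rerevisions = reg$rerevisions$records,
                 revision_qol = reg$revision_qol$records)
    suppressMessages(fits <- cmd_fit(data, cfg, seed = 43))
    setup <- build_cea_setup(
      qol_fit = fits$qol_fit, state_fits = fits$state_fits,
      spline_models = fits$spline_models, rerevision = fits$rerevision
    )
    list(cfg = cfg, registry = reg, fits = fits, setup = setup)
  })
}

study_psa <- function(sex) {
  fixture(paste0("study_psa_", sex), {
    run_psa(study_fits()$setup, sex = sex, age = 70, n_sims = 1000,
            seed = if (sex == "M") 4201 else 4202)
  })
}

# generic, moderately severe model inputs for Markov-engine tests
test_model_inputs <- function(...) {
  args <- list(
    brand = "Nexgen", sex = "M", age_at_surgery = 70,
    utility_primary = 0.74, utility_revision_year = 0.45,
    utility_post_revision = 0.62,
    revision_probs = rep(0.004, 45),
    rerevision_probs = c(year1 = 0.04, later = 0.015),
    op_mortality = 0.002,
    mortality_probs = adjusted_mortality(default_life_table(),
                                         healthy_patient_effect(),
                                         70, "M", 1:45),
    prosthesis_price = 1676, los_days = 4.5
  )
  do.call(model_inputs, modifyList(args, list(...)))
}
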