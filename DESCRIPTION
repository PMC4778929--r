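Package: kneecea
Title: Lifetime Cost-Effectiveness of Knee Prosthesis Brands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for lifetime cost-effectiveness
    analysis of total knee replacement (TKR) prosthesis brands. Generates
    synthetic registry data (PROMs-style quality-of-life records linked to
    revision follow-up) with known ground truth; estimates case-mix-adjusted
    post-operative EQ-5D-3L by brand with fractional polynomials and multiple
    imputation; fits restricted-cubic-spline (Royston-Parmar) revision-hazard
    models with extrapolation and piecewise-constant re-revision models; runs
    a 4-state annual-cycle Markov cohort model over 45 cycles with discounting
    and an aging-related quality-of-life decline; and performs probabilistic
    cost-effectiveness analysis including net monetary benefit, ICER ladders
    with extended dominance, cost-effectiveness acceptability frontiers, and
    scenario analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
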