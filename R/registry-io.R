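# Delimited-text persistence for the synthetic registry. Doubles are
# written with 17 significant digits (enough to reproduce any IEEE double
# exactly) and re-typed on reading, so a write/read cycle is lossless.

write_csv_exact <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      s <- sprintf("%.17g", df[[j]])
      s[is.na(df[[j]])] <- NA
      df[[j]] <- s
    }
  }
  write.csv(df, path, row.names = FALSE, na = "")
}

read_csv_exact <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (j in seq_along(d)) {
    if (is.character(d[[j]])) {
      d[[j]] <- utils::type.convert(d[[j]], as.is = TRUE)
    }
  }
  d
}

registry_dictionary <- function() {
  data.frame(
    file = c(rep("proms_cohort.csv", 19), rep("revisions.csv", 12),
             rep("rerevisions.csv", 3), rep("revision_qol.csv", 4)),
    column = c(
      "patient_id", "hospital_id", "brand", "age", "sex",
      "comorbidity_count", "asa_grade", "bmi", "imd_quintile",
      "patella_replaced", "disability", "surgical_position",
      "senior_surgeon", "treatment_centre", "preop_eq5d", "preop_oks",
      "postop_eq5d", "postop_oks", "los_days",
      "patient_id", "brand", "age", "sex", "asa_grade", "bmi",
      "patella_replaced", "antibiotic_cement", "senior_surgeon",
      "treatment_centre", "time_to_event", "event",
      "patient_id", "time_to_event", "event",
      "timing", "age", "sex", "eq5d"
    ),
    description = c(
      "row id", "synthetic provider id", "prosthesis brand",
      "age at surgery (years, 55-84)", "sex (M/F)",
      "number of patient-reported comorbidities", "ASA grade (1-3)",
      "body mass index (kg/m2)", "IMD quintile (5 = most deprived)",
      "patella replaced (0/1)", "disability flag (0/1)",
      "non-standard surgical position flag (0/1)",
      "operation by consultant (0/1)",
      "independent-sector treatment centre (0/1)",
      "pre-operative EQ-5D-3L index (-0.594..1)",
      "pre-operative Oxford Knee Score (0-48)",
      "6-month EQ-5D-3L index (NA if questionnaire missing)",
      "6-month Oxford Knee Score (NA if missing)",
      "length of stay (days)",
      "row id", "prosthesis brand", "age at surgery", "sex (M/F)",
      "ASA grade", "BMI", "patella replaced (0/1)",
      "antibiotic-loaded cement (0/1)", "operation by consultant (0/1)",
      "treatment centre (0/1)",
      "years to first revision or censoring", "1 = revision, 0 = censored",
      "row id", "years from revision to re-revision or censoring",
      "1 = re-revision, 0 = censored",
      "pre_revision or post_revision questionnaire", "age (years)",
      "sex (M/F)", "EQ-5D-3L index"
    ),
    stringsAsFactors = FALSE
  )
}

#' Write a complete synthetic registry to delimited text
#'
#' Writes `proms_cohort.csv`, `revisions.csv`, `rerevisions.csv`,
#' `revision_qol.csv`, the ground truth as `truth.json`, and a
#' `data_dictionary.csv` describing every column. Doubles are written with
#' 17 significant digits so the files round-trip losslessly.
#'
#' @param registry list with elements `proms` ([generate_proms_cohort()]
#'   output), `revisions`, `rerevisions`, `revision_qol`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_exact(registry$proms$records, file.path(dir, "proms_cohort.csv"))
  write_csv_exact(registry$revisions$records, file.path(dir, "revisions.csv"))
  write_csv_exact(registry$rerevisions$records,
                  file.path(dir, "rerevisions.csv"))
  write_csv_exact(registry$revision_qol$records,
                  file.path(dir, "revision_qol.csv"))
  # JSON drops names of atomic vectors and dimnames of matrices; convert
  # them to named lists so the truth file is self-describing
  namify <- function(x) {
    if (is.matrix(x)) {
      rows <- lapply(seq_len(nrow(x)), function(i) {
        as.list(setNames(x[i, ], colnames(x)))
      })
      names(rows) <- rownames(x)
      rows
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else if (is.list(x) && !is.data.frame(x)) {
      lapply(x, namify)
    } else {
      x
    }
  }
  truth <- namify(list(proms = unclass(registry$proms$truth),
                revisions = unclass(registry$revisions$truth),
                rerevisions = unclass(registry$rerevisions$truth),
                revision_qol = unclass(registry$revision_qol$truth)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(registry_dictionary(), file.path(dir, "data_dictionary.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a synthetic registry written by [write_registry()]
#'
#' @param dir directory containing the registry files.
#' @return List with `proms`, `revisions`, `rerevisions`, `revision_qol`
#'   data.frames and the deserialized `truth` list.
#' @export
read_registry <- function(dir) {
  rd <- function(f) {
    d <- read_csv_exact(file.path(dir, f))
    if ("brand" %in% names(d)) d$brand <- factor(d$brand, levels = tkr_brands())
    d
  }
  list(proms = rd("proms_cohort.csv"),
       revisions = rd("revisions.csv"),
       rerevisions = rd("rerevisions.csv"),
       revision_qol = rd("revision_qol.csv"),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
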