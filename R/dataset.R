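#' Study dataset container
#'
#' Bundles the instrument tables the analysis consumes: the practice rosters,
#' the patient table (demographics, response/consent status, chart-extracted
#' treatment flags), the long-form patient contact reports, the long-form
#' provider survey reports, and the medical-record measurement extract.
#'
#' @param practices data frame: `practice_id`, `professional_id`,
#'   `discipline`.
#' @param patients data frame: `patient_id`, `practice_id`, `condition`,
#'   `responded`, `consent`, `hospital_only`, demographics and treatment
#'   flag columns.
#' @param contacts data frame (responders only): `patient_id`, `activity`,
#'   `discipline`, `contact` (`"yes"`/`"no"`), `n_contacts`.
#' @param providers data frame: `professional_id`, `practice_id`,
#'   `responded`, `activity`, `discipline`, `contact`
#'   (`"yes"`/`"no"`/`NA`).
#' @param records data frame: `patient_id`, `parameter`, `date`, `value`,
#'   `discipline` (who recorded the measurement).
#' @param extraction_date chart extraction date (`Date`).
#' @param window_days monitoring window in days.
#' @return an object of class `study_dataset`.
#' @export
new_study_dataset <- function(practices, patients, contacts, providers,
                              records, extraction_date, window_days = 365L) {
  ds <- structure(
    list(practices = practices, patients = patients, contacts = contacts,
         providers = providers, records = records,
         extraction_date = as.Date(extraction_date),
         window_days = as.integer(window_days)),
    class = "study_dataset")
  validate_study_dataset(ds)
}

#' Validate a study dataset
#'
#' Checks referential integrity (patients and providers reference existing
#' practices and roster members), the closed discipline/activity/parameter
#' vocabularies, id uniqueness, and the missingness contract (a
#' non-responding provider has no contact flags; contact counts above zero
#' imply a reported contact). Errors name the offending row.
#'
#' @param ds a `study_dataset`.
#' @return the dataset, invisibly usable in a pipeline.
#' @export
validate_study_dataset <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  pr <- ds$practices
  schema_check(pr, c("practice_id", "professional_id", "discipline"),
               "practices")
  bad <- which(!pr$discipline %in% IN_PRACTICE_DISCIPLINES)
  if (length(bad))
    stop(sprintf("practices row %d: unknown in-practice discipline '%s'",
                 bad[1], pr$discipline[bad[1]]), call. = FALSE)
  if (anyDuplicated(pr$professional_id))
    stop("practices: duplicate professional_id", call. = FALSE)

  pa <- ds$patients
  schema_check(pa, c("patient_id", "practice_id", "condition", "responded",
                     "consent", "hospital_only"), "patients")
  if (anyDuplicated(pa$patient_id))
    stop("patients: duplicate patient_id", call. = FALSE)
  bad <- which(!pa$practice_id %in% pr$practice_id)
  if (length(bad))
    stop(sprintf("patients row %d: unknown practice '%s'",
                 bad[1], pa$practice_id[bad[1]]), call. = FALSE)
  bad <- which(!pa$condition %in% CONDITIONS)
  if (length(bad))
    stop(sprintf("patients row %d: unknown condition '%s'",
                 bad[1], pa$condition[bad[1]]), call. = FALSE)

  ct <- ds$contacts
  schema_check(ct, c("patient_id", "activity", "discipline", "contact",
                     "n_contacts"), "contacts")
  bad <- which(!ct$patient_id %in% pa$patient_id)
  if (length(bad))
    stop(sprintf("contacts row %d: unknown patient '%s'",
                 bad[1], ct$patient_id[bad[1]]), call. = FALSE)
  bad <- which(!ct$discipline %in% DISCIPLINES)
  if (length(bad))
    stop(sprintf("contacts row %d: unknown discipline '%s'",
                 bad[1], ct$discipline[bad[1]]), call. = FALSE)
  bad <- which(!ct$activity %in% ACTIVITIES)
  if (length(bad))
    stop(sprintf("contacts row %d: unknown activity '%s'",
                 bad[1], ct$activity[bad[1]]), call. = FALSE)
  bad <- which(ct$n_contacts > 0 & ct$contact != "yes")
  if (length(bad))
    stop(sprintf("contacts row %d: positive contact count without a reported contact",
                 bad[1]), call. = FALSE)

  pv <- ds$providers
  schema_check(pv, c("professional_id", "practice_id", "responded",
                     "activity", "discipline", "contact"), "providers")
  bad <- which(!pv$professional_id %in% pr$professional_id)
  if (length(bad))
    stop(sprintf("providers row %d: unknown professional '%s'",
                 bad[1], pv$professional_id[bad[1]]), call. = FALSE)
  bad <- which(!pv$discipline %in% DISCIPLINES)
  if (length(bad))
    stop(sprintf("providers row %d: unknown discipline '%s'",
                 bad[1], pv$discipline[bad[1]]), call. = FALSE)
  bad <- which(!pv$responded & !is.na(pv$contact))
  if (length(bad))
    stop(sprintf("providers row %d: non-responder carries a contact flag",
                 bad[1]), call. = FALSE)

  rc <- ds$records
  schema_check(rc, c("patient_id", "parameter", "date"), "records")
  bad <- which(!rc$parameter %in% MONITORING_PARAMETERS)
  if (length(bad))
    stop(sprintf("records row %d: unknown parameter '%s'",
                 bad[1], rc$parameter[bad[1]]), call. = FALSE)
  bad <- which(!rc$patient_id %in% pa$patient_id)
  if (length(bad))
    stop(sprintf("records row %d: unknown patient '%s'",
                 bad[1], rc$patient_id[bad[1]]), call. = FALSE)
  ds
}

schema_check <- function(df, cols, table) {
  if (!is.data.frame(df))
    stop(sprintf("%s: not a data frame", table), call. = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", table,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(paste0("<study_dataset> %d practices, %d professionals, ",
                     "%d patients (%d responded), %d record rows\n"),
              length(unique(x$practices$practice_id)),
              nrow(x$practices), nrow(x$patients), sum(x$patients$responded),
              nrow(x$records)))
  invisible(x)
}

#' Extract one patient's source bundle
#'
#' Collects everything network construction needs for one patient: the
#' per-activity questionnaire reports, the disciplines inferable from the
#' medical-record extract within the monitoring window (`chart_contacts`),
#' and the consent / hospital-only flags.
#'
#' @param dataset a `study_dataset`.
#' @param patient_id patient identifier.
#' @return list of class `patient_bundle`.
#' @export
patient_bundle <- function(dataset, patient_id) {
  stopifnot(inherits(dataset, "study_dataset"))
  row <- dataset$patients[dataset$patients$patient_id == patient_id, ]
  if (nrow(row) != 1)
    stop(sprintf("unknown patient id '%s'", patient_id), call. = FALSE)
  ct <- dataset$contacts[dataset$contacts$patient_id == patient_id, ]
  rc <- dataset$records[dataset$records$patient_id == patient_id, ]
  in_window <- rc$date > dataset$extraction_date - dataset$window_days &
    rc$date <= dataset$extraction_date
  chart <- unique(rc$discipline[in_window])
  chart <- chart[!is.na(chart)]
  structure(
    list(patient_id = patient_id,
         practice_id = row$practice_id,
         condition = row$condition,
         responded = isTRUE(row$responded),
         consent = isTRUE(row$consent),
         hospital_only = isTRUE(row$hospital_only),
         contacts = ct,
         chart_contacts = chart),
    class = "patient_bundle")
}
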