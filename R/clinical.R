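#' Was a parameter measured within the monitoring window?
#'
#' True iff at least one record of the parameter has a date in
#' `(reference_date - window_days, reference_date]` — half-open at the start,
#' inclusive at the reference date.
#'
#' @param records medical-record extract (`patient_id`, `parameter`, `date`).
#' @param parameter one of the monitoring parameters.
#' @param reference_date anchor date (`Date`).
#' @param window_days window length in days (> 0).
#' @return logical flag.
#' @export
measured_within <- function(records, parameter, reference_date,
                            window_days = 365) {
  if (!parameter %in% MONITORING_PARAMETERS)
    stop(sprintf("unknown monitoring parameter '%s'", parameter),
         call. = FALSE)
  stopifnot(window_days > 0)
  reference_date <- as.Date(reference_date)
  d <- records$date[records$parameter == parameter]
  any(d > reference_date - window_days & d <= reference_date)
}

#' Comprehensive-monitoring composite
#'
#' A patient received comprehensive monitoring if BMI or weight, systolic
#' blood pressure, and creatinine were each obtained at least once in the
#' window. BMI and weight are interchangeable.
#'
#' @param weight,bmi,systolic_bp,creatinine in-window measurement flags.
#' @return logical flag.
#' @export
comprehensive_monitoring <- function(weight, bmi, systolic_bp, creatinine) {
  (isTRUE(weight) | isTRUE(bmi)) & isTRUE(systolic_bp) & isTRUE(creatinine)
}

#' Monitoring profiles for all consented patients
#'
#' Per patient: an in-window flag per monitoring parameter, the
#' comprehensive-monitoring composite, the questionnaire-derived contact
#' counts (disease-specific consultations = treatment + advice contacts;
#' blood-value monitoring = monitoring contacts), and the chart-extracted
#' treatment flags.
#'
#' @param dataset a `study_dataset`.
#' @param reference_date anchor date; defaults to the dataset's extraction
#'   date.
#' @param window_days window length; defaults to the dataset's window.
#' @return data frame, one row per consented patient.
#' @export
monitoring_profiles <- function(dataset,
                                reference_date = dataset$extraction_date,
                                window_days = dataset$window_days) {
  stopifnot(inherits(dataset, "study_dataset"))
  pa <- dataset$patients[dataset$patients$consent, ]
  rows <- lapply(pa$patient_id, function(pid) {
    rc <- dataset$records[dataset$records$patient_id == pid, ]
    flags <- vapply(MONITORING_PARAMETERS, function(p)
      measured_within(rc, p, reference_date, window_days), logical(1))
    ct <- dataset$contacts[dataset$contacts$patient_id == pid, ]
    out <- data.frame(patient_id = pid, stringsAsFactors = FALSE)
    out[MONITORING_PARAMETERS] <- as.list(flags)
    out$comprehensive <- comprehensive_monitoring(
      flags["weight"], flags["bmi"], flags["systolic_bp"],
      flags["creatinine"])
    out$n_disease_contacts <-
      sum(ct$n_contacts[ct$activity %in% c("treatment", "advice")])
    out$n_blood_monitoring_contacts <-
      sum(ct$n_contacts[ct$activity == "monitoring"])
    out
  })
  prof <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cbind(prof,
        pa[match(prof$patient_id, pa$patient_id),
           c("condition", TREATMENT_FLAGS)],
        row.names = NULL)
}

#' Clinical management summary by condition
#'
#' Per condition: mean contact counts, the percentage (and k/n) of patients
#' with each parameter measured in-window, and treatment percentages.
#' HbA1c is reported for diabetes only; diabetes-specific treatments are
#' omitted for CHF and vice versa.
#'
#' @param profiles output of [monitoring_profiles()], optionally restricted
#'   (e.g. to analyzable patients).
#' @return list with `contacts`, `monitoring`, `treatment` data frames.
#' @export
clinical_summary <- function(profiles) {
  conds <- intersect(CONDITIONS, unique(profiles$condition))
  if (length(conds) < length(CONDITIONS))
    warning("condition group(s) with zero patients omitted from summary")
  pct_row <- function(x) {
    x <- x[!is.na(x)]
    data.frame(pct = round(100 * mean(x)), k = sum(x), n = length(x))
  }
  contacts <- do.call(rbind, lapply(conds, function(cd) {
    p <- profiles[profiles$condition == cd, ]
    data.frame(condition = cd,
               mean_disease_contacts = mean(p$n_disease_contacts),
               mean_blood_monitoring_contacts =
                 mean(p$n_blood_monitoring_contacts),
               n = nrow(p), stringsAsFactors = FALSE)
  }))
  monitoring <- do.call(rbind, lapply(conds, function(cd) {
    p <- profiles[profiles$condition == cd, ]
    params <- if (cd == "diabetes") MONITORING_PARAMETERS else
      setdiff(MONITORING_PARAMETERS, "hba1c")
    cbind(condition = cd, parameter = params,
          do.call(rbind, lapply(params, function(pm) pct_row(p[[pm]]))),
          row.names = NULL)
  }))
  treatment <- do.call(rbind, lapply(conds, function(cd) {
    p <- profiles[profiles$condition == cd, ]
    flags <- TREATMENT_FLAGS[colSums(!is.na(p[TREATMENT_FLAGS])) > 0]
    cbind(condition = cd, flag = flags,
          do.call(rbind, lapply(flags, function(f) pct_row(p[[f]]))),
          row.names = NULL)
  }))
  list(contacts = contacts, monitoring = monitoring, treatment = treatment)
}
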