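#' Closed vocabularies used throughout the package
#'
#' The discipline list is fixed: three in-practice roles found in Dutch
#' GP-led practices and five collapsed external disciplines. Every external
#' discipline contributes at most one node per patient network.
#'
#' @name vocab
#' @keywords internal
NULL

#' In-practice disciplines
#' @export
IN_PRACTICE_DISCIPLINES <- c("gp", "practice_nurse", "practice_assistant")

#' External (outside-practice) disciplines, collapsed to one node each
#' @export
EXTERNAL_DISCIPLINES <- c("physiotherapist", "dietician", "pharmacist",
                          "medical_specialist", "other")

#' All disciplines, in tie-break priority order (GP first)
#' @export
DISCIPLINES <- c(IN_PRACTICE_DISCIPLINES, EXTERNAL_DISCIPLINES)

#' The three clinical activities networks are constructed for
#' @export
ACTIVITIES <- c("treatment", "advice", "monitoring")

#' Chronic conditions under study
#' @export
CONDITIONS <- c("diabetes", "chf")

#' Monitoring parameters extractable from medical records
#' @export
MONITORING_PARAMETERS <- c("weight", "bmi", "systolic_bp", "hba1c", "glucose",
                           "creatinine", "potassium", "sodium",
                           "total_cholesterol", "hdl", "ldl", "triglycerides")

#' Treatment (medication/diet) flags extracted from medical records
#' @export
TREATMENT_FLAGS <- c("diet", "oral_medication", "insulin", "antihypertensive",
                     "lipid_lowering", "ace_inhibitor", "beta_blocker",
                     "furosemide_ace_nsaid")

# Tie provenance tokens. Present ties carry the source that created them;
# absent dyads distinguish an informative "no" from complete missingness.
PROVENANCE_PRESENT <- c("patient-reported", "chart-derived",
                        "provider-reported", "substituted")
PROVENANCE_ABSENT <- c("absent", "zero-filled-absent")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_config(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_count <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop_config(field, "must be a non-negative integer count")
  invisible(x)
}

#' Node identifier helpers
#'
#' Stable node id scheme: `P:<patient_id>` for the ego,
#' `HP:<practice_id>:<discipline>:<index>` for in-practice professionals,
#' `EXT:<discipline>` for collapsed external disciplines. Stability across
#' activities is what makes cross-network overlap well defined.
#'
#' @param patient_id,practice_id,discipline,index identifier components
#' @return character id
#' @export
node_id_patient <- function(patient_id) paste0("P:", patient_id)

#' @rdname node_id_patient
#' @export
node_id_professional <- function(practice_id, discipline, index) {
  paste0("HP:", practice_id, ":", discipline, ":", index)
}

#' @rdname node_id_patient
#' @export
node_id_external <- function(discipline) paste0("EXT:", discipline)
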