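#' Configuration for a synthetic multi-source care-team cohort
#'
#' Defines the study conditions a synthetic cohort is generated under:
#' practice structure, sampling frame, response behaviour, tie formation for
#' both patient-reported and provider-reported contacts, and chart-recorded
#' monitoring. Defaults emulate a three-practice Dutch primary-care study with
#' roughly ten diabetes and ten chronic-heart-failure patients per practice,
#' about half of invited patients responding and nearly all providers
#' responding.
#'
#' @param n_practices number of GP-led practices.
#' @param practice_rosters list (length `n_practices`) of named integer
#'   vectors giving in-practice staff counts by discipline; every roster must
#'   contain at least one `gp`.
#' @param n_diabetes_per_practice,n_chf_per_practice invited patients per
#'   practice and condition; scalar or vector of length `n_practices`.
#' @param patient_response_rate probability an invited patient completes the
#'   questionnaire and consents to chart extraction.
#' @param provider_response_rate probability a practice professional returns
#'   the provider survey.
#' @param tie_prob_patient named list `activity -> named vector
#'   discipline -> probability` of a true patient contact.
#' @param tie_prob_provider named vector `activity -> probability` of a true
#'   contact on a provider dyad (professional pairs within a practice, and
#'   professional-to-external-discipline pairs).
#' @param report_asymmetry probability that only one side of a true
#'   within-practice provider dyad reports it.
#' @param hospital_only_chf_rate probability a responding CHF patient received
#'   all treatment in hospital (contacts with the medical specialist only).
#' @param monitoring_rates named vector `parameter -> probability` of at least
#'   one in-window measurement; `hba1c` applies to diabetes patients only.
#' @param treatment_rates named list `condition -> named vector flag ->
#'   probability` for chart-extracted medication/diet flags.
#' @param contact_lambda named vector `activity -> mean` of the (zero-
#'   truncated) Poisson contact count given a reported tie.
#' @param extraction_date chart extraction date anchoring the monitoring
#'   window (class `Date`).
#' @param window_days monitoring window length in days.
#' @param rng_seed integer master seed; split into independent streams for
#'   patients, providers and records so enlarging one table does not perturb
#'   the others.
#'
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_practices = 3,
                          practice_rosters = default_rosters(n_practices),
                          n_diabetes_per_practice = 10,
                          n_chf_per_practice = c(10, 10, 7)[seq_len(n_practices)],
                          patient_response_rate = 0.56,
                          provider_response_rate = 0.909,
                          tie_prob_patient = default_tie_prob_patient(),
                          tie_prob_provider = c(treatment = 0.30,
                                                advice = 0.18,
                                                monitoring = 0.28),
                          report_asymmetry = 0.35,
                          hospital_only_chf_rate = 0.30,
                          monitoring_rates = default_monitoring_rates(),
                          treatment_rates = default_treatment_rates(),
                          contact_lambda = c(treatment = 2.5, advice = 1.2,
                                             monitoring = 3.5),
                          extraction_date = as.Date("2010-06-30"),
                          window_days = 365,
                          rng_seed = 1L) {
  cfg <- structure(
    list(n_practices = as.integer(n_practices),
         practice_rosters = practice_rosters,
         n_diabetes_per_practice = rep_len(as.integer(n_diabetes_per_practice),
                                           n_practices),
         n_chf_per_practice = rep_len(as.integer(n_chf_per_practice),
                                      n_practices),
         patient_response_rate = patient_response_rate,
         provider_response_rate = provider_response_rate,
         tie_prob_patient = tie_prob_patient,
         tie_prob_provider = tie_prob_provider,
         report_asymmetry = report_asymmetry,
         hospital_only_chf_rate = hospital_only_chf_rate,
         monitoring_rates = monitoring_rates,
         treatment_rates = treatment_rates,
         contact_lambda = contact_lambda,
         extraction_date = as.Date(extraction_date),
         window_days = as.integer(window_days),
         rng_seed = as.integer(rng_seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
}

default_rosters <- function(n_practices) {
  base <- list(
    c(gp = 2L, practice_nurse = 2L, practice_assistant = 2L),
    c(gp = 2L, practice_nurse = 2L, practice_assistant = 2L),
    c(gp = 3L, practice_nurse = 3L, practice_assistant = 4L))
  rep_len(base, n_practices)
}

default_tie_prob_patient <- function() {
  list(
    treatment  = c(gp = 0.70, practice_nurse = 0.35, practice_assistant = 0.10,
                   physiotherapist = 0.02, dietician = 0.08, pharmacist = 0.30,
                   medical_specialist = 0.20, other = 0.02),
    advice     = c(gp = 0.40, practice_nurse = 0.30, practice_assistant = 0.03,
                   physiotherapist = 0.20, dietician = 0.15, pharmacist = 0.02,
                   medical_specialist = 0.08, other = 0.02),
    monitoring = c(gp = 0.70, practice_nurse = 0.50, practice_assistant = 0.20,
                   physiotherapist = 0.01, dietician = 0.05, pharmacist = 0.05,
                   medical_specialist = 0.20, other = 0.02))
}

default_monitoring_rates <- function() {
  c(weight = 0.80, bmi = 0.70, systolic_bp = 0.95, hba1c = 0.83,
    glucose = 0.72, creatinine = 0.55, potassium = 0.47, sodium = 0.35,
    total_cholesterol = 0.52, hdl = 0.52, ldl = 0.48, triglycerides = 0.60)
}

default_treatment_rates <- function() {
  list(
    diabetes = c(diet = 0.28, oral_medication = 0.67, insulin = 0.22,
                 antihypertensive = 0.89, lipid_lowering = 0.78,
                 ace_inhibitor = 0, beta_blocker = 0, furosemide_ace_nsaid = 0),
    chf = c(diet = 0, oral_medication = 0, insulin = 0,
            antihypertensive = 0.95, lipid_lowering = 0.57,
            ace_inhibitor = 0.57, beta_blocker = 0.86,
            furosemide_ace_nsaid = 0.43))
}

validate_cohort_config <- function(cfg) {
  check_count(cfg$n_practices, "n_practices")
  if (cfg$n_practices < 1) stop_config("n_practices", "must be >= 1")
  if (length(cfg$practice_rosters) != cfg$n_practices)
    stop_config("practice_rosters",
                sprintf("must have one roster per practice (%d)",
                        cfg$n_practices))
  for (i in seq_along(cfg$practice_rosters)) {
    r <- cfg$practice_rosters[[i]]
    check_count(r, "practice_rosters")
    if (length(r) == 0 || sum(r) == 0)
      stop_config("practice_rosters", sprintf("practice %d roster is empty", i))
    if (!all(names(r) %in% IN_PRACTICE_DISCIPLINES))
      stop_config("practice_rosters",
                  sprintf("unknown in-practice discipline in practice %d", i))
    if (is.na(r["gp"]) || r["gp"] < 1)
      stop_config("practice_rosters",
                  sprintf("practice %d roster has no GP", i))
  }
  check_count(cfg$n_diabetes_per_practice, "n_diabetes_per_practice")
  check_count(cfg$n_chf_per_practice, "n_chf_per_practice")
  check_prob(cfg$patient_response_rate, "patient_response_rate")
  check_prob(cfg$provider_response_rate, "provider_response_rate")
  if (!setequal(names(cfg$tie_prob_patient), ACTIVITIES))
    stop_config("tie_prob_patient", "must map every activity")
  for (a in ACTIVITIES) {
    p <- cfg$tie_prob_patient[[a]]
    check_prob(p, "tie_prob_patient")
    if (!all(names(p) %in% DISCIPLINES))
      stop_config("tie_prob_patient", "unknown discipline")
  }
  if (!setequal(names(cfg$tie_prob_provider), ACTIVITIES))
    stop_config("tie_prob_provider", "must map every activity")
  check_prob(cfg$tie_prob_provider, "tie_prob_provider")
  check_prob(cfg$report_asymmetry, "report_asymmetry")
  check_prob(cfg$hospital_only_chf_rate, "hospital_only_chf_rate")
  if (!all(names(cfg$monitoring_rates) %in% MONITORING_PARAMETERS))
    stop_config("monitoring_rates", "unknown monitoring parameter")
  check_prob(cfg$monitoring_rates, "monitoring_rates")
  if (cfg$window_days <= 0) stop_config("window_days", "must be positive")
  cfg
}

# Independent reproducible streams split from the master seed. Evaluates
# `expr` under its own RNG state and restores the caller's state afterwards.
with_stream <- function(master_seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  sub <- (as.numeric(master_seed) * 7919 + stream * 104729) %% 2147483647
  set.seed(as.integer(sub))
  expr
}

#' Generate a synthetic multi-source study dataset
#'
#' Emulates the three instruments the analysis consumes: patient
#' questionnaires (per-activity contact reports with counts), medical-record
#' extracts (dated monitoring measurements, recorder discipline, and
#' medication flags), and care-provider surveys (per-activity reported contact
#' with each discipline, with configurable non-response and one-sided
#' reporting of true contacts). Returns the observable dataset together with
#' the latent ground truth so recovery can be tested.
#'
#' Non-responding patients have no questionnaire rows and, lacking consent, no
#' record extract; hospital-only CHF patients report contact with the medical
#' specialist only. Identical configurations (including the seed) yield
#' byte-identical datasets.
#'
#' @param config a [cohort_config()].
#' @return list with elements `dataset` (a `study_dataset`) and `truth`
#'   (class `synthetic_truth`: `true_patient_ties`, `true_provider_ties`,
#'   `true_monitoring_status` data frames).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- validate_cohort_config(config)
  seed <- cfg$rng_seed

  practice_ids <- paste0("pr", seq_len(cfg$n_practices))

  roster <- do.call(rbind, lapply(seq_len(cfg$n_practices), function(i) {
    counts <- cfg$practice_rosters[[i]]
    disc <- rep(names(counts), counts)
    idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
    data.frame(practice_id = practice_ids[i],
               professional_id = node_id_professional(practice_ids[i], disc, idx),
               discipline = disc,
               stringsAsFactors = FALSE)
  }))
  rownames(roster) <- NULL

  ## ---- patient stream: response, true ties, contacts, demographics --------
  pat <- do.call(rbind, lapply(seq_len(cfg$n_practices), function(i) {
    n_dm <- cfg$n_diabetes_per_practice[i]
    n_hf <- cfg$n_chf_per_practice[i]
    data.frame(
      practice_id = practice_ids[i],
      condition = rep(CONDITIONS, c(n_dm, n_hf)),
      stringsAsFactors = FALSE)
  }))
  pat$patient_id <- sprintf("pt%04d", seq_len(nrow(pat)))
  pat <- pat[, c("patient_id", "practice_id", "condition")]

  patient_out <- with_stream(seed, 1L, {
    n <- nrow(pat)
    responded <- stats::runif(n) < cfg$patient_response_rate
    hospital_only <- pat$condition == "chf" &
      stats::runif(n) < cfg$hospital_only_chf_rate
    age <- as.integer(round(stats::rnorm(n, mean = 72.8, sd = 10.7)))
    sex <- ifelse(stats::runif(n) < 0.44, "male", "female")

    # True patient-discipline contacts per activity (latent for everyone).
    grid <- expand.grid(patient_id = pat$patient_id, activity = ACTIVITIES,
                        discipline = DISCIPLINES, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$patient_id, grid$activity, grid$discipline), ]
    rownames(grid) <- NULL
    p <- mapply(function(a, d) cfg$tie_prob_patient[[a]][[d]] %||% 0,
                grid$activity, grid$discipline)
    grid$true_tie <- stats::runif(nrow(grid)) < p
    # Hospital-only CHF: every true contact is with the medical specialist.
    ho <- pat$patient_id[hospital_only]
    in_ho <- grid$patient_id %in% ho
    grid$true_tie[in_ho] <- grid$discipline[in_ho] == "medical_specialist" &
      stats::runif(sum(in_ho)) < 0.80
    lam <- cfg$contact_lambda[grid$activity]
    cnt <- integer(nrow(grid))
    cnt[grid$true_tie] <- rtruncpois(sum(grid$true_tie), lam[grid$true_tie])
    grid$n_contacts <- cnt
    list(responded = responded, hospital_only = hospital_only, age = age,
         sex = sex, ties = grid)
  })

  pat$responded <- patient_out$responded
  pat$consent <- patient_out$responded   # consent obtained with the questionnaire
  pat$hospital_only <- ifelse(pat$responded, patient_out$hospital_only, NA)
  pat$age <- patient_out$age
  pat$sex <- patient_out$sex

  ties <- patient_out$ties
  responders <- pat$patient_id[pat$responded]
  contacts <- ties[ties$patient_id %in% responders,
                   c("patient_id", "activity", "discipline", "true_tie",
                     "n_contacts")]
  names(contacts)[names(contacts) == "true_tie"] <- "contact"
  contacts$contact <- ifelse(contacts$contact, "yes", "no")
  rownames(contacts) <- NULL

  ## ---- provider stream: true dyads, asymmetric reports, non-response ------
  provider_out <- with_stream(seed, 2L, {
    responded <- stats::runif(nrow(roster)) < cfg$provider_response_rate
    true_dyads <- list()
    reports <- list()
    for (pid in practice_ids) {
      staff <- roster[roster$practice_id == pid, ]
      targets <- c(staff$professional_id, node_id_external(EXTERNAL_DISCIPLINES))
      target_disc <- c(staff$discipline, EXTERNAL_DISCIPLINES)
      pairs <- utils::combn(length(targets), 2)
      # Professional-professional and professional-external dyads; purely
      # external pairs carry no survey information and are never true here.
      keep <- pairs[1, ] <= nrow(staff)
      pairs <- pairs[, keep, drop = FALSE]
      for (a in ACTIVITIES) {
        tie <- stats::runif(ncol(pairs)) < cfg$tie_prob_provider[[a]]
        n_tie <- sum(tie)
        td <- data.frame(practice_id = rep(pid, n_tie),
                         activity = rep(a, n_tie),
                         id_a = targets[pairs[1, tie]],
                         id_b = targets[pairs[2, tie]],
                         stringsAsFactors = FALSE)
        true_dyads[[paste(pid, a)]] <- td
        # One side of a true within-practice dyad may fail to report it.
        both_staff <- grepl("^HP:", td$id_a) & grepl("^HP:", td$id_b)
        forget <- both_staff & stats::runif(nrow(td)) < cfg$report_asymmetry
        forget_side <- ifelse(stats::runif(nrow(td)) < 0.5, "a", "b")
        # Flags: professional x discipline, yes iff a remembered true dyad
        # links them to >= 1 member of that discipline (or the external node).
        flag <- matrix(FALSE, nrow(staff), length(DISCIPLINES),
                       dimnames = list(staff$professional_id, DISCIPLINES))
        if (nrow(td)) {
          for (k in seq_len(nrow(td))) {
            da <- target_disc[match(td$id_a[k], targets)]
            db <- target_disc[match(td$id_b[k], targets)]
            if (!(forget[k] && forget_side[k] == "a"))
              flag[td$id_a[k], db] <- TRUE
            if (grepl("^HP:", td$id_b[k]) &&
                !(forget[k] && forget_side[k] == "b"))
              flag[td$id_b[k], da] <- TRUE
          }
        }
        rep_df <- expand.grid(professional_id = staff$professional_id,
                              discipline = DISCIPLINES,
                              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        rep_df$practice_id <- pid
        rep_df$activity <- a
        rep_df$contact <- ifelse(flag[cbind(rep_df$professional_id,
                                            rep_df$discipline)], "yes", "no")
        reports[[paste(pid, a)]] <- rep_df
      }
    }
    true_dyads <- do.call(rbind, c(true_dyads, list(make.row.names = FALSE)))
    list(responded = responded, true_dyads = true_dyads,
         reports = do.call(rbind, reports))
  })

  providers <- provider_out$reports
  rownames(providers) <- NULL
  resp_map <- stats::setNames(provider_out$responded, roster$professional_id)
  providers$responded <- unname(resp_map[providers$professional_id])
  providers$contact[!providers$responded] <- NA
  providers <- providers[, c("professional_id", "practice_id", "responded",
                             "activity", "discipline", "contact")]
  providers <- providers[order(providers$professional_id, providers$activity,
                               providers$discipline), ]
  rownames(providers) <- NULL

  ## ---- records stream: monitoring measurements and treatment flags --------
  records_out <- with_stream(seed, 3L, {
    consented <- pat$patient_id[pat$consent]
    grid <- expand.grid(patient_id = consented,
                        parameter = MONITORING_PARAMETERS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cond <- pat$condition[match(grid$patient_id, pat$patient_id)]
    rate <- cfg$monitoring_rates[grid$parameter]
    rate[is.na(rate)] <- 0
    rate[grid$parameter == "hba1c" & cond != "diabetes"] <- 0
    grid$measured <- stats::runif(nrow(grid)) < rate

    recs <- list()
    mw <- grid[grid$measured, ]
    if (nrow(mw)) {
      n_in <- 1L + stats::rpois(nrow(mw), 0.8)
      mw_rep <- mw[rep(seq_len(nrow(mw)), n_in), ]
      mw_rep$date <- cfg$extraction_date -
        floor(stats::runif(nrow(mw_rep), 0, cfg$window_days))
      recs$inwin <- mw_rep
    }
    # Historical out-of-window measurements, regardless of in-window status.
    old <- grid[stats::runif(nrow(grid)) < 0.30, ]
    if (nrow(old)) {
      old$date <- cfg$extraction_date - cfg$window_days -
        floor(stats::runif(nrow(old), 1, 700))
      recs$old <- old
    }
    records <- do.call(rbind, lapply(recs, function(x)
      x[, c("patient_id", "parameter", "date")]))
    if (is.null(records))
      records <- data.frame(patient_id = character(), parameter = character(),
                            date = as.Date(character()))
    records$value <- round(stats::rlnorm(nrow(records), 3, 0.5), 1)
    # Each patient has a main monitoring discipline (mostly the practice
    # nurse) that records the bulk of the measurements.
    main_disc <- sample(IN_PRACTICE_DISCIPLINES, length(consented),
                        replace = TRUE, prob = c(0.25, 0.60, 0.15))
    names(main_disc) <- consented
    use_main <- stats::runif(nrow(records)) < 0.80
    records$discipline <- ifelse(
      use_main, main_disc[records$patient_id],
      sample(IN_PRACTICE_DISCIPLINES, nrow(records), replace = TRUE))
    records <- records[order(records$patient_id, records$parameter,
                             records$date), ]
    rownames(records) <- NULL

    tr <- matrix(NA, nrow(pat), length(TREATMENT_FLAGS),
                 dimnames = list(pat$patient_id, TREATMENT_FLAGS))
    for (cd in CONDITIONS) {
      idx <- which(pat$condition == cd & pat$consent)
      if (!length(idx)) next
      rates <- cfg$treatment_rates[[cd]][TREATMENT_FLAGS]
      rates[is.na(rates)] <- 0
      tr[idx, ] <- stats::runif(length(idx) * length(TREATMENT_FLAGS)) <
        rep(rates, each = length(idx))
    }
    list(records = records, treatment = tr, measured = grid)
  })

  pat <- cbind(pat, as.data.frame(records_out$treatment[pat$patient_id, ,
                                                        drop = FALSE]))
  rownames(pat) <- NULL

  dataset <- new_study_dataset(
    practices = roster, patients = pat, contacts = contacts,
    providers = providers, records = records_out$records,
    extraction_date = cfg$extraction_date, window_days = cfg$window_days)

  # Ground truth: resolved node ids for patient ties (every roster member of a
  # reported in-practice discipline; one collapsed node per external one).
  tt <- ties[ties$true_tie, c("patient_id", "activity", "discipline")]
  tt$practice_id <- pat$practice_id[match(tt$patient_id, pat$patient_id)]
  true_patient_ties <- resolve_discipline_nodes(tt, roster)

  truth <- structure(
    list(true_patient_ties = true_patient_ties,
         true_provider_ties = provider_out$true_dyads,
         true_monitoring_status = records_out$measured),
    class = "synthetic_truth")

  list(dataset = dataset, truth = truth)
}

# Zero-truncated Poisson draws (a reported contact implies >= 1 contact).
rtruncpois <- function(n, lambda) {
  if (n == 0) return(integer(0))
  x <- stats::rpois(n, lambda)
  while (any(zero <- x == 0)) x[zero] <- stats::rpois(sum(zero), lambda[zero])
  x
}

# Expand (patient, activity, discipline) contact rows to concrete node ids.
resolve_discipline_nodes <- function(rows, roster) {
  if (nrow(rows) == 0)
    return(data.frame(patient_id = character(), activity = character(),
                      node_id = character(), discipline = character()))
  out <- lapply(seq_len(nrow(rows)), function(k) {
    d <- rows$discipline[k]
    ids <- if (d %in% EXTERNAL_DISCIPLINES) {
      node_id_external(d)
    } else {
      roster$professional_id[roster$practice_id == rows$practice_id[k] &
                               roster$discipline == d]
    }
    if (!length(ids)) return(NULL)
    data.frame(patient_id = rows$patient_id[k], activity = rows$activity[k],
               node_id = ids, discipline = d, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mark provider surveys as missing
#'
#' Simulates additional provider non-response after generation: the named
#' professionals' surveys are marked not responded and all their per-activity
#' contact flags set missing. All other rows are untouched.
#'
#' @param dataset a `study_dataset`.
#' @param provider_missing_ids character vector of professional ids.
#' @return the modified `study_dataset`.
#' @export
degrade_responses <- function(dataset, provider_missing_ids) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (length(provider_missing_ids) == 0) return(dataset)
  unknown <- setdiff(provider_missing_ids, dataset$practices$professional_id)
  if (length(unknown))
    stop(sprintf("unknown professional id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  hit <- dataset$providers$professional_id %in% provider_missing_ids
  dataset$providers$responded[hit] <- FALSE
  dataset$providers$contact[hit] <- NA
  dataset
}
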