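# Builders for small handmade datasets used across the unit tests.

mk_roster <- function(practice_id = "pr1",
                      counts = c(gp = 1L, practice_nurse = 1L,
                                 practice_assistant = 1L)) {
  disc <- rep(names(counts), counts)
  idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
  data.frame(practice_id = practice_id,
             professional_id = node_id_professional(practice_id, disc, idx),
             discipline = disc, stringsAsFactors = FALSE)
}

mk_patients <- function(ids, practice_id = "pr1", condition = "diabetes",
                        responded = TRUE, consent = responded,
                        hospital_only = FALSE) {
  df <- data.frame(patient_id = ids, practice_id = practice_id,
                   condition = condition, responded = responded,
                   consent = consent, hospital_only = hospital_only,
                   age = 70L, sex = "female", stringsAsFactors = FALSE)
  for (f in TREATMENT_FLAGS) df[[f]] <- NA
  df
}

# Full yes/no contact grid for one patient; `yes` is a named list
# activity -> disciplines reported, counts default to 1 per reported tie.
mk_contacts <- function(patient_id, yes = list()) {
  g <- expand.grid(patient_id = patient_id, activity = ACTIVITIES,
                   discipline = DISCIPLINES, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g$contact <- rep("no", nrow(g))
  g$n_contacts <- rep(0L, nrow(g))
  for (a in names(yes)) {
    hit <- g$activity == a & g$discipline %in% yes[[a]]
    g$contact[hit] <- "yes"
    g$n_contacts[hit] <- 1L
  }
  g
}

# Provider survey grid; `yes` is a named list professional_id -> list
# activity -> disciplines reported. Non-responders get all-missing flags.
mk_providers <- function(roster, responders = roster$professional_id,
                         yes = list()) {
  g <- expand.grid(professional_id = roster$professional_id,
                   activity = ACTIVITIES, discipline = DISCIPLINES,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$practice_id <- roster$practice_id[match(g$professional_id,
                                            roster$professional_id)]
  g$responded <- g$professional_id %in% responders
  g$contact <- ifelse(g$responded, "no", NA)
  for (id in names(yes)) {
    for (a in names(yes[[id]])) {
      hit <- g$professional_id == id & g$activity == a &
        g$discipline %in% yes[[id]][[a]]
      g$contact[hit & g$responded] <- "yes"
    }
  }
  g[, c("professional_id", "practice_id", "responded", "activity",
        "discipline", "contact")]
}

mk_records <- function(patient_id = character(0), parameter = character(0),
                       date = as.Date(character(0)),
                       discipline = character(0)) {
  data.frame(patient_id = patient_id, parameter = parameter,
             date = as.Date(date),
             value = rep(1, length(patient_id)),
             discipline = discipline, stringsAsFactors = FALSE)
}

mk_dataset <- function(roster = mk_roster(), patients, contacts = NULL,
                       providers = NULL, records = mk_records(),
                       extraction_date = as.Date("2010-06-30"),
                       window_days = 365) {
  if (is.null(contacts))
    contacts <- mk_contacts(character(0))[0, ]
  if (is.null(providers))
    providers <- mk_providers(roster)
  new_study_dataset(roster, patients, contacts, providers, records,
                    extraction_date, window_days)
}

# A small randomized cohort with <= 6 professionals, for construction oracles.
small_cohort <- function(seed) {
  cfg <- cohort_config(
    n_practices = 2,
    practice_rosters = list(
      c(gp = 1L, practice_nurse = 1L, practice_assistant = 1L),
      c(gp = 2L, practice_nurse = 1L)),
    n_diabetes_per_practice = 3,
    n_chf_per_practice = 3,
    provider_response_rate = 0.7,
    rng_seed = seed)
  generate_cohort(cfg)
}
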