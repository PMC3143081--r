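test_that("cohort structure follows the configuration", {
  out <- generate_cohort(cohort_config(rng_seed = 7))
  ds <- out$dataset
  expect_equal(nrow(ds$patients), 57)   # 30 diabetes + 27 CHF invited
  expect_equal(length(unique(ds$practices$practice_id)), 3)
  expect_equal(nrow(ds$practices), 22)
  expect_setequal(unique(ds$patients$condition), CONDITIONS)

  big <- generate_cohort(cohort_config(
    n_chf_per_practice = 10, rng_seed = 7))
  expect_equal(nrow(big$dataset$patients), 60)
})

test_that("generation is deterministic in the seed and streams are split", {
  a <- generate_cohort(cohort_config(rng_seed = 11))
  b <- generate_cohort(cohort_config(rng_seed = 11))
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(rng_seed = 12))
  expect_false(identical(a$dataset$contacts, c$dataset$contacts))

  # Enlarging the patient table must not perturb the provider stream.
  small <- generate_cohort(cohort_config(rng_seed = 11))
  large <- generate_cohort(cohort_config(n_diabetes_per_practice = 20,
                                         rng_seed = 11))
  expect_identical(small$dataset$providers, large$dataset$providers)
})

test_that("degenerate response rates behave as specified", {
  none <- generate_cohort(cohort_config(patient_response_rate = 0,
                                        rng_seed = 3))$dataset
  expect_equal(nrow(none$contacts), 0)
  expect_false(any(none$patients$responded))
  expect_equal(nrow(none$records), 0)  # no consent, no chart extraction

  all_resp <- generate_cohort(cohort_config(patient_response_rate = 1,
                                            hospital_only_chf_rate = 0,
                                            rng_seed = 3))$dataset
  expect_true(all(all_resp$patients$responded))
})

test_that("certain ties with symmetric reporting give exact dyad agreement", {
  certain <- default_tie_prob_patient()
  for (a in ACTIVITIES) certain[[a]][] <- 1
  out <- generate_cohort(cohort_config(
    tie_prob_patient = certain,
    tie_prob_provider = c(treatment = 1, advice = 1, monitoring = 1),
    report_asymmetry = 0,
    patient_response_rate = 1,
    provider_response_rate = 1,
    hospital_only_chf_rate = 0,
    rng_seed = 5))
  ds <- out$dataset
  # Every responder reports every discipline for treatment: a treatment
  # network exists for every patient.
  tr <- ds$contacts[ds$contacts$activity == "treatment", ]
  expect_true(all(tr$contact == "yes"))
  # Exhaustive scan: every provider dyad report is mutually "yes".
  pv <- ds$providers
  for (pid in unique(ds$practices$practice_id)) {
    expect_equal(reciprocity(pv, pid), 1.0)
  }
})

test_that("configuration errors name the offending field", {
  expect_error(cohort_config(patient_response_rate = 1.2),
               "patient_response_rate")
  expect_error(cohort_config(n_practices = 1, practice_rosters =
                               list(c(practice_nurse = 2L))),
               "practice_rosters")
  expect_error(cohort_config(window_days = 0), "window_days")
  expect_error(cohort_config(tie_prob_provider = c(treatment = 0.5)),
               "tie_prob_provider")
})

test_that("empirical rates recover their configured values at scale", {
  cfg <- cohort_config(n_diabetes_per_practice = 200,
                       n_chf_per_practice = 0,
                       hospital_only_chf_rate = 0,
                       rng_seed = 19)
  ds <- generate_cohort(cfg)$dataset
  n <- nrow(ds$patients)
  p <- cfg$patient_response_rate
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(ds$patients$responded) - p), 3 * se)

  # Patient-reported tie frequency per activity x discipline (diabetes
  # patients follow the configured map directly).
  ct <- ds$contacts
  n_resp <- length(unique(ct$patient_id))
  for (a in ACTIVITIES) {
    for (d in c("gp", "practice_nurse", "pharmacist")) {
      pr <- cfg$tie_prob_patient[[a]][[d]]
      emp <- mean(ct$contact[ct$activity == a & ct$discipline == d] == "yes")
      expect_lt(abs(emp - pr), 3 * sqrt(pr * (1 - pr) / n_resp) + 1e-9)
    }
  }
})

test_that("degrade_responses blanks exactly the named surveys", {
  ds <- generate_cohort(cohort_config(rng_seed = 2))$dataset
  expect_identical(degrade_responses(ds, character(0)), ds)
  expect_error(degrade_responses(ds, "HP:nowhere:gp:1"), "unknown")

  p1 <- ds$practices$professional_id[ds$practices$practice_id == "pr1"]
  deg <- degrade_responses(ds, p1)
  hit <- deg$providers$professional_id %in% p1
  expect_true(all(is.na(deg$providers$contact[hit])))
  expect_false(any(deg$providers$responded[hit]))
  expect_identical(deg$providers[!hit, ], ds$providers[!hit, ])
  # With the whole practice missing, no practice-1 dyad has a report on
  # either side: reciprocity is undefined there.
  expect_error(reciprocity(deg$providers, "pr1"), "2 responding")
})

test_that("a one-sided survey still resolves dyads against the truth", {
  out <- generate_cohort(cohort_config(
    n_practices = 1,
    practice_rosters = list(c(gp = 1L, practice_nurse = 1L)),
    n_diabetes_per_practice = 4, n_chf_per_practice = 0,
    patient_response_rate = 1, provider_response_rate = 1,
    report_asymmetry = 0, rng_seed = 23))
  ds <- degrade_responses(out$dataset, "HP:pr1:practice_nurse:1")
  built <- build_networks(ds)
  gp <- "HP:pr1:gp:1"; pn <- "HP:pr1:practice_nurse:1"
  for (net in built$networks) {
    if (!all(c(gp, pn) %in% net$nodes$id)) next
    truth <- out$truth$true_provider_ties
    truly_tied <- any(truth$activity == net$activity &
                        ((truth$id_a == gp & truth$id_b == pn) |
                           (truth$id_a == pn & truth$id_b == gp)))
    expect_equal(unname(net$adjacency[gp, pn]), as.numeric(truly_tied))
    if (truly_tied)
      expect_equal(unname(net$provenance[gp, pn]), "substituted")
  }
})
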