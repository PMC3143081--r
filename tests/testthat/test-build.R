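roster2 <- mk_roster("pr1", c(gp = 2L, practice_nurse = 1L,
                              practice_assistant = 1L))

test_that("patient ties union questionnaire and chart sources", {
  pats <- mk_patients("a")
  ct <- mk_contacts("a", yes = list(monitoring = "gp"))
  rec <- mk_records("a", "creatinine", as.Date("2010-05-01"), "dietician")
  ds <- mk_dataset(roster2, pats, ct, records = rec)
  b <- patient_bundle(ds, "a")
  ties <- patient_ties(b, ds$practices, "monitoring")
  expect_setequal(ties$discipline, c("gp", "dietician"))
  expect_equal(sort(ties$node_id),
               sort(c("HP:pr1:gp:1", "HP:pr1:gp:2", "EXT:dietician")))
  expect_equal(ties$provenance[ties$discipline == "dietician"],
               "chart-derived")
  # Chart-derived contacts feed monitoring only.
  expect_equal(nrow(patient_ties(b, ds$practices, "treatment")), 0)
})

test_that("no reports and an empty chart give an empty tie set", {
  ds <- mk_dataset(roster2, mk_patients("a"), mk_contacts("a"))
  ties <- patient_ties(patient_bundle(ds, "a"), ds$practices, "treatment")
  expect_equal(nrow(ties), 0)
})

test_that("a reported practice-nurse contact with count maps to the nurse node", {
  ct <- mk_contacts("a", yes = list(treatment = "practice_nurse"))
  ct$n_contacts[ct$contact == "yes"] <- 3L
  ds <- mk_dataset(roster2, mk_patients("a"), ct)
  ties <- patient_ties(patient_bundle(ds, "a"), ds$practices, "treatment")
  expect_equal(ties$node_id, "HP:pr1:practice_nurse:1")
})

test_that("practice expansion adds the whole roster, once", {
  expect_setequal(expand_practice("HP:pr1:gp:1", roster2),
                  roster2$professional_id)
  # External-only ties do not trigger the rule.
  expect_equal(expand_practice("EXT:physiotherapist", roster2),
               "EXT:physiotherapist")
  # Idempotent on its own output.
  once <- expand_practice("HP:pr1:gp:1", roster2)
  expect_setequal(expand_practice(once, roster2), once)
  expect_error(expand_practice("HP:prX:gp:1", roster2), "no roster")
})

test_that("discipline-level reports create ties to every individual of it", {
  ct <- mk_contacts("a", yes = list(treatment = "gp"))
  ds <- mk_dataset(roster2, mk_patients("a"), ct)
  net <- assemble(ds, "a", "treatment")
  expect_equal(unname(net$adjacency["P:a", c("HP:pr1:gp:1", "HP:pr1:gp:2")]),
               c(1, 1))
})

test_that("cross-activity union shares nodes but not ties", {
  sets <- list(treatment = c("A"), advice = c("B"), monitoring = c("C"))
  un <- cross_activity_union(sets)
  for (s in un) expect_setequal(s, c("A", "B", "C"))
  same <- list(treatment = c("A", "B"), advice = c("A", "B"))
  expect_equal(cross_activity_union(same)$treatment, c("A", "B"))
  expect_identical(cross_activity_union(un), un)  # fixed point

  # End to end: a physiotherapist reported for advice only appears as a node
  # in the treatment network without a patient tie there.
  ct <- mk_contacts("a", yes = list(treatment = "gp",
                                    advice = "physiotherapist"))
  ds <- mk_dataset(roster2, mk_patients("a"), ct)
  tr <- assemble(ds, "a", "treatment")
  expect_true("EXT:physiotherapist" %in% tr$nodes$id)
  expect_equal(unname(tr$adjacency["P:a", "EXT:physiotherapist"]), 0)
  ad <- assemble(ds, "a", "advice")
  expect_equal(unname(ad$adjacency["P:a", "EXT:physiotherapist"]), 1)
  expect_setequal(tr$nodes$id, ad$nodes$id)
})

test_that("provider dyads follow the one-or-both rule with substitution and zero-fill", {
  gp1 <- "HP:pr1:gp:1"; gp2 <- "HP:pr1:gp:2"
  pn <- "HP:pr1:practice_nurse:1"; pa <- "HP:pr1:practice_assistant:1"
  nodes <- c(gp1, gp2, pn, pa)

  # gp1 reports contact with the nurse, the nurse denies: tie present.
  pv <- mk_providers(roster2, yes = list(
    `HP:pr1:gp:1` = list(treatment = "practice_nurse")))
  ties <- provider_ties(nodes, pv, "treatment")
  expect_equal(unname(ties$adjacency[gp1, pn]), 1)
  expect_equal(unname(ties$provenance[gp1, pn]), "provider-reported")
  # Both deny: absent.
  expect_equal(unname(ties$adjacency[gp2, pa]), 0)
  expect_equal(unname(ties$provenance[gp2, pa]), "absent")

  # Nurse missing, gp reports yes: substituted. Assistant also missing and
  # nobody reports: zero-filled.
  pv <- mk_providers(roster2, responders = c(gp1, gp2),
                     yes = list(`HP:pr1:gp:1` =
                                  list(treatment = "practice_nurse")))
  ties <- provider_ties(nodes, pv, "treatment")
  expect_equal(unname(ties$adjacency[gp1, pn]), 1)
  expect_equal(unname(ties$provenance[gp1, pn]), "substituted")
  expect_equal(unname(ties$adjacency[pn, pa]), 0)
  expect_equal(unname(ties$provenance[pn, pa]), "zero-filled-absent")

  # Union rule is monotone: adding a report never removes a tie.
  pv1 <- mk_providers(roster2, yes = list(
    `HP:pr1:gp:1` = list(treatment = "practice_nurse")))
  pv2 <- mk_providers(roster2, yes = list(
    `HP:pr1:gp:1` = list(treatment = c("practice_nurse", "gp")),
    `HP:pr1:practice_nurse:1` = list(treatment = "gp")))
  t1 <- provider_ties(nodes, pv1, "treatment")
  t2 <- provider_ties(nodes, pv2, "treatment")
  expect_true(all(t2$adjacency >= t1$adjacency))
  expect_equal(unname(t2$provenance[gp1, pn]), "provider-reported")
})

test_that("networks only exist where the patient reported a connection", {
  ct <- mk_contacts("a", yes = list(treatment = "gp"))
  ds <- mk_dataset(roster2, mk_patients("a"), ct)
  expect_s3_class(assemble(ds, "a", "treatment"), "ego_network")
  expect_null(assemble(ds, "a", "advice"))
  expect_null(assemble(ds, "a", "monitoring"))

  # Chart-only monitoring contact: exists after merge, not before.
  rec <- mk_records("a", "creatinine", as.Date("2010-05-01"), "gp")
  ds2 <- mk_dataset(roster2, mk_patients("a"), ct, records = rec)
  expect_s3_class(assemble(ds2, "a", "monitoring"), "ego_network")
  expect_null(assemble(ds2, "a", "monitoring", existence = "before_merge"))
})

test_that("with certain ties the network contains roster + externals + ego", {
  certain <- default_tie_prob_patient()
  for (a in ACTIVITIES) certain[[a]][] <- 1
  cfg <- cohort_config(n_practices = 1,
                       practice_rosters = list(c(gp = 2L, practice_nurse = 1L,
                                                 practice_assistant = 1L)),
                       n_diabetes_per_practice = 2, n_chf_per_practice = 0,
                       tie_prob_patient = certain,
                       patient_response_rate = 1, rng_seed = 9)
  ds <- generate_cohort(cfg)$dataset
  net <- assemble(ds, ds$patients$patient_id[1], "treatment")
  expect_equal(nrow(net$nodes), 4 + length(EXTERNAL_DISCIPLINES) + 1)
})

test_that("exclusions run consent -> zero-connection -> hospital-only", {
  roster <- mk_roster()
  pats <- mk_patients(c("resp", "zero", "hosp", "none"))
  pats$responded[pats$patient_id == "none"] <- FALSE
  pats$consent[pats$patient_id == "none"] <- FALSE
  pats$hospital_only[pats$patient_id == "none"] <- NA
  pats$hospital_only[pats$patient_id == "hosp"] <- TRUE
  ct <- rbind(mk_contacts("resp", yes = list(treatment = "gp")),
              mk_contacts("zero"),
              mk_contacts("hosp", yes = list(monitoring =
                                               "medical_specialist")))
  ds <- mk_dataset(roster, pats, ct)
  ex <- apply_exclusions(ds)
  expect_equal(ex$analyzable, "resp")
  got <- ex$exclusions$reason[match(c("none", "zero", "hosp"),
                                    ex$exclusions$patient_id)]
  expect_equal(got, c("no_response_or_consent", "no_connections",
                      "hospital_only"))
  # Identity when nothing triggers.
  ds2 <- mk_dataset(roster, mk_patients("resp"),
                    mk_contacts("resp", yes = list(treatment = "gp")))
  ex2 <- apply_exclusions(ds2)
  expect_equal(ex2$analyzable, "resp")
  expect_equal(nrow(ex2$exclusions), 0)
})

test_that("hospital-only flags remove all CHF patients when set", {
  ds <- generate_cohort(cohort_config(hospital_only_chf_rate = 1,
                                      rng_seed = 17))$dataset
  ex <- apply_exclusions(ds)
  cond <- ds$patients$condition[match(ex$analyzable,
                                      ds$patients$patient_id)]
  expect_true(all(cond == "diabetes"))
})

test_that("constructed networks satisfy the structural invariants", {
  for (seed in c(1, 2)) {
    built <- build_networks(generate_cohort(
      cohort_config(rng_seed = seed))$dataset)
    for (net in built$networks) {
      adj <- net$adjacency
      expect_equal(adj, t(adj))
      expect_true(all(diag(adj) == 0))
      expect_true(all(adj %in% c(0, 1)))
      ego <- ego_id(net)
      expect_gte(sum(adj[ego, ]), 1)
      # All activity networks of a patient share one node set.
      expect_s3_class(validate_ego_network(net), "ego_network")
    }
    pt <- vapply(built$networks, function(n) n$patient_id, character(1))
    for (pid in unique(pt)) {
      sets <- lapply(built$networks[pt == pid], function(n) n$nodes$id)
      for (s in sets) expect_setequal(s, sets[[1]])
    }
  }
})

test_that("the independent dyad enumerator reconstructs small cohorts", {
  out <- small_cohort(seed = 101)
  ds <- out$dataset
  built <- build_networks(ds)
  expect_gt(length(built$networks), 0)
  for (net in built$networks) {
    bf <- bf_assemble(ds, net$patient_id, net$activity)
    expect_setequal(net$nodes$id, bf$ids)
    expect_equal(net$adjacency[bf$ids, bf$ids], bf$adjacency)
    expect_equal(net$provenance[bf$ids, bf$ids], bf$provenance)
  }
})
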