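Package: careteamnet
Title: Ego-Centered Network Analysis of Patient Care Teams in Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs and analyzes activity-specific ego-centered networks
    around chronic-disease patients (type 2 diabetes, chronic heart failure)
    in primary care. Reconstructs patient-professional ties from patient
    questionnaires and medical-record extracts, professional-professional ties
    from care-provider surveys using a one-or-both reporting rule with
    within-practice substitution for missing respondents, and computes the
    network parameter families used in care-team research: size, discipline
    diversity, density, Freeman degree centralization, degree centrality of
    the patient and of the most central professional, and activity-network
    overlap. Includes a synthetic cohort generator emulating the multi-source
    survey structure, clinical monitoring indicators (including a
    comprehensive-monitoring composite), dyadic reciprocity of provider
    reports, and Mann-Whitney group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
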