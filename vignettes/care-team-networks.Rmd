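---
title: "Measuring patient care teams as ego-centered networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring patient care teams as ego-centered networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careteamnet)
```

## The measurement problem

Chronic conditions such as type 2 diabetes and chronic heart failure (CHF)
are managed by teams: a general practitioner (GP), practice nurses and
assistants inside a primary-care practice, and external disciplines such as
physiotherapists, dieticians, pharmacists and hospital specialists. Two
team properties are widely hypothesised to matter for the care a patient
actually receives: the presence of a central coordinating professional, and
an active role of the patient in the web of contacts. Neither is observable
from a single instrument. `careteamnet` implements a multi-source
measurement design: for each patient, three *activity-specific ego-centered
networks* — medical treatment, physical exercise advice, and disease
monitoring — are reconstructed from (1) a patient questionnaire reporting
per-activity contacts by discipline with contact counts, (2) the patient's
medical record, and (3) a written survey among the practice's care
providers reporting per-activity contact with each discipline.

## Construction procedure

Networks are undirected and binary, and are built in two steps.

**Step 1 — patient ties.** The patient is connected to every professional
named by the questionnaire or inferable from the chart (for the monitoring
activity, the disciplines that recorded an in-window measurement). Both
instruments name *disciplines*, not individuals, so a reported contact with
"practice nurse" creates a tie to every nurse on the roster. This is a
known overestimation mechanism of discipline-level instruments; we
reproduce it deliberately and record tie provenance
(`patient-reported` / `chart-derived`) so its effect stays visible.
External disciplines are collapsed to one node each (`EXT:dietician`, ...),
which conversely underestimates outside involvement.

**Step 2 — provider ties.** For every professional dyad, a tie is present
if *either one or both* sides reported contact with the other's discipline
for the activity. A missing survey is substituted by the response of the
other individual in the practice (provenance `substituted`); when neither
side provides information a zero is filled in (`zero-filled-absent`), so a
zero means "no contact" or "no data". Collapsed external nodes are never
surveyed; their ties rest entirely on the in-practice side's report and are
labelled `provider-reported`, since no within-practice substitution takes
place. Purely external dyads are always zero-filled.

Two membership rules complete the construction. If the patient has contact
with anyone inside a practice, the *whole practice roster* joins the node
set; and a professional involved in one activity-specific network of a
patient joins the patient's other activity networks as a node (ties are not
copied). A network is only constructed for an activity in which the patient
reported at least one connection; patients without any deducible connection,
without questionnaire/consent, or whose care was delivered entirely in
hospital are excluded, in that order.

Two points are not fixed by the design and had to be decided here. First,
whether the at-least-one-connection existence test runs before or after
chart-derived ties are merged: we evaluate it **after the merge** (a chart
contact is evidence of a real care relation), with
`existence = "before_merge"` available as a switch. Second, hospital
professionals appearing in the charts of retained patients enter only
through the ordinary discipline mapping (as the collapsed
`medical_specialist` node); we do not invent additional individual hospital
nodes.

## Network parameters

For a network with $n$ nodes (the patient counts toward $n$) and degree
sequence $d_1,\dots,d_n$:

* **size** — number of professionals ($n-1$); **diversity** — number of
  distinct disciplines among them;
* **density** $= \#\text{ties} / \binom{n}{2}$, on 0–1;
* **degree centrality** of node $i$: $100\, d_i/(n-1)$, reported for the
  patient and for the most central professional (patient ineligible);
* **Freeman degree centralization**
  $100 \sum_i (d_{\max}-d_i)/\big((n-1)(n-2)\big)$: 100 for a star, 0 for
  any regular network;
* **overlap** between two activity networks of one patient: the simple
  matching coefficient — the share of dyads with the same tie status
  (present *or* absent) in both. With the union of the two node sets as
  dyad universe the coefficient is symmetric; an index-network variant
  (`universe = "index"`) is available because asymmetric readings of the
  definition exist.

The patient node is included in the denominators of density, degree and
centralization but excluded from size and diversity: reported patient
degrees near 50% are only consistent with the ego inside the graph, while
"number of professionals" plainly excludes it. Degree and centralization
are reported on 0–100 and density on 0–1, following the convention of the
feasibility literature this design comes from.

Ties between most-central candidates are broken deterministically: higher
degree, then in-practice before external, then discipline priority (GP
first), then lexical node id. GP-led practices make the GP the natural
modal central discipline; the rule only matters for exact ties.

**Reciprocity** of provider reports — the reliability check — is the share
of professional dyads whose two members agree (both report the contact
present, or both absent), computed over dyads where both surveys were
returned and pooled across the three activities. Pooling (rather than
averaging per-activity coefficients) weights every dyad–activity judgement
equally; with complete surveys the two choices coincide.

## The synthetic cohort generator

No raw questionnaires are publicly available, so the package ships a
generator that emulates the study conditions: 3 GP-led practices with
rosters of 6, 6 and 10 staff (22 providers), 10 diabetes patients invited
per practice and 10/10/7 CHF patients (one practice could identify only 7),
a patient response-and-consent rate of 0.56, a provider response rate of
0.909, and a 0.30 rate of responding CHF patients whose care was entirely
hospital-based (their contacts collapse onto the medical specialist).

Latent truth is generated first and observed through the instruments:

* patient–discipline contacts per activity are Bernoulli draws with
  per-discipline probabilities (GP highest, ~0.7 for treatment and
  monitoring); contact counts given a tie are zero-truncated Poisson
  (means 2.5/1.2/3.5 per activity) — counts are generated for realism and
  contact-count summaries, presence drives the networks;
* provider dyads (professional pairs and professional–external pairs) are
  Bernoulli with per-activity rates 0.30/0.18/0.28; each true
  within-practice dyad is reported by both sides unless, with probability
  0.35, one randomly chosen side fails to report it. Because reports are
  aggregated to discipline level, one true dyad can surface as several
  observed ties — the same overestimation the construction rules propagate;
* monitoring measurements per parameter are Bernoulli (e.g. systolic BP
  0.95, creatinine 0.55; HbA1c for diabetes only) with 1–3 in-window dated
  records each, plus out-of-window historical records at rate 0.30; each
  patient has a main recording discipline (mostly the practice nurse) that
  writes ~80% of the chart entries; medication flags are drawn per
  condition at guideline-plausible rates.

These defaults were chosen once to land the emitted tables in the realistic
range for this setting (response rates near 50%/90%, network sizes around
8, densities 0.3–0.55, dyadic agreement 0.5–0.9) and are documented here
rather than claimed to match any particular study; the distribution of
contact counts in particular is unreported in the literature and the
Poisson means are conventions. Three independent RNG streams (patients,
providers, records) are split from the master seed, so enlarging the
patient table never perturbs provider draws. Identical configurations give
byte-identical datasets.

What the generator does *not* emulate: longitudinal disease progression,
realistic laboratory values (values are log-normal placeholders),
correlation between monitoring parameters (flags are independent, so the
comprehensive-monitoring rate has the closed form
$(1-(1-p_w)(1-p_b))\,p_{sbp}\,p_{cr}$), or any true association between
network structure and monitoring. Passing recovery tests therefore shows
the pipeline measures what the generator encodes — not that real care teams
behave this way.

## Clinical indicators

A parameter counts as monitored if at least one record falls in the window
$(\text{reference} - 365\text{d}, \text{reference}]$ — half-open at the
start, inclusive at the reference day; the one-day boundary ambiguity is
resolved in favour of the reference day. The reference date is the chart
extraction date, a dataset-level field, not a per-patient anchor.
**Comprehensive monitoring** is the composite: (BMI *or* weight) and
systolic blood pressure and creatinine each measured in-window. It is
monotone — adding records can only switch it on.

## Statistical comparisons

Group differences (diabetes vs CHF; comprehensive monitoring received vs
not) are tested with the two-sided Mann–Whitney test: exact enumeration
when the combined sample is ≤ 12 without ties, otherwise the normal
approximation with tie and continuity correction (both routes are exposed
via the `exact` argument, since either could have been used at these sample
sizes in the original SPSS workflow). No multiplicity correction is applied
by default, matching the exploratory framing; `stats::p.adjust` composes
trivially with the report if wanted. Percentages are rendered to one
decimal and reciprocity to three; raw CSV output keeps full precision.

## Verification strategy and problem sizes

The test suite checks the mathematics against independent routes rather
than against itself:

* metric functions agree with a brute-force dyad enumerator on **all**
  graphs with up to 6 nodes (33,544 graphs) and on 1,000 random graphs up
  to 10 nodes, and with igraph after rescaling its centralization
  denominator ($n(n-1)$ there vs Freeman's $(n-1)(n-2)$);
* the full construction — union rule, substitution, zero-fill, roster
  expansion, cross-activity membership — is reproduced tie-for-tie and
  provenance-for-provenance by an independent single-pass enumerator on
  small cohorts (≤ 6 professionals);
* the exact Mann–Whitney path equals full enumeration of all group
  assignments for every split with $n_a+n_b \le 10$; its size under the
  null is estimated at 0.05 ± 0.01 from 5,000 replicates in which a fresh
  independent monitoring outcome is drawn over a fixed cohort of 210
  invited patients — a size chosen so the approximate path operates in its
  intended regime;
* generator recovery runs at ~1,000 invited patients: response rates, tie
  frequencies and the comprehensive-monitoring rate fall within 3 standard
  errors of their configured values.

## A small worked example

```{r example}
sim <- generate_cohort(cohort_config(rng_seed = 42))
built <- build_networks(sim$dataset)
params <- parameter_table(built$networks)
aggregate(cbind(size, density, centralization, patient_degree) ~ activity,
          params, function(x) round(mean(x), 2))
feasibility(sim$dataset, built)$reciprocity
```

## Known limitations

Provider surveys describe practice-level collaboration, not contacts about
the individual patient, so professional–professional ties are shared across
all patients of a practice and network size is strongly driven by practice
size — parameters across patients of one practice are not independent, and
the package accordingly stops at descriptive comparisons and rank tests
rather than regression or multilevel modelling. Discipline-level reporting
overestimates within-practice ties; collapsing external disciplines
underestimates outside involvement. All ties are binary and undirected;
contact counts inform summaries only.
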