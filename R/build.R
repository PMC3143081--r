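#' Patient-professional ties for one activity
#'
#' First step of the two-step construction: the professionals the patient is
#' directly connected to for an activity, as the union of questionnaire
#' reports and chart-derived contacts. Discipline-level reports expand to
#' every roster member of that discipline in the patient's practice (an
#' acknowledged overestimation mechanism of discipline-level instruments);
#' external disciplines map to one collapsed node each. Chart-derived
#' contacts (the disciplines that recorded an in-window measurement) feed the
#' `monitoring` activity only.
#'
#' @param bundle a [patient_bundle()].
#' @param roster practices roster table (`practice_id`, `professional_id`,
#'   `discipline`).
#' @param activity one of `treatment`, `advice`, `monitoring`.
#' @param use_chart include chart-derived contacts (monitoring only).
#' @return data frame `node_id`, `discipline`, `provenance`
#'   (`patient-reported` / `chart-derived`); zero rows when the patient has
#'   no connection for the activity.
#' @export
patient_ties <- function(bundle, roster, activity, use_chart = TRUE) {
  stopifnot(inherits(bundle, "patient_bundle"), activity %in% ACTIVITIES)
  ct <- bundle$contacts
  q_disc <- unique(ct$discipline[ct$activity == activity &
                                   !is.na(ct$contact) & ct$contact == "yes"])
  chart_disc <- if (use_chart && activity == "monitoring" && bundle$consent) {
    setdiff(bundle$chart_contacts, q_disc)
  } else {
    character(0)
  }
  rows <- data.frame(
    discipline = c(q_disc, chart_disc),
    provenance = rep(c("patient-reported", "chart-derived"),
                     c(length(q_disc), length(chart_disc))),
    stringsAsFactors = FALSE)
  if (nrow(rows) == 0)
    return(data.frame(node_id = character(), discipline = character(),
                      provenance = character(), stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(rows)), function(k) {
    d <- rows$discipline[k]
    ids <- if (d %in% EXTERNAL_DISCIPLINES) {
      node_id_external(d)
    } else {
      roster$professional_id[roster$practice_id == bundle$practice_id &
                               roster$discipline == d]
    }
    if (!length(ids)) return(NULL)
    data.frame(node_id = ids, discipline = d, provenance = rows$provenance[k],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(node_id = character(), discipline = character(),
                      provenance = character(), stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

#' Practice-roster expansion of a node set
#'
#' If the patient has contact with anyone inside a general practice, all
#' health professionals of that practice are included in the constructed
#' network. Only the node set grows; patient ties are unchanged.
#'
#' @param node_ids character vector of node ids (the patient's direct ties).
#' @param roster practices roster table.
#' @return character vector: `node_ids` plus any roster completion.
#' @export
expand_practice <- function(node_ids, roster) {
  hp <- node_ids[startsWith(node_ids, "HP:")]
  if (!length(hp)) return(node_ids)
  prac <- unique(vapply(strsplit(hp, ":", fixed = TRUE), `[[`, "", 2))
  missing_prac <- setdiff(prac, roster$practice_id)
  if (length(missing_prac))
    stop(sprintf("no roster for referenced practice '%s'", missing_prac[1]),
         call. = FALSE)
  union(node_ids, roster$professional_id[roster$practice_id %in% prac])
}

#' Cross-activity union of node sets
#'
#' A professional involved in one activity-specific network of a patient is
#' included (as a node) in the patient's other activity-specific networks as
#' well. Ties are not copied, only node membership; the operation is
#' idempotent.
#'
#' @param node_sets named list (per activity) of node id vectors.
#' @return the same list with every element replaced by the union.
#' @export
cross_activity_union <- function(node_sets) {
  all_ids <- unique(unlist(node_sets, use.names = FALSE))
  lapply(node_sets, function(x) all_ids)
}

#' Professional-professional ties from provider surveys
#'
#' Second construction step: for every professional dyad, a tie is present if
#' either one or both sides reported patient-related contact with the other's
#' discipline for this activity. A missing survey is substituted by the
#' response of the other individual in the practice (provenance
#' `substituted`); a zero is filled in when neither side provided information
#' (provenance `zero-filled-absent`). Collapsed external-discipline nodes
#' have no survey, so their ties rest on the in-practice side's report.
#'
#' @param node_ids professional node ids (in-practice `HP:` and external
#'   `EXT:`).
#' @param providers provider survey table of a `study_dataset`.
#' @param activity one of the three activities.
#' @return list with `adjacency` and `provenance` matrices over `node_ids`.
#' @export
provider_ties <- function(node_ids, providers, activity) {
  n <- length(node_ids)
  adj <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  prov <- matrix(NA_character_, n, n, dimnames = list(node_ids, node_ids))
  if (n < 2) return(list(adjacency = adj, provenance = prov))
  disc <- node_discipline(node_ids)
  pv <- providers[providers$activity == activity, ]
  flag <- stats::setNames(pv$contact, paste(pv$professional_id, pv$discipline))
  report_of <- function(id, about_disc) {
    if (!startsWith(id, "HP:")) return(NA_character_)
    unname(flag[paste(id, about_disc)])
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ri <- report_of(node_ids[i], disc[j])
      rj <- report_of(node_ids[j], disc[i])
      reports <- c(ri, rj)
      informative <- reports[!is.na(reports)]
      if (length(informative) == 0) {
        status <- 0
        p <- "zero-filled-absent"
      } else if (any(informative == "yes")) {
        status <- 1
        both_surveyed <- startsWith(node_ids[i], "HP:") &&
          startsWith(node_ids[j], "HP:")
        p <- if (both_surveyed && anyNA(reports)) "substituted"
             else "provider-reported"
      } else {
        status <- 0
        p <- "absent"
      }
      adj[i, j] <- adj[j, i] <- status
      prov[i, j] <- prov[j, i] <- p
    }
  }
  list(adjacency = adj, provenance = prov)
}

node_discipline <- function(ids) {
  vapply(strsplit(ids, ":", fixed = TRUE), function(p) {
    if (p[1] == "HP") p[3] else if (p[1] == "EXT") p[2] else NA_character_
  }, character(1))
}

# Stable node ordering: patient, in-practice professionals in roster order,
# external nodes in fixed discipline order.
order_nodes <- function(patient_node, prof_ids, roster) {
  hp <- intersect(roster$professional_id, prof_ids)
  ext <- intersect(node_id_external(EXTERNAL_DISCIPLINES), prof_ids)
  c(patient_node, hp, ext)
}

#' Assemble one activity-specific ego network
#'
#' Full construction for one (patient, activity): patient ties from the
#' two-source union, practice-roster expansion, cross-activity node union,
#' then provider ties among the included professionals. Returns `NULL` when
#' the patient has no connection for the activity — by default the existence
#' test is applied after merging chart-derived contacts
#' (`existence = "after_merge"`); `"before_merge"` tests the questionnaire
#' alone.
#'
#' @param dataset a validated `study_dataset`.
#' @param patient_id patient identifier.
#' @param activity one of the three activities.
#' @param existence when the at-least-one-connection rule is evaluated.
#' @param use_chart include chart-derived contacts.
#' @return an `ego_network`, or `NULL` if no network exists for the activity.
#' @export
assemble <- function(dataset, patient_id, activity,
                     existence = c("after_merge", "before_merge"),
                     use_chart = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  existence <- match.arg(existence)
  bundle <- patient_bundle(dataset, patient_id)
  if (!bundle$consent) return(NULL)
  roster <- dataset$practices

  named <- lapply(ACTIVITIES, function(a)
    patient_ties(bundle, roster, a, use_chart = use_chart))
  names(named) <- ACTIVITIES
  exists_for <- vapply(ACTIVITIES, function(a) {
    tie_df <- named[[a]]
    if (existence == "before_merge")
      tie_df <- tie_df[tie_df$provenance == "patient-reported", , drop = FALSE]
    nrow(tie_df) > 0
  }, logical(1))
  if (!exists_for[[activity]]) return(NULL)

  node_sets <- lapply(ACTIVITIES[exists_for], function(a)
    expand_practice(named[[a]]$node_id, roster))
  shared <- cross_activity_union(node_sets)[[1]]

  patient_node <- node_id_patient(patient_id)
  ids <- order_nodes(patient_node, shared, roster)
  disc <- node_discipline(ids)
  resp_map <- provider_responded(dataset$providers)
  nodes <- data.frame(
    id = ids,
    role = c("patient", rep("professional", length(ids) - 1)),
    discipline = disc,
    practice_id = ifelse(startsWith(ids, "HP:"),
                         vapply(strsplit(ids, ":", fixed = TRUE), `[[`, "", 2),
                         NA_character_),
    responded = unname(resp_map[ids]),
    stringsAsFactors = FALSE)
  nodes$responded[1] <- bundle$responded

  pt <- provider_ties(setdiff(ids, patient_node), dataset$providers, activity)
  n <- length(ids)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  prov <- matrix(NA_character_, n, n, dimnames = list(ids, ids))
  adj[-1, -1] <- pt$adjacency[ids[-1], ids[-1]]
  prov[-1, -1] <- pt$provenance[ids[-1], ids[-1]]
  tie_df <- named[[activity]]
  adj[1, tie_df$node_id] <- adj[tie_df$node_id, 1] <- 1
  prov[1, tie_df$node_id] <- prov[tie_df$node_id, 1] <- tie_df$provenance
  absent_p <- ids[-1][adj[1, -1] == 0]
  prov[1, absent_p] <- prov[absent_p, 1] <- "absent"

  new_ego_network(patient_id, activity, nodes, adj, prov)
}

provider_responded <- function(providers) {
  u <- unique(providers[, c("professional_id", "responded")])
  stats::setNames(u$responded, u$professional_id)
}

#' Apply the study's patient exclusion rules
#'
#' In order: patients without questionnaire response/consent, patients for
#' whom no connection with any health professional can be deduced from
#' questionnaire or medical record, and (hospital-only) patients who received
#' all treatment in hospital rather than primary care. A log records one
#' reason per excluded patient.
#'
#' @param dataset a `study_dataset`.
#' @param existence,use_chart passed to the connection test (see
#'   [assemble()]).
#' @return list: `analyzable` (patient ids), `exclusions` (data frame
#'   `patient_id`, `reason`).
#' @export
apply_exclusions <- function(dataset, existence = "after_merge",
                             use_chart = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  pa <- dataset$patients
  excl <- list()
  remaining <- pa$patient_id

  no_consent <- pa$patient_id[!pa$responded | !pa$consent]
  excl$consent <- data.frame(patient_id = no_consent,
                             reason = rep("no_response_or_consent",
                                          length(no_consent)),
                             stringsAsFactors = FALSE)
  remaining <- setdiff(remaining, no_consent)

  has_any <- vapply(remaining, function(pid) {
    b <- patient_bundle(dataset, pid)
    any(vapply(ACTIVITIES, function(a) {
      tie_df <- patient_ties(b, dataset$practices, a, use_chart = use_chart)
      if (existence == "before_merge")
        tie_df <- tie_df[tie_df$provenance == "patient-reported", ,
                         drop = FALSE]
      nrow(tie_df) > 0
    }, logical(1)))
  }, logical(1))
  zero_conn <- remaining[!has_any]
  excl$zero <- data.frame(patient_id = zero_conn,
                          reason = rep("no_connections", length(zero_conn)),
                          stringsAsFactors = FALSE)
  remaining <- setdiff(remaining, zero_conn)

  ho <- pa$patient_id[pa$patient_id %in% remaining &
                        !is.na(pa$hospital_only) & pa$hospital_only]
  excl$hosp <- data.frame(patient_id = ho,
                          reason = rep("hospital_only", length(ho)),
                          stringsAsFactors = FALSE)
  remaining <- setdiff(remaining, ho)

  list(analyzable = remaining,
       exclusions = do.call(rbind, c(excl, list(make.row.names = FALSE))))
}

#' Build all ego networks for the analyzable patients
#'
#' Runs [apply_exclusions()] and then [assemble()] for every analyzable
#' patient and activity.
#'
#' The existence table covers every connected patient — including
#' hospital-only patients later excluded — so that identified-versus-retained
#' network accounting is possible; networks themselves are assembled for the
#' analyzable patients only.
#'
#' @inheritParams apply_exclusions
#' @return list: `networks` (named list `patient.activity` of
#'   `ego_network`s), `existence` (data frame `patient_id`, `activity`,
#'   `exists`, over connected patients), `exclusions`, `analyzable`,
#'   `hospital_only` (excluded patient ids).
#' @export
build_networks <- function(dataset, existence = "after_merge",
                           use_chart = TRUE) {
  ex <- apply_exclusions(dataset, existence = existence,
                         use_chart = use_chart)
  ho <- ex$exclusions$patient_id[ex$exclusions$reason == "hospital_only"]
  connected <- c(ex$analyzable, ho)
  connected <- dataset$patients$patient_id[dataset$patients$patient_id %in%
                                             connected]
  nets <- list()
  rows <- list()
  for (pid in connected) {
    for (a in ACTIVITIES) {
      net <- assemble(dataset, pid, a, existence = existence,
                      use_chart = use_chart)
      rows[[paste(pid, a)]] <- data.frame(patient_id = pid, activity = a,
                                          exists = !is.null(net),
                                          stringsAsFactors = FALSE)
      if (!is.null(net) && pid %in% ex$analyzable)
        nets[[paste(pid, a, sep = ".")]] <- net
    }
  }
  list(networks = nets,
       existence = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       exclusions = ex$exclusions,
       analyzable = ex$analyzable,
       hospital_only = ho)
}
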