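#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact enumeration when
#' the combined sample size is at most 12 and there are no ties, otherwise
#' the normal approximation with tie and continuity correction. `U` is the
#' number of (a, b) pairs won by `group_a`.
#'
#' @param group_a,group_b numeric vectors, each nonempty.
#' @param exact override the automatic exact/asymptotic choice.
#' @return list `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(group_a, group_b, exact = NULL) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- exact %||% (length(group_a) + length(group_b) <= 12 && !ties)
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic),
       p_value = wt$p.value,
       method = if (use_exact && !ties) "exact" else "normal-approximation")
}

#' Group comparison of network parameters
#'
#' Mirrors the study's comparison tables: for each parameter and activity,
#' group means and SDs, the modal discipline of the most central
#' professional, and the two-sided Mann-Whitney p value. Overlap rows are
#' reported per activity pair. Rows where a group has no networks for an
#' activity are flagged not estimable.
#'
#' @param params parameter table ([parameter_table()]).
#' @param overlaps overlap table ([overlap_table()]), or `NULL`.
#' @param groups data frame `patient_id`, `group` (two levels).
#' @return data frame of class `comparison_report`.
#' @export
summarize_parameters <- function(params, overlaps = NULL, groups) {
  lv <- sort(unique(groups$group))
  if (length(lv) != 2)
    stop("grouping must have exactly two levels", call. = FALSE)
  numeric_params <- c("size", "diversity", "density", "n_connections",
                      "centralization", "central_prof_degree",
                      "patient_degree")
  params <- merge(params, groups, by = "patient_id")
  rows <- list()
  for (a in intersect(ACTIVITIES, unique(params$activity))) {
    pa <- params[params$activity == a, ]
    for (pm in numeric_params) {
      va <- pa[[pm]][pa$group == lv[1]]
      vb <- pa[[pm]][pa$group == lv[2]]
      est <- length(va) > 0 && length(vb) > 0
      mw <- if (est && sum(!is.na(va)) > 0 && sum(!is.na(vb)) > 0)
        mann_whitney(va, vb) else list(U = NA_real_, p_value = NA_real_)
      modal <- function(v) {
        if (!length(v)) return(NA_character_)
        names(sort(table(v), decreasing = TRUE))[1]
      }
      rows[[paste(a, pm)]] <- data.frame(
        activity = a, parameter = pm,
        group_1 = lv[1], group_2 = lv[2],
        n_1 = length(va), n_2 = length(vb),
        mean_1 = mean(va, na.rm = TRUE), sd_1 = stats::sd(va),
        mean_2 = mean(vb, na.rm = TRUE), sd_2 = stats::sd(vb),
        modal_central_1 = modal(pa$central_prof_discipline[pa$group == lv[1]]),
        modal_central_2 = modal(pa$central_prof_discipline[pa$group == lv[2]]),
        U = mw$U, p_value = mw$p_value, estimable = est,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(overlaps) && nrow(overlaps)) {
    ov <- merge(overlaps, groups, by = "patient_id")
    for (pr in unique(ov$pair)) {
      va <- ov$coefficient[ov$pair == pr & ov$group == lv[1]]
      vb <- ov$coefficient[ov$pair == pr & ov$group == lv[2]]
      est <- length(va) > 0 && length(vb) > 0
      mw <- if (est) mann_whitney(va, vb)
            else list(U = NA_real_, p_value = NA_real_)
      rows[[paste("overlap", pr)]] <- data.frame(
        activity = pr, parameter = "overlap",
        group_1 = lv[1], group_2 = lv[2],
        n_1 = length(va), n_2 = length(vb),
        mean_1 = mean(va), sd_1 = stats::sd(va),
        mean_2 = mean(vb), sd_2 = stats::sd(vb),
        modal_central_1 = NA_character_, modal_central_2 = NA_character_,
        U = mw$U, p_value = mw$p_value, estimable = est,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("comparison_report", class(out))
  out
}

#' Response rate as a percentage
#'
#' @param responders,invited counts.
#' @param digits rounding for the percentage.
#' @return `100 * responders / invited`, rounded.
#' @export
response_rate <- function(responders, invited, digits = 1) {
  stopifnot(all(invited > 0), all(responders >= 0), all(responders <= invited))
  round(100 * responders / invited, digits)
}

#' Network and exclusion accounting
#'
#' From a per-patient table of activity-network existence and
#' hospital-only flags: the theoretical maximum number of activity-specific
#' networks (3 per connected patient), the number identified per activity,
#' and the number retained per activity after excluding hospital-only
#' patients.
#'
#' @param existence data frame `patient_id`, `activity`, `exists`, plus a
#'   per-patient logical `hospital_only` column (or a separate
#'   `hospital_only` vector of patient ids).
#' @param hospital_only_ids patient ids excluded as hospital-only.
#' @return list `max_networks`, `identified` (per activity + total),
#'   `retained` (per activity + total), `n_patients`, `n_retained_patients`.
#' @export
network_counts <- function(existence, hospital_only_ids = character(0)) {
  pats <- unique(existence$patient_id)
  per_act <- function(rows) {
    v <- vapply(ACTIVITIES, function(a)
      sum(rows$exists[rows$activity == a]), numeric(1))
    c(v, total = sum(v))
  }
  kept <- existence[!existence$patient_id %in% hospital_only_ids, ]
  list(max_networks = 3L * length(pats),
       identified = per_act(existence),
       retained = per_act(kept),
       n_patients = length(pats),
       n_retained_patients = length(unique(kept$patient_id)))
}

#' Feasibility report
#'
#' Response-rate and reliability accounting in the layout of the study's
#' feasibility table: patient response per practice and condition, provider
#' response per practice and overall, dyadic reciprocity per practice, and
#' the network/exclusion counts. Percentages are rounded to one decimal,
#' reciprocity to three.
#'
#' @param dataset a `study_dataset`.
#' @param built output of [build_networks()] (or `NULL` to skip network
#'   accounting).
#' @return list of class `feasibility_report`.
#' @export
feasibility <- function(dataset, built = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  pa <- dataset$patients
  cell <- function(rows) {
    data.frame(responded = sum(rows$responded), invited = nrow(rows),
               pct = response_rate(sum(rows$responded), nrow(rows)))
  }
  prs <- sort(unique(pa$practice_id))
  patient_rates <- do.call(rbind, lapply(c(prs, "total"), function(pid) {
    rows <- if (pid == "total") pa else pa[pa$practice_id == pid, ]
    do.call(rbind, lapply(c("all", CONDITIONS), function(cd) {
      sub <- if (cd == "all") rows else rows[rows$condition == cd, ]
      cbind(practice = pid, condition = cd, cell(sub))
    }))
  }))

  pv <- unique(dataset$providers[, c("professional_id", "practice_id",
                                     "responded")])
  provider_rates <- do.call(rbind, lapply(c(prs, "total"), function(pid) {
    rows <- if (pid == "total") pv else pv[pv$practice_id == pid, ]
    cbind(practice = pid, cell(rows))
  }))

  recip <- vapply(prs, function(pid) {
    r <- tryCatch(reciprocity(dataset$providers, pid),
                  error = function(e) NA_real_)
    round(r, 3)
  }, numeric(1))

  out <- list(patient_rates = patient_rates,
              provider_rates = provider_rates,
              reciprocity = data.frame(practice = prs, reciprocity = recip))
  if (!is.null(built)) {
    out$network_counts <- network_counts(built$existence,
                                         hospital_only_ids =
                                           built$hospital_only)
    out$exclusion_tally <- table(built$exclusions$reason)
  }
  structure(out, class = "feasibility_report")
}
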