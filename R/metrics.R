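#' Normalized degree centrality of one node
#'
#' The proportion of all possible connections that are actually present for
#' an individual, on a 0--100 scale: `100 * degree / (n - 1)` with the
#' patient counted in `n`.
#'
#' @param net an `ego_network`.
#' @param node node id (defaults to the patient).
#' @return percentage in \[0, 100\].
#' @export
degree_centrality <- function(net, node = ego_id(net)) {
  stopifnot(inherits(net, "ego_network"))
  n <- nrow(net$adjacency)
  if (n < 2)
    stop("degree centrality is undefined on a singleton network",
         call. = FALSE)
  if (!node %in% rownames(net$adjacency))
    stop(sprintf("node '%s' not in network", node), call. = FALSE)
  100 * sum(net$adjacency[node, ]) / (n - 1)
}

#' Most central health professional
#'
#' The professional (patient ineligible) with maximal degree. Ties are broken
#' deterministically: higher degree, then in-practice before external, then
#' discipline priority (GP first), then lexical node id.
#'
#' @param net an `ego_network` with at least one professional node.
#' @return list `id`, `discipline`, `degree` (percentage).
#' @export
most_central_professional <- function(net) {
  stopifnot(inherits(net, "ego_network"))
  prof <- professional_ids(net)
  if (!length(prof))
    stop("network has no professional nodes", call. = FALSE)
  deg <- rowSums(net$adjacency)[prof]
  disc <- net$nodes$discipline[match(prof, net$nodes$id)]
  in_practice <- startsWith(prof, "HP:")
  ord <- order(-deg, !in_practice, match(disc, DISCIPLINES), prof)
  best <- prof[ord[1]]
  list(id = best,
       discipline = disc[ord[1]],
       degree = degree_centrality(net, best))
}

#' Freeman degree centralization
#'
#' Whole-network index of how far degree is concentrated on a single person:
#' `100 * sum(d_max - d_i) / ((n - 1) * (n - 2))` over all nodes including
#' the patient. 100 for a star, 0 for any regular network.
#'
#' @param net an `ego_network` with at least 3 nodes.
#' @return percentage in \[0, 100\].
#' @export
network_centralization <- function(net) {
  stopifnot(inherits(net, "ego_network"))
  n <- nrow(net$adjacency)
  if (n < 3)
    stop("centralization is undefined for networks with fewer than 3 nodes",
         call. = FALSE)
  d <- rowSums(net$adjacency)
  100 * sum(max(d) - d) / ((n - 1) * (n - 2))
}

#' Network density
#'
#' The proportion of all possible connections in the network that are
#' actually present: `ties / (n * (n - 1) / 2)`, the patient node included
#' in `n`.
#'
#' @param net an `ego_network` with at least 2 nodes.
#' @return fraction in \[0, 1\].
#' @export
net_density <- function(net) {
  stopifnot(inherits(net, "ego_network"))
  n <- nrow(net$adjacency)
  if (n < 2)
    stop("density is undefined on a singleton network", call. = FALSE)
  sum(net$adjacency) / 2 / (n * (n - 1) / 2)
}

#' Overlap between two activity-specific networks of one patient
#'
#' Simple matching coefficient over dyads: the proportion of present and
#' absent ties in one network that have the same status in the other. The
#' default dyad universe is the union of the two node sets, a node absent
#' from one network contributing absent ties there; this makes the
#' coefficient symmetric. `universe = "index"` restricts dyads to the first
#' (index) network's nodes.
#'
#' @param net_a,net_b `ego_network`s of the same patient.
#' @param universe `"union"` (default, symmetric) or `"index"`.
#' @return list `activity_pair`, `coefficient` (fraction in \[0, 1\]).
#' @export
overlap <- function(net_a, net_b, universe = c("union", "index")) {
  stopifnot(inherits(net_a, "ego_network"), inherits(net_b, "ego_network"))
  universe <- match.arg(universe)
  if (!identical(net_a$patient_id, net_b$patient_id))
    stop("overlap is defined between networks of the same patient",
         call. = FALSE)
  ids <- if (universe == "union") {
    union(rownames(net_a$adjacency), rownames(net_b$adjacency))
  } else {
    rownames(net_a$adjacency)
  }
  expand <- function(net) {
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    have <- intersect(ids, rownames(net$adjacency))
    m[have, have] <- net$adjacency[have, have]
    m
  }
  a <- expand(net_a)
  b <- expand(net_b)
  ut <- upper.tri(a)
  list(activity_pair = c(net_a$activity, net_b$activity),
       coefficient = mean(a[ut] == b[ut]))
}

#' Dyadic reciprocity of provider reports within a practice
#'
#' Reliability of reported connections: the proportion of all possible
#' professional dyads whose two members mutually report the contact as
#' present or as absent. Only dyads where both surveys were returned enter
#' the denominator; dyads are pooled over the three activities. (In a
#' non-directed network this agreement proportion is the reciprocity
#' coefficient.)
#'
#' @param providers provider survey table (rows of one practice, or pass
#'   `practice_id`).
#' @param practice_id optional practice filter.
#' @return fraction in \[0, 1\].
#' @export
reciprocity <- function(providers, practice_id = NULL) {
  pv <- providers
  if (!is.null(practice_id)) pv <- pv[pv$practice_id == practice_id, ]
  ids <- unique(pv$professional_id[pv$responded])
  if (length(ids) < 2)
    stop("reciprocity requires at least 2 responding professionals",
         call. = FALSE)
  disc_map <- node_discipline(ids)
  flag <- stats::setNames(pv$contact,
                          paste(pv$professional_id, pv$activity,
                                pv$discipline))
  agree <- total <- 0L
  pairs <- utils::combn(length(ids), 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    for (a in ACTIVITIES) {
      ri <- flag[paste(ids[i], a, disc_map[j])]
      rj <- flag[paste(ids[j], a, disc_map[i])]
      if (is.na(ri) || is.na(rj)) next
      total <- total + 1L
      if (ri == rj) agree <- agree + 1L
    }
  }
  if (total == 0)
    stop("no mutually reported dyads available", call. = FALSE)
  agree / total
}

#' All network parameters of one ego network
#'
#' One row with the parameter families reported per network: size (number of
#' professionals), diversity (distinct disciplines), density and number of
#' connections (patient node included in the denominator), Freeman
#' centralization, the most central professional (id, discipline, degree)
#' and the patient's degree centrality.
#'
#' @param net an `ego_network`.
#' @return one-row data frame.
#' @export
parameter_set <- function(net) {
  stopifnot(inherits(net, "ego_network"))
  prof <- professional_ids(net)
  n <- nrow(net$adjacency)
  mc <- most_central_professional(net)
  data.frame(
    patient_id = net$patient_id,
    activity = net$activity,
    size = length(prof),
    diversity = length(unique(net$nodes$discipline[net$nodes$role ==
                                                     "professional"])),
    density = net_density(net),
    n_connections = sum(net$adjacency) / 2,
    centralization = if (n >= 3) network_centralization(net) else NA_real_,
    central_prof_id = mc$id,
    central_prof_discipline = mc$discipline,
    central_prof_degree = mc$degree,
    patient_degree = degree_centrality(net),
    stringsAsFactors = FALSE)
}

#' Parameter table for a set of networks
#'
#' @param networks list of `ego_network`s (e.g. from [build_networks()]).
#' @return data frame, one row per network (see [parameter_set()]).
#' @export
parameter_table <- function(networks) {
  do.call(rbind, c(lapply(networks, parameter_set),
                   list(make.row.names = FALSE)))
}

#' Overlap table for a set of networks
#'
#' Overlap coefficients for every activity pair of every patient with both
#' networks present.
#'
#' @param networks named list of `ego_network`s.
#' @param universe dyad universe rule, see [overlap()].
#' @return data frame `patient_id`, `pair`, `coefficient`.
#' @export
overlap_table <- function(networks, universe = "union") {
  pats <- unique(vapply(networks, function(n) n$patient_id, character(1)))
  pairs <- utils::combn(ACTIVITIES, 2)
  rows <- list()
  for (pid in pats) {
    mine <- Filter(function(n) n$patient_id == pid, networks)
    acts <- vapply(mine, function(n) n$activity, character(1))
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      if (!(a %in% acts) || !(b %in% acts)) next
      ov <- overlap(mine[[which(acts == a)]], mine[[which(acts == b)]],
                    universe = universe)
      rows[[paste(pid, a, b)]] <- data.frame(
        patient_id = pid, pair = paste(a, b, sep = "-"),
        coefficient = ov$coefficient, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
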