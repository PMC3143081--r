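#' Ego-centered care-team network
#'
#' An undirected, unweighted network for one (patient, activity) pair: the
#' patient (ego) plus the included care professionals, a symmetric binary
#' adjacency matrix with zero diagonal, and per-dyad provenance recording how
#' each tie status was established.
#'
#' Provenance tokens: `patient-reported`, `chart-derived`,
#' `provider-reported`, `substituted` for present ties; `absent` (at least
#' one informative "no") and `zero-filled-absent` (no information on either
#' side) for absent dyads. Patient--patient entries are empty by construction.
#'
#' @param patient_id ego patient id.
#' @param activity one of `treatment`, `advice`, `monitoring`.
#' @param nodes data frame: `id`, `role` (`patient`/`professional`),
#'   `discipline` (`NA` for the patient), `practice_id` (`NA` for external
#'   nodes), `responded`.
#' @param adjacency symmetric binary matrix with dimnames = node ids.
#' @param provenance character matrix, same shape, provenance per dyad.
#' @return object of class `ego_network`.
#' @export
new_ego_network <- function(patient_id, activity, nodes, adjacency,
                            provenance = NULL) {
  net <- structure(
    list(patient_id = patient_id, activity = activity, nodes = nodes,
         adjacency = adjacency, provenance = provenance),
    class = "ego_network")
  validate_ego_network(net)
}

#' Validate an ego network
#'
#' Enforces the structural invariants: symmetric 0/1 adjacency with zero
#' diagonal, matching node table and dimnames, exactly one patient node, and
#' at least one patient--professional tie (networks are only constructed for
#' activities where the patient reported a connection).
#'
#' @param net an `ego_network`.
#' @return the network, invisibly usable in a pipeline.
#' @export
validate_ego_network <- function(net) {
  stopifnot(inherits(net, "ego_network"))
  nodes <- net$nodes
  adj <- net$adjacency
  if (!net$activity %in% ACTIVITIES)
    stop(sprintf("unknown activity '%s'", net$activity), call. = FALSE)
  if (!identical(rownames(adj), nodes$id) ||
      !identical(colnames(adj), nodes$id))
    stop("adjacency dimnames must equal the node id column", call. = FALSE)
  if (!all(adj %in% c(0, 1)))
    stop("adjacency must be binary", call. = FALSE)
  if (!isTRUE(all.equal(adj, t(adj))))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adj) != 0))
    stop("self-ties are not allowed", call. = FALSE)
  ego <- which(nodes$role == "patient")
  if (length(ego) != 1)
    stop("network must contain exactly one patient node", call. = FALSE)
  if (nrow(nodes) > 1 && sum(adj[ego, ]) < 1)
    stop("network must contain at least one patient-professional tie",
         call. = FALSE)
  if (!is.null(net$provenance)) {
    pv <- net$provenance
    if (!identical(dim(pv), dim(adj)))
      stop("provenance matrix shape must match adjacency", call. = FALSE)
    vals <- pv[adj == 1]
    bad <- vals[!is.na(vals) & !vals %in% PROVENANCE_PRESENT]
    if (length(bad))
      stop(sprintf("present tie with non-present provenance '%s'", bad[1]),
           call. = FALSE)
  }
  net
}

#' @export
print.ego_network <- function(x, ...) {
  n <- nrow(x$nodes)
  cat(sprintf("<ego_network> patient %s, activity %s: %d professionals, %d ties\n",
              x$patient_id, x$activity, n - 1L, sum(x$adjacency) / 2))
  invisible(x)
}

ego_id <- function(net) net$nodes$id[net$nodes$role == "patient"]

professional_ids <- function(net) net$nodes$id[net$nodes$role == "professional"]

#' Convert an ego network to an igraph graph
#'
#' Node attributes (`role`, `discipline`, `practice`, `responded`) and the
#' provenance of present ties are carried over; useful for plotting and
#' GraphML export.
#'
#' @param net an `ego_network`.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ego_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  igraph::V(g)$role <- net$nodes$role
  igraph::V(g)$discipline <- ifelse(is.na(net$nodes$discipline), "",
                                    net$nodes$discipline)
  igraph::V(g)$practice <- ifelse(is.na(net$nodes$practice_id), "",
                                  net$nodes$practice_id)
  igraph::V(g)$responded <- ifelse(is.na(net$nodes$responded), "",
                                   as.character(net$nodes$responded))
  if (!is.null(net$provenance) && igraph::ecount(g) > 0) {
    ends <- igraph::as_edgelist(g)
    igraph::E(g)$provenance <- net$provenance[ends]
  }
  g$patient_id <- net$patient_id
  g$activity <- net$activity
  g
}
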