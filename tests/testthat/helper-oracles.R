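# Independent brute-force oracles, written directly from the definitions and
# kept free of the package's metric/construction code paths.

# Build a bare network object around an adjacency matrix; node 1 is the
# patient. Bypasses the constructed-network invariants on purpose so that
# arbitrary graphs (edgeless, isolated ego, ...) can be fed to the metrics.
graph_net <- function(adj, disciplines = NULL, activity = "treatment",
                      patient_id = "px") {
  n <- nrow(adj)
  if (is.null(disciplines))
    disciplines <- rep_len(c("gp", "practice_nurse", "practice_assistant"),
                           n - 1)
  ids <- c(node_id_patient(patient_id),
           mapply(function(d, i) {
             if (d %in% EXTERNAL_DISCIPLINES) node_id_external(d)
             else node_id_professional("pr1", d, i)
           }, disciplines, seq_len(n - 1)))
  ids <- unname(ids)
  dimnames(adj) <- list(ids, ids)
  nodes <- data.frame(
    id = ids, role = c("patient", rep("professional", n - 1)),
    discipline = c(NA, disciplines),
    practice_id = c(NA, ifelse(disciplines %in% EXTERNAL_DISCIPLINES,
                               NA, "pr1")),
    responded = NA, stringsAsFactors = FALSE)
  structure(list(patient_id = patient_id, activity = activity, nodes = nodes,
                 adjacency = adj, provenance = NULL),
            class = "ego_network")
}

# Adjacency matrix of the k-th graph (edge subset) on n labelled nodes.
# Only valid for n <= 6 (the edge count must fit in 32 bits).
graph_from_index <- function(n, k) {
  m <- n * (n - 1) / 2
  stopifnot(m <= 31)
  bits <- as.integer(intToBits(k))[seq_len(m)]
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- bits
  adj + t(adj)
}

# Uniform random simple graph on n nodes (edge probability p).
rand_adj <- function(n, p = 0.5) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

# Degree of node i by explicit dyad enumeration.
bf_degree <- function(adj, i) {
  d <- 0
  for (j in seq_len(nrow(adj))) if (j != i && adj[i, j] == 1) d <- d + 1
  d
}

bf_density <- function(adj) {
  n <- nrow(adj)
  ties <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ties <- ties + adj[i, j]
  ties / (n * (n - 1) / 2)
}

bf_centralization <- function(adj) {
  n <- nrow(adj)
  d <- vapply(seq_len(n), function(i) bf_degree(adj, i), numeric(1))
  100 * sum(max(d) - d) / ((n - 1) * (n - 2))
}

bf_degree_pct <- function(adj, i) 100 * bf_degree(adj, i) / (nrow(adj) - 1)

# Simple matching coefficient over shared dyad universe.
bf_overlap <- function(adj_a, adj_b) {
  ids <- union(rownames(adj_a), rownames(adj_b))
  status <- function(adj, i, j) {
    if (i %in% rownames(adj) && j %in% rownames(adj)) adj[i, j] else 0
  }
  match_n <- tot <- 0
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      tot <- tot + 1
      if (status(adj_a, ids[i], ids[j]) == status(adj_b, ids[i], ids[j]))
        match_n <- match_n + 1
    }
  }
  match_n / tot
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
enum_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  mu <- na * length(b) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p_value = p)
}

# Independent ego-network constructor: a single pass over the raw tables,
# resolving every dyad by direct lookup. Returns NULL when no network exists.
bf_assemble <- function(dataset, patient_id, activity) {
  pa <- dataset$patients[dataset$patients$patient_id == patient_id, ]
  if (!isTRUE(pa$consent)) return(NULL)
  roster <- dataset$practices[dataset$practices$practice_id ==
                                pa$practice_id, ]
  direct_disc <- function(a) {
    ct <- dataset$contacts
    q <- unique(ct$discipline[ct$patient_id == patient_id &
                                ct$activity == a & !is.na(ct$contact) &
                                ct$contact == "yes"])
    if (a == "monitoring") {
      rc <- dataset$records[dataset$records$patient_id == patient_id, ]
      inw <- rc$date > dataset$extraction_date - dataset$window_days &
        rc$date <= dataset$extraction_date
      q2 <- unique(c(q, rc$discipline[inw]))
    } else q2 <- q
    list(all = q2, questionnaire = q)
  }
  to_nodes <- function(disc) {
    unlist(lapply(disc, function(d)
      if (d %in% EXTERNAL_DISCIPLINES) node_id_external(d)
      else roster$professional_id[roster$discipline == d]))
  }
  per_act <- lapply(ACTIVITIES, direct_disc)
  names(per_act) <- ACTIVITIES
  exists_for <- vapply(per_act, function(x) length(to_nodes(x$all)) > 0,
                       logical(1))
  if (!exists_for[[activity]]) return(NULL)
  node_set <- character(0)
  for (a in ACTIVITIES[exists_for]) {
    direct <- to_nodes(per_act[[a]]$all)
    node_set <- union(node_set, direct)
    if (any(grepl("^HP:", direct)))
      node_set <- union(node_set, roster$professional_id)
  }
  hp <- intersect(roster$professional_id, node_set)
  ext <- intersect(node_id_external(EXTERNAL_DISCIPLINES), node_set)
  ids <- c(node_id_patient(patient_id), hp, ext)
  n <- length(ids)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  prov <- matrix(NA_character_, n, n, dimnames = list(ids, ids))
  disc_of <- function(id) {
    p <- strsplit(id, ":", fixed = TRUE)[[1]]
    if (p[1] == "HP") p[3] else p[2]
  }
  lookup <- function(id, d) {
    pv <- dataset$providers
    hit <- pv$professional_id == id & pv$activity == activity &
      pv$discipline == d
    if (!any(hit)) NA_character_ else pv$contact[hit][1]
  }
  direct_here <- to_nodes(per_act[[activity]]$all)
  q_nodes <- to_nodes(per_act[[activity]]$questionnaire)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (i == 1) {
        if (ids[j] %in% direct_here) {
          adj[1, j] <- adj[j, 1] <- 1
          prov[1, j] <- prov[j, 1] <-
            if (ids[j] %in% q_nodes) "patient-reported" else "chart-derived"
        } else prov[1, j] <- prov[j, 1] <- "absent"
        next
      }
      ri <- if (grepl("^HP:", ids[i])) lookup(ids[i], disc_of(ids[j]))
            else NA_character_
      rj <- if (grepl("^HP:", ids[j])) lookup(ids[j], disc_of(ids[i]))
            else NA_character_
      if (identical(ri, "yes") || identical(rj, "yes")) {
        adj[i, j] <- adj[j, i] <- 1
        one_missing <- is.na(ri) || is.na(rj)
        both_hp <- grepl("^HP:", ids[i]) && grepl("^HP:", ids[j])
        prov[i, j] <- prov[j, i] <-
          if (both_hp && one_missing) "substituted" else "provider-reported"
      } else if (is.na(ri) && is.na(rj)) {
        prov[i, j] <- prov[j, i] <- "zero-filled-absent"
      } else {
        prov[i, j] <- prov[j, i] <- "absent"
      }
    }
  }
  list(ids = ids, adjacency = adj, provenance = prov)
}
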