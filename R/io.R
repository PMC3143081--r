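#' Write a study dataset to a directory of CSV files
#'
#' Emits the instrument tables as five UTF-8 comma-separated files with
#' mandatory header rows (`practices.csv`, `patients.csv`,
#' `patient_contacts.csv`, `providers.csv`, `records.csv`) plus `meta.json`
#' holding the extraction date and monitoring window. Tri-state flags are
#' encoded `yes`/`no`/empty.
#'
#' @param dataset a `study_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, na = "")
  wr(dataset$practices, "practices.csv")
  wr(dataset$patients, "patients.csv")
  wr(dataset$contacts, "patient_contacts.csv")
  wr(dataset$providers, "providers.csv")
  rc <- dataset$records
  rc$date <- format(rc$date, "%Y-%m-%d")
  wr(rc, "records.csv")
  jsonlite::write_json(
    list(extraction_date = format(dataset$extraction_date, "%Y-%m-%d"),
         window_days = dataset$window_days),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study dataset from a directory of CSV files
#'
#' Inverse of [write_dataset()]. All tables are validated against the closed
#' vocabularies and referential-integrity rules; schema violations raise an
#' error naming the offending table and row. Row counts are reported via
#' `message()`.
#'
#' @param dir directory containing the instrument CSVs.
#' @param quiet suppress the row-count log.
#' @return a validated `study_dataset`.
#' @export
read_dataset <- function(dir, quiet = FALSE) {
  need <- c("practices.csv", "patients.csv", "patient_contacts.csv",
            "providers.csv", "records.csv", "meta.json")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop(sprintf("missing dataset file(s) in '%s': %s", dir,
                 paste(miss, collapse = ", ")), call. = FALSE)
  rd <- function(file, ...)
    utils::read.csv(file.path(dir, file), na.strings = "",
                    stringsAsFactors = FALSE, ...)
  practices <- rd("practices.csv")
  patients <- rd("patients.csv")
  for (col in intersect(c("responded", "consent", "hospital_only",
                          TREATMENT_FLAGS), names(patients)))
    patients[[col]] <- as.logical(patients[[col]])
  contacts <- rd("patient_contacts.csv")
  contacts$n_contacts <- as.integer(contacts$n_contacts)
  providers <- rd("providers.csv")
  providers$responded <- as.logical(providers$responded)
  records <- rd("records.csv")
  records$date <- as.Date(as.character(records$date))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  ds <- new_study_dataset(practices, patients, contacts, providers, records,
                          extraction_date = as.Date(meta$extraction_date),
                          window_days = meta$window_days)
  if (!quiet)
    message(sprintf(
      "read dataset from %s: %d roster rows, %d patients, %d contact rows, %d provider rows, %d record rows",
      dir, nrow(practices), nrow(patients), nrow(contacts), nrow(providers),
      nrow(records)))
  ds
}

#' Write / read synthetic ground truth as JSON
#'
#' @param truth a `synthetic_truth` (see [generate_cohort()]).
#' @param path JSON file path.
#' @return `path` invisibly; `read_truth()` returns the `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- lapply(x, as.data.frame)
  structure(x, class = "synthetic_truth")
}

#' Write an ego network to file
#'
#' Supported formats: UCINET `dl` (full-matrix dialect with node labels),
#' `graphml` (node attributes and tie provenance as edge attributes, via
#' igraph), and a plain-text `edgelist` (a node block followed by an edge
#' block, so isolated nodes survive the round trip). Re-reading any format
#' with [read_network()] reproduces the adjacency exactly.
#'
#' @param net an `ego_network`.
#' @param path output file path.
#' @param format one of `"dl"`, `"graphml"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("dl", "graphml", "edgelist")) {
  stopifnot(inherits(net, "ego_network"))
  format <- match.arg(format)
  switch(format,
    dl = write_network_dl(net, path),
    graphml = igraph::write_graph(as_igraph(net), path, format = "graphml"),
    edgelist = write_network_edgelist(net, path))
  invisible(path)
}

write_network_dl <- function(net, path) {
  adj <- net$adjacency
  n <- nrow(adj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("dl n=%d format=fullmatrix diagonal=present", n), con)
  writeLines("labels:", con)
  writeLines(paste(sprintf('"%s"', rownames(adj)), collapse = ","), con)
  writeLines("data:", con)
  writeLines(apply(adj, 1, paste, collapse = " "), con)
}

write_network_edgelist <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("*nodes %d", nrow(net$nodes)), con)
  writeLines(net$nodes$id, con)
  ut <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  writeLines("*edges", con)
  if (nrow(ut))
    writeLines(paste(rownames(net$adjacency)[ut[, 1]],
                     rownames(net$adjacency)[ut[, 2]]), con)
}

#' Read an ego network written by [write_network()]
#'
#' Node roles, disciplines and practice membership are recovered from the
#' structured node ids (`P:`, `HP:practice:discipline:index`,
#' `EXT:discipline`); GraphML additionally restores tie provenance for
#' present ties. Provenance of absent dyads is not serialized and comes back
#' `NA`.
#'
#' @param path file path.
#' @param format one of `"dl"`, `"graphml"`, `"edgelist"`.
#' @param patient_id,activity metadata for formats that do not carry it
#'   (`dl`, `edgelist`); inferred from the node ids / file when `NULL`.
#' @return an `ego_network`.
#' @export
read_network <- function(path, format = c("dl", "graphml", "edgelist"),
                         patient_id = NULL, activity = NULL) {
  format <- match.arg(format)
  switch(format,
    dl = read_network_dl(path, activity),
    graphml = read_network_graphml(path),
    edgelist = read_network_edgelist(path, activity))
}

read_network_dl <- function(path, activity = NULL) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1], regexec("dl n=(\\d+)", lines[1]))[[1]]
  if (length(hdr) != 2)
    stop(sprintf("'%s' is not a dl full-matrix file", path), call. = FALSE)
  n <- as.integer(hdr[2])
  labels <- scan(text = lines[3], what = character(), sep = ",", quiet = TRUE)
  data_at <- which(lines == "data:")
  rows <- lines[(data_at + 1):(data_at + n)]
  adj <- do.call(rbind, lapply(rows, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
  dimnames(adj) <- list(labels, labels)
  network_from_labels(adj, activity)
}

read_network_edgelist <- function(path, activity = NULL) {
  lines <- readLines(path)
  n <- as.integer(sub("\\*nodes ", "", lines[1]))
  ids <- lines[2:(n + 1)]
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  edge_at <- which(lines == "*edges")
  if (edge_at < length(lines)) {
    for (ln in lines[(edge_at + 1):length(lines)]) {
      e <- strsplit(ln, "\\s+")[[1]]
      adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1
    }
  }
  network_from_labels(adj, activity)
}

read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  dimnames(adj) <- list(igraph::V(g)$name, igraph::V(g)$name)
  net <- network_from_labels(adj, g$activity, patient_id = g$patient_id)
  if (igraph::ecount(g) > 0 &&
      "provenance" %in% igraph::edge_attr_names(g)) {
    pv <- net$provenance
    ends <- igraph::as_edgelist(g)
    pv[ends] <- igraph::E(g)$provenance
    pv[ends[, 2:1, drop = FALSE]] <- igraph::E(g)$provenance
    net$provenance <- pv
  }
  net
}

# Rebuild the node table from the structured id scheme.
network_from_labels <- function(adj, activity = NULL, patient_id = NULL) {
  ids <- rownames(adj)
  parts <- strsplit(ids, ":", fixed = TRUE)
  role <- ifelse(startsWith(ids, "P:"), "patient", "professional")
  discipline <- vapply(parts, function(p) {
    if (p[1] == "HP") p[3] else if (p[1] == "EXT") p[2] else NA_character_
  }, character(1))
  practice <- vapply(parts, function(p) {
    if (p[1] == "HP") p[2] else NA_character_
  }, character(1))
  nodes <- data.frame(id = ids, role = role, discipline = discipline,
                      practice_id = practice, responded = NA,
                      stringsAsFactors = FALSE)
  pid <- patient_id %||% sub("^P:", "", ids[role == "patient"][1])
  pv <- matrix(NA_character_, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  new_ego_network(pid, activity %||% "treatment", nodes, adj, pv)
}
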