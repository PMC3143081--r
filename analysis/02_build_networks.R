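#!/usr/bin/env Rscript
# Step 2 — construct activity-specific ego networks.
#
# Reads the simulated instruments, applies the exclusion cascade
# (no response/consent -> no deducible connections -> hospital-only care),
# constructs one network per remaining (patient, activity) with a reported
# connection, and exports each as UCINET DL and GraphML plus an exclusion log.
#
# Usage: Rscript analysis/02_build_networks.R [--in <dir>] [--out <dir>]

suppressMessages(library(careteamnet))
args <- commandArgs(trailingOnly = TRUE)
arg_of <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
in_dir <- arg_of("--in", "results/data")
out_dir <- arg_of("--out", "results/networks")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ds <- read_dataset(in_dir)
built <- build_networks(ds)

for (name in names(built$networks)) {
  net <- built$networks[[name]]
  stem <- file.path(out_dir, paste0(net$patient_id, "_", net$activity))
  write_network(net, paste0(stem, ".dl"), format = "dl")
  write_network(net, paste0(stem, ".graphml"), format = "graphml")
}
jsonlite::write_json(
  list(exclusions = built$exclusions, existence = built$existence,
       analyzable = built$analyzable),
  file.path(out_dir, "exclusion_log.json"), dataframe = "rows",
  auto_unbox = TRUE)

nc <- network_counts(built$existence, built$hospital_only)
cat(sprintf("connected patients: %d (max %d networks)\n",
            nc$n_patients, nc$max_networks))
cat(sprintf("identified: %s (total %d)\n",
            paste(sprintf("%s %d", ACTIVITIES, nc$identified[ACTIVITIES]),
                  collapse = ", "),
            nc$identified[["total"]]))
cat(sprintf("retained after hospital-only exclusion: %d networks of %d patients\n",
            nc$retained[["total"]], nc$n_retained_patients))
print(table(built$exclusions$reason))
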