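#!/usr/bin/env Rscript
# Step 1 — simulate a multi-source study cohort.
#
# Generates the three instruments (patient questionnaires, provider surveys,
# medical-record extracts) for three GP-led practices under the default study
# conditions, and writes them as CSV together with the latent ground truth.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>] [--out <dir>]

suppressMessages(library(careteamnet))
args <- commandArgs(trailingOnly = TRUE)
arg_of <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(arg_of("--seed", "20260925"))
out <- arg_of("--out", "results/data")

cfg <- cohort_config(rng_seed = seed)
sim <- generate_cohort(cfg)
write_dataset(sim$dataset, out)
write_truth(sim$truth, file.path(out, "truth.json"))

pa <- sim$dataset$patients
cat(sprintf("seed %d | %d patients invited across %d practices\n",
            seed, nrow(pa), length(unique(pa$practice_id))))
cat(sprintf("%d responded (%.1f%%); %d providers, %d responded\n",
            sum(pa$responded), 100 * mean(pa$responded),
            nrow(sim$dataset$practices),
            length(unique(sim$dataset$providers$professional_id[
              sim$dataset$providers$responded]))))
cat(sprintf("instruments written to %s\n", out))
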