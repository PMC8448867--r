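#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: 18 patients, a 40-region toy atlas
# on a 20x20x20 grid, contiguous random-walk lesion blobs confined to half
# the grid (so the encoder prunes the never-lesioned half, as a
# left-hemisphere-only lesion distribution prunes most of a whole-brain
# atlas), therapy hours ~ 73 +/- 25, and responses from a planted negative
# region-weight map plus an hours term plus 10% noise.
#
# Writes the cohort tables under results/cohort/.

suppressPackageStartupMessages(library(anomiaPLS))

master_seed <- 20260928L
outdir <- "results/cohort"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

config <- synthetic_config(seed = master_seed)
sim <- simulate_cohort(config)
print(sim)

cat(sprintf("regions retained after zero-load pruning: %d of %d (%d dropped)\n",
            ncol(sim$loads$values), length(sim$atlas$regions),
            length(sim$loads$dropped_region_ids)))
cat(sprintf("therapy hours: mean %.1f, sd %.1f\n",
            mean(sim$cohort$blocks$hours), sd(sim$cohort$blocks$hours)))
cat(sprintf("treatment response: mean %.1f, sd %.1f (noise sd %.2f)\n",
            mean(sim$cohort$response), sd(sim$cohort$response),
            sim$truth$noise_sd))

write_load_matrix(sim$loads, file.path(outdir, "lesion_loads.csv"))
write_region_manifest(sim$atlas, file.path(outdir, "region_manifest.tsv"))

tab <- data.frame(
  patient_id = sim$cohort$patient_ids,
  sim$cohort$blocks$demographics,
  initial_naming = sim$cohort$blocks$initial_severity[, 1],
  hours = sim$cohort$blocks$hours[, 1],
  response = sim$cohort$response,
  noiseless_response = sim$truth$noiseless)
write.csv(tab, file.path(outdir, "cohort.csv"), row.names = FALSE)

truth <- data.frame(region_id = names(sim$truth$weights),
                    planted_weight = unname(sim$truth$weights))
write.csv(truth, file.path(outdir, "planted_weights.csv"), row.names = FALSE)

cat("written: results/cohort/{cohort.csv, lesion_loads.csv, region_manifest.tsv, planted_weights.csv}\n")
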