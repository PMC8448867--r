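#!/usr/bin/env Rscript

# Stage 2 — lesion encoding round trip through NIfTI.
#
# Demonstrates the imaging path a real cohort would take: the simulated
# masks and atlas regions are written as NIfTI images (to scratch/, they are
# bulky), read back through the standard readers, binarized where
# probabilistic, and re-encoded; the resulting load matrix must equal the
# directly encoded one exactly.

suppressPackageStartupMessages(library(anomiaPLS))

master_seed <- 20260928L
nifti_dir <- "scratch/nifti"
dir.create(file.path(nifti_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(nifti_dir, "atlas"), recursive = TRUE, showWarnings = FALSE)

config <- synthetic_config(seed = master_seed)
sim <- simulate_cohort(config)

mask_paths <- vapply(sim$masks, function(m) {
  p <- file.path(nifti_dir, "masks", paste0(m$patient_id, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(m$voxel_grid + 0), p)
  p
}, "")

man <- region_manifest(sim$atlas)
man$file <- paste0(man$region_id, ".nii.gz")
for (i in seq_len(nrow(man))) {
  img <- array(0, config$grid)
  img[sim$atlas$regions[[i]]$voxels] <- 1
  RNifti::writeNifti(RNifti::asNifti(img),
                     file.path(nifti_dir, "atlas", man$file[i]))
}
write.table(man, file.path(nifti_dir, "atlas", "manifest.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

masks <- read_lesion_masks(mask_paths, patient_ids = sim$cohort$patient_ids,
                           space_tag = sim$atlas$space_tag)
regions <- read_region_set(file.path(nifti_dir, "atlas", "manifest.tsv"),
                           threshold = 0.5,
                           space_tag = sim$atlas$space_tag)
loads <- encode_cohort(masks, regions, drop_zero_variance = TRUE)

stopifnot(identical(loads$values, sim$loads$values),
          identical(loads$dropped_region_ids, sim$loads$dropped_region_ids))
cat(sprintf("NIfTI round trip exact: %d patients x %d regions, %d regions pruned\n",
            nrow(loads$values), ncol(loads$values),
            length(loads$dropped_region_ids)))
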