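#!/usr/bin/env Rscript
# Stage 1 — simulate the paired phantom study and write it to disk in the
# exchange formats the rest of the workflow consumes: one continuous-mode
# imzML per section, a shared ROI label raster + legend, the ground-truth
# table of planted changes, the control m/z list, and a study manifest.
#
# The phantom emulates six age/gender-matched case-control section pairs at
# 100 um raster pitch over m/z 400-2000, with ten planted region-specific
# lipid changes (|percent change| >= 30) among forty species.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(msidiff))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 42L
out_dir <- "results/phantom"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# Demo scale: 32x32 pixels and m/z 500-1000 keep the on-disk study small and
# this stage fast; the full 48x48 / m/z 400-2000 conditions are exercised
# in-memory by analysis/04_differential.R and scripts/acceptance.R.
spec <- phantom_spec(image_shape = c(32, 32), mz_range = c(500, 1000),
                     seed = seed)
study <- simulate_paired_study(spec, n_pairs = 6L, seed = seed)

labels <- study$pairs[[1]]$labels
write_label_raster(labels, file.path(out_dir, "roi_labels.png"),
                   file.path(out_dir, "roi_legend.tsv"))
write_ground_truth(study$ground_truth, file.path(out_dir, "ground_truth.tsv"))

ref <- phantom_reference_list(spec)
write.table(data.frame(mz = ref$mz), file.path(out_dir, "reference_mz.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pairs_manifest <- list()
for (p in study$pairs) {
  ctrl_file <- sprintf("%s_control.imzML", p$pair_id)
  case_file <- sprintf("%s_case.imzML", p$pair_id)
  write_imzml(p$control, file.path(out_dir, ctrl_file))
  write_imzml(p$case, file.path(out_dir, case_file))
  pairs_manifest[[length(pairs_manifest) + 1L]] <- list(
    pair_id = p$pair_id,
    control = list(imzml = ctrl_file, labels = "roi_labels.png",
                   legend = "roi_legend.tsv"),
    case = list(imzml = case_file, labels = "roi_labels.png",
                legend = "roi_legend.tsv"))
  cat(sprintf("wrote %s (control + case)\n", p$pair_id))
}
write_study_manifest(pairs_manifest, file.path(out_dir, "study.yaml"))

cat(sprintf("\nPhantom study: %d pairs, %d species (%d planted changes), seed %d\n",
            length(study$pairs), length(spec$species$mz),
            nrow(study$ground_truth), seed))
cat("Ground truth:\n")
print(study$ground_truth, row.names = FALSE)
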