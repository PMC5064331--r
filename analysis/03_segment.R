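#!/usr/bin/env Rscript
# Stage 3 — spatial segmentation QC: cluster the first control section's
# peak vectors (weakly denoised, k = 3), name the clusters with the
# white-matter marker species, and compare the white/gray split against the
# phantom's known regions. Downstream statistics use the traced ROI labels,
# not these clusters; this stage mirrors how segmentation is used in
# practice — differentiating white from gray matter before ROI tracing.
#
# Usage: Rscript analysis/03_segment.R

suppressPackageStartupMessages(library(msidiff))

in_dir <- "results/phantom"
out_dir <- "results/segmentation"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ref <- read_reference_list(file.path(in_dir, "reference_mz.tsv"))
study <- read_paired_study(file.path(in_dir, "study.yaml"))
d <- study$pairs[[1]]$control
labels <- study$pairs[[1]]$labels

pm <- preprocess_dataset(d, ref)
pm <- denoise_feature_images(pm, "weak")

# white-matter markers: the sulfatide-like species at m/z 906.7 and 918.7
marker_refs <- which(sprintf("%.1f", ref$mz) %in% c("906.7", "918.7"))
seg <- segment_spatial(pm, k = 3, seed = 42)
seg <- map_clusters(seg, marker_refs)
cat("cluster assignment:\n")
print(seg$assignment)

named_map <- matrix("background", nrow(seg$cluster_map), ncol(seg$cluster_map))
on_map <- seg$cluster_map > 0
named_map[on_map] <- seg$assignment[as.character(seg$cluster_map[on_map])]

truth <- labels$legend[as.character(labels$raster)]
truth_wm <- truth == "white_matter"
pred_wm <- named_map == "white_matter"
tissue <- truth != "background"
agreement <- mean((pred_wm == truth_wm)[tissue])
cat(sprintf("white-matter agreement with phantom regions: %.3f\n", agreement))

if (requireNamespace("mclust", quietly = TRUE)) {
  wm_gm_truth <- ifelse(truth_wm, "white_matter", "gray_matter")[tissue]
  wm_gm_pred <- ifelse(pred_wm, "white_matter", "gray_matter")[tissue]
  cat(sprintf("adjusted Rand index (white vs gray): %.3f\n",
              mclust::adjustedRandIndex(wm_gm_pred, wm_gm_truth)))
}

out_labels <- roi_labels(seg$cluster_map,
                         setNames(c("background", seg$assignment),
                                  as.character(0:seg$k)))
write_label_raster(out_labels, file.path(out_dir, "cluster_map.png"),
                   file.path(out_dir, "cluster_legend.tsv"))
cat("cluster map written to", file.path(out_dir, "cluster_map.png"), "\n")
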