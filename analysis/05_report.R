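#!/usr/bin/env Rscript
# Stage 5 — presentation artifacts from the stage-4 results: per-region
# percent-change bar plots and ion distribution images (hotspot-clipped at
# the 99th percentile, weak median denoising, rainbow scale) for the most
# changed species, regenerated from a small phantom section.
#
# Usage: Rscript analysis/05_report.R

suppressPackageStartupMessages({
  library(msidiff)
  library(ggplot2)
})

in_file <- "results/differential/consistent_changes.tsv"
out_dir <- "results/figures"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

changes <- read_results_table(in_file)
cat(sprintf("loaded %d consistent changes\n", nrow(changes)))

for (region in unique(changes$region)) {
  p <- change_barplot(changes, region)
  f <- file.path(out_dir, sprintf("pct_change_%s.png",
                                  gsub("[^A-Za-z0-9]", "_", region)))
  ggsave(f, p, width = 5, height = 4, dpi = 150)
  cat("wrote", f, "\n")
}

# ion images from a fresh demo section (the full-scale spectra are not kept)
spec <- phantom_spec(image_shape = c(48, 48), mz_range = c(500, 1000))
lab <- make_phantom_labels(spec)
d <- simulate_dataset(spec, lab, "case", seed = 42)
pm <- preprocess_dataset(d, phantom_reference_list(spec))
top_mz <- head(changes$mz[order(-abs(changes$mean_percent_change))], 4)
for (mz in unique(top_mz)) {
  j <- which.min(abs(attr(pm, "ref_mz") - mz))
  img <- ion_image(pm, j, clip_quantile = 0.99, denoise = "weak")
  f <- file.path(out_dir, sprintf("ion_mz%.1f.png", mz))
  ggsave(f, plot(img), width = 4, height = 4, dpi = 150)
  cat("wrote", f, "\n")
}
cat("figures under", out_dir, "\n")
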