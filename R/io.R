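#' Reference (control) m/z list
#'
#' Ordered control m/z values the spectra are aligned against, with optional
#' lipid annotations and ionization polarity.
#'
#' @param entries Data frame with numeric column `mz` and optional `label`
#'   and `polarity` columns.
#' @param dedup_tol Entries closer than this (Da) are collapsed to the first
#'   occurrence (default 1e-4).
#' @return Object of class `ref_mz_list`: a data frame sorted by m/z with
#'   columns `mz`, `label`, `polarity`.
#' @export
ref_mz_list <- function(entries, dedup_tol = 1e-4) {
  entries <- as.data.frame(entries)
  if (!"mz" %in% names(entries)) stop("reference list needs an `mz` column")
  if (nrow(entries) == 0L) stop("reference list is empty")
  mz <- as.numeric(entries$mz)
  if (anyNA(mz)) stop("reference list has unparseable m/z values")
  out <- data.frame(
    mz = mz,
    label = if ("label" %in% names(entries)) as.character(entries$label) else NA_character_,
    polarity = if ("polarity" %in% names(entries)) as.character(entries$polarity) else NA_character_)
  out <- out[order(out$mz), , drop = FALSE]
  keep <- c(TRUE, diff(out$mz) > dedup_tol)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ref_mz_list", "data.frame")
  out
}

#' Read a control m/z list from CSV/TSV
#'
#' The file must have a header with at least an `mz` column; `label` and
#' `polarity` columns are carried along. Entries are sorted and deduplicated
#' within 1e-4 Da. An unparseable m/z aborts with the offending line number.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A [ref_mz_list()].
#' @export
read_reference_list <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, colClasses = "character",
                    check.names = FALSE)
  if (nrow(raw) == 0L) stop("reference list is empty: ", path)
  if (!"mz" %in% names(raw)) stop("reference list needs an `mz` column: ", path)
  mz <- suppressWarnings(as.numeric(raw$mz))
  if (anyNA(mz)) {
    bad <- which(is.na(mz))[1]
    stop(sprintf("unparseable m/z at line %d of %s: '%s'",
                 bad + 1L, path, raw$mz[bad]))
  }
  raw$mz <- mz
  ref_mz_list(raw)
}

#' Read an ROI label raster and its legend
#'
#' The raster is an integer-valued grayscale PNG (labels encoded as
#' intensity, 0 = background); the legend is a TSV with columns `label` and
#' `region`. Every label present in the raster must have a legend entry.
#'
#' @param path PNG file of integer labels.
#' @param legend_path TSV legend file.
#' @return An [roi_labels()] map.
#' @export
read_label_raster <- function(path, legend_path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  raster <- round(img * 255)
  storage.mode(raster) <- "integer"
  leg <- read.delim(legend_path, colClasses = "character")
  if (!all(c("label", "region") %in% names(leg)))
    stop("legend needs columns `label` and `region`: ", legend_path)
  legend <- setNames(leg$region, leg$label)
  present <- unique(as.vector(raster))
  missing <- setdiff(as.character(present), names(legend))
  if (length(missing) > 0L)
    stop("raster label(s) without legend entry: ", paste(missing, collapse = ", "))
  roi_labels(raster, legend)
}

#' Write an ROI label raster and legend
#'
#' @param labels An [roi_labels()] map.
#' @param path Output PNG path (labels stored as gray levels).
#' @param legend_path Output TSV legend path.
#' @return Invisibly, `path`.
#' @export
write_label_raster <- function(labels, path, legend_path) {
  if (max(labels$raster) > 255L) stop("more than 255 labels not supported")
  png::writePNG(labels$raster / 255, path)
  leg <- data.frame(label = names(labels$legend),
                    region = unname(labels$legend))
  write.table(leg, legend_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

results_table_columns <- c("mz", "lipid_assignment", "region", "direction",
                           "mean_percent_change", "n_pairs_consistent",
                           "mean_auc")

#' Write the consistent-change results table
#'
#' Fixed-order TSV with columns `mz`, `lipid_assignment`, `region`,
#' `direction`, `mean_percent_change`, `n_pairs_consistent`, `mean_auc`
#' (the schema of the published per-region summary tables). An empty report
#' yields a header-only file.
#'
#' @param report Data frame holding at least the columns above.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(report, path) {
  report <- as.data.frame(report)
  for (cn in results_table_columns)
    if (!cn %in% names(report)) report[[cn]] <- logical(0)
  out <- report[, results_table_columns, drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path TSV path.
#' @return Data frame.
#' @export
read_results_table <- function(path) {
  read.delim(path, check.names = FALSE)
}

#' Write the phantom ground-truth table
#' @param truth Data frame from [phantom_ground_truth()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  write.table(truth[, c("mz", "region", "direction", "fold")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study manifest
#'
#' YAML manifest pairing matched case/control sections, e.g.:
#' ```yaml
#' pairs:
#'   - pair_id: pair01
#'     control: {imzml: n01.imzML, labels: n01.png, legend: n01_legend.tsv}
#'     case:    {imzml: a01.imzML, labels: a01.png, legend: a01_legend.tsv}
#' ```
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest YAML path.
#' @return List of pair descriptors (`pair_id`, `control`, `case` path sets).
#' @export
read_study_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$pairs) || length(man$pairs) == 0L)
    stop("manifest has no pairs: ", path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  lapply(man$pairs, function(p) {
    for (m in c("control", "case"))
      p[[m]] <- lapply(p[[m]], resolve)
    p
  })
}

#' Write a study manifest
#' @param pairs List of pair descriptors as in [read_study_manifest()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_study_manifest <- function(pairs, path) {
  yaml::write_yaml(list(pairs = pairs), path)
  invisible(path)
}

#' Load a paired study from a manifest
#'
#' Reads each pair's control and case imzML datasets and ROI label rasters.
#'
#' @param manifest_path Manifest YAML path.
#' @return A `paired_study` list (without ground truth).
#' @export
read_paired_study <- function(manifest_path) {
  pairs <- read_study_manifest(manifest_path)
  loaded <- lapply(pairs, function(p) {
    list(pair_id = p$pair_id,
         control = read_imzml(p$control$imzml),
         case = read_imzml(p$case$imzml),
         labels = read_label_raster(p$control$labels, p$control$legend))
  })
  structure(list(pairs = loaded, ground_truth = NULL), class = "paired_study")
}
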