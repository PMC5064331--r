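# Statistical core: per-ROI, per-pair ROC analysis of case vs control pixel
# intensities, the all-pairs consistency filter, and percent-change
# quantification. The unit of observation is the pixel; matched pairs are
# the replication unit via the consistency rule, so no pooling across pairs
# and no multiple-testing correction beyond the all-pairs criterion itself.

#' ROC area under the curve by the midrank (Mann-Whitney) formula
#'
#' `AUC = P(case > control) + 0.5 * P(case = control)` over all
#' (case, control) pixel pairs, computed from midranks. Exactly antisymmetric
#' (`roc_auc(a, b) + roc_auc(b, a) == 1`) and invariant to common positive
#' scaling.
#'
#' @param control_values,case_values Non-empty numeric intensity samples.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(control_values, case_values) {
  n0 <- length(control_values); n1 <- length(case_values)
  if (n0 == 0L || n1 == 0L) stop("both samples must be non-empty")
  r <- rank(c(case_values, control_values))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

auc_direction <- function(auc, theta_up = 0.75, theta_down = 0.25) {
  ifelse(auc >= theta_up, "up", ifelse(auc <= theta_down, "down", "none"))
}

default_regions <- function() {
  c("whole_hippocampus", "white_matter", "gray_matter",
    "CA1", "CA2/3", "CA4", "DG")
}

gray_matter_subfields <- c("CA1", "CA2/3", "CA4", "DG")

# pixel selector for a (possibly composite) region
region_pixels <- function(region_names, region) {
  if (region == "whole_hippocampus") return(region_names != "background")
  if (region == "gray_matter")
    return(region_names %in% c("gray_matter", gray_matter_subfields))
  if (region == "white_matter")
    return(region_names == "white_matter")
  region_names == region
}

#' Per-ROI, per-pair ROC analysis
#'
#' For every reference, region and matched pair, compares the case member's
#' pixel intensities against the control member's within that region.
#' `white_matter`/`gray_matter` are unions over their labels and
#' `whole_hippocampus` is all on-tissue pixels. Regions with fewer than
#' `min_pixels` pixels in either member are skipped with a warning.
#'
#' @param study_matrices List of pairs, each
#'   `list(pair_id, control = peak_matrix, case = peak_matrix, labels)` with
#'   a shared [roi_labels()] map (see [study_peak_matrices()]).
#' @param regions Region names to analyze (default: whole hippocampus, white
#'   and gray matter, and the CA1, CA2/3, CA4 and DG subfields).
#' @param theta_up,theta_down AUC thresholds calling a reference increased
#'   (`auc >= theta_up`) or decreased (`auc <= theta_down`) in a pair;
#'   defaults 0.75/0.25, a conventional discriminative-AUC cutoff.
#' @param min_pixels Minimum pixels per region per section (default 20).
#' @return Data frame of ROC records: `ref_index`, `mz`, `region`,
#'   `pair_id`, `auc`, `n_control_pixels`, `n_case_pixels`, `direction`.
#' @export
pairwise_roc <- function(study_matrices, regions = default_regions(),
                         theta_up = 0.75, theta_down = 0.25,
                         min_pixels = 20L) {
  records <- list()
  for (pair in study_matrices) {
    ctrl <- pair$control; case <- pair$case
    ref_mz <- attr(ctrl, "ref_mz")
    reg_ctrl <- pixel_regions(pair$labels, attr(ctrl, "coords"))
    reg_case <- pixel_regions(pair$labels, attr(case, "coords"))
    for (region in regions) {
      i_ctrl <- which(region_pixels(reg_ctrl, region))
      i_case <- which(region_pixels(reg_case, region))
      if (length(i_ctrl) < min_pixels || length(i_case) < min_pixels) {
        warning(sprintf("pair %s: region '%s' below %d pixels, skipped",
                        pair$pair_id, region, min_pixels))
        next
      }
      aucs <- vapply(seq_along(ref_mz), function(j)
        roc_auc(ctrl[i_ctrl, j], case[i_case, j]), numeric(1))
      records[[length(records) + 1L]] <- data.frame(
        ref_index = seq_along(ref_mz), mz = ref_mz, region = region,
        pair_id = pair$pair_id, auc = aucs,
        n_control_pixels = length(i_ctrl), n_case_pixels = length(i_case),
        direction = auc_direction(aucs, theta_up, theta_down))
    }
  }
  if (length(records) == 0L)
    return(data.frame(ref_index = integer(0), mz = numeric(0),
                      region = character(0), pair_id = character(0),
                      auc = numeric(0), n_control_pixels = integer(0),
                      n_case_pixels = integer(0), direction = character(0)))
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Cross-pair consistency filter
#'
#' A (reference, region) combination is retained only when all `n_pairs`
#' records exist and every pair shows the same non-`none` direction — the
#' selection rule "consistently increased or decreased in every matched
#' pair". This is deliberately the only selection step: the all-pairs
#' criterion is the error control.
#'
#' @param records ROC record data frame from [pairwise_roc()].
#' @param n_pairs Number of pairs the study contains.
#' @return Data frame of consistent changes: `ref_index`, `mz`, `region`,
#'   `direction`, `mean_auc`, `min_auc`, `max_auc`, `n_pairs_consistent`.
#' @export
consistency_filter <- function(records, n_pairs) {
  n_pairs <- as.integer(n_pairs)
  if (nrow(records) == 0L)
    return(data.frame(ref_index = integer(0), mz = numeric(0),
                      region = character(0), direction = character(0),
                      mean_auc = numeric(0), min_auc = numeric(0),
                      max_auc = numeric(0), n_pairs_consistent = integer(0)))
  keys <- split(records, list(records$ref_index, records$region), drop = TRUE)
  kept <- lapply(keys, function(g) {
    if (nrow(g) != n_pairs) return(NULL)
    dirs <- unique(g$direction)
    if (length(dirs) != 1L || dirs == "none") return(NULL)
    data.frame(ref_index = g$ref_index[1], mz = g$mz[1], region = g$region[1],
               direction = dirs, mean_auc = mean(g$auc),
               min_auc = min(g$auc), max_auc = max(g$auc),
               n_pairs_consistent = n_pairs)
  })
  kept <- kept[!vapply(kept, is.null, logical(1))]
  if (length(kept) == 0L)
    return(consistency_filter(records[0, , drop = FALSE], n_pairs))
  out <- do.call(rbind, kept)
  out <- out[order(out$mz, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent change of a reference in a region
#'
#' Per pair, `100 * (mean_case - mean_control) / mean_control` over the
#' region's pixels of the same preprocessed peak matrix the ROC analysis
#' uses; the reported value is the mean over pairs. A zero control mean
#' makes the pair's value undefined (`NA`).
#'
#' @param study_matrices As in [pairwise_roc()].
#' @param ref_index Reference column index.
#' @param region Region name.
#' @return List: `mean_percent_change`, `se_percent_change` (standard error
#'   across pairs), `per_pair` (named numeric vector).
#' @export
percent_change <- function(study_matrices, ref_index, region) {
  per_pair <- vapply(study_matrices, function(pair) {
    reg_ctrl <- pixel_regions(pair$labels, attr(pair$control, "coords"))
    reg_case <- pixel_regions(pair$labels, attr(pair$case, "coords"))
    m0 <- mean(pair$control[region_pixels(reg_ctrl, region), ref_index])
    m1 <- mean(pair$case[region_pixels(reg_case, region), ref_index])
    if (!is.finite(m0) || m0 == 0) return(NA_real_)
    100 * (m1 - m0) / m0
  }, numeric(1))
  names(per_pair) <- vapply(study_matrices, `[[`, character(1), "pair_id")
  ok <- !is.na(per_pair)
  list(mean_percent_change = if (any(ok)) mean(per_pair[ok]) else NA_real_,
       se_percent_change = if (sum(ok) > 1L)
         sd(per_pair[ok]) / sqrt(sum(ok)) else NA_real_,
       per_pair = per_pair)
}

#' Build the final change report
#'
#' Joins the consistency-filtered changes with percent-change quantification
#' and optional lipid annotation, in the fixed results-table schema.
#'
#' @param study_matrices As in [pairwise_roc()].
#' @param changes Data frame from [consistency_filter()].
#' @param annotation Optional named character vector mapping
#'   `sprintf("%.4f", mz)` to lipid assignments (see [annotate_mz()]).
#' @return Data frame with columns `mz`, `lipid_assignment`, `region`,
#'   `direction`, `mean_percent_change`, `se_percent_change`,
#'   `n_pairs_consistent`, `mean_auc`, ordered by m/z then region.
#' @export
build_change_report <- function(study_matrices, changes, annotation = NULL) {
  n <- nrow(changes)
  pct <- numeric(n); se <- numeric(n)
  for (i in seq_len(n)) {
    p <- percent_change(study_matrices, changes$ref_index[i], changes$region[i])
    pct[i] <- p$mean_percent_change
    se[i] <- p$se_percent_change
  }
  lipid <- rep("unassigned", n)
  if (!is.null(annotation) && n > 0L) {
    key <- sprintf("%.4f", changes$mz)
    hit <- key %in% names(annotation)
    lipid[hit] <- annotation[key[hit]]
  }
  out <- data.frame(mz = changes$mz, lipid_assignment = lipid,
                    region = changes$region, direction = changes$direction,
                    mean_percent_change = pct, se_percent_change = se,
                    n_pairs_consistent = changes$n_pairs_consistent,
                    mean_auc = changes$mean_auc)
  out <- out[order(out$mz, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
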