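# End-to-end drivers: preprocess a paired study into peak matrices and run
# the full phantom-study pipeline (simulate -> preprocess -> ROC ->
# consistency filter -> percent change) deterministically for a given seed.

#' Preprocess every dataset of a paired study
#'
#' @param study A `paired_study` (from [simulate_paired_study()] or
#'   [read_paired_study()]).
#' @param ref A [ref_mz_list()].
#' @param tolerance Alignment half-window in Da (default 0.25).
#' @param tophat_window Top-hat window in Da (default 1.5).
#' @return `study_matrices`: list of pairs, each
#'   `list(pair_id, control, case, labels)` with `peak_matrix` members.
#' @export
study_peak_matrices <- function(study, ref, tolerance = 0.25,
                                tophat_window = 1.5) {
  lapply(study$pairs, function(pair) {
    list(pair_id = pair$pair_id,
         control = preprocess_dataset(pair$control, ref, tolerance,
                                      tophat_window),
         case = preprocess_dataset(pair$case, ref, tolerance, tophat_window),
         labels = pair$labels)
  })
}

#' Run the full phantom study pipeline
#'
#' Simulates a paired phantom study one pair at a time (raw spectra are
#' discarded once reduced to peak matrices, keeping memory flat), runs the
#' canonical preprocessing chain, the per-ROI per-pair ROC analysis, the
#' all-pairs consistency filter and percent-change quantification. Pair
#' seeds and scale factors are derived exactly as in
#' [simulate_paired_study()], so both routes agree for the same
#' `(spec, n_pairs, seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param n_pairs Number of matched pairs (default 6).
#' @param seed Integer seed (default `spec$seed`).
#' @param tolerance,tophat_window Preprocessing parameters.
#' @param theta_up,theta_down,min_pixels ROC parameters (see
#'   [pairwise_roc()]).
#' @param regions Regions to analyze.
#' @param annotation Optional annotation vector (see [annotate_mz()]).
#' @return List: `ref` (reference list), `records` (all ROC records),
#'   `changes` (consistency-filtered), `report` (final table with percent
#'   changes), `ground_truth`, `matrices` (per-pair peak matrices),
#'   `labels`.
#' @export
run_phantom_study <- function(spec, n_pairs = 6L, seed = spec$seed,
                              tolerance = 0.25, tophat_window = 1.5,
                              theta_up = 0.75, theta_down = 0.25,
                              min_pixels = 20L, regions = default_regions(),
                              annotation = NULL) {
  labels <- make_phantom_labels(spec)
  ref <- phantom_reference_list(spec)
  plan <- study_plan(spec, n_pairs, seed)
  matrices <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    ctrl <- simulate_dataset(spec, labels, "control",
                             seed = plan$seeds[p, 1], scale = plan$scales[p])
    m_ctrl <- preprocess_dataset(ctrl, ref, tolerance, tophat_window)
    rm(ctrl)
    case <- simulate_dataset(spec, labels, "case",
                             seed = plan$seeds[p, 2], scale = plan$scales[p])
    m_case <- preprocess_dataset(case, ref, tolerance, tophat_window)
    rm(case)
    matrices[[p]] <- list(pair_id = sprintf("pair%02d", p),
                          control = m_ctrl, case = m_case, labels = labels)
  }
  records <- pairwise_roc(matrices, regions = regions, theta_up = theta_up,
                          theta_down = theta_down, min_pixels = min_pixels)
  changes <- consistency_filter(records, n_pairs)
  report <- build_change_report(matrices, changes, annotation = annotation)
  list(ref = ref, records = records, changes = changes, report = report,
       ground_truth = phantom_ground_truth(spec), matrices = matrices,
       labels = labels)
}

#' Score a phantom-study result against its ground truth
#'
#' Sensitivity is the fraction of planted (m/z, region) changes recovered
#' with the planted direction; false positives are retained (m/z, region)
#' combinations whose m/z carries no planted change in any region (null
#' species). Changes recovered for a planted species in an aggregate region
#' (gray matter, whole hippocampus) are neither hits nor false positives.
#'
#' @param result List from [run_phantom_study()].
#' @return List: `sensitivity`, `n_false_positive`, `n_true_positive`,
#'   `direction_match` (logical: every recovered planted change has the
#'   planted direction), `hits` (per-truth-row logical).
#' @export
score_recovery <- function(result) {
  truth <- result$ground_truth
  changes <- result$changes
  key <- function(mz, region) paste(sprintf("%.4f", mz), region)
  truth_key <- key(truth$mz, truth$region)
  change_key <- key(changes$mz, changes$region)
  hit_rows <- match(truth_key, change_key)
  hits <- !is.na(hit_rows) &
    changes$direction[ifelse(is.na(hit_rows), 1L, hit_rows)] == truth$direction
  null_mz <- setdiff(sprintf("%.4f", result$ref$mz),
                     sprintf("%.4f", truth$mz))
  fp <- sum(sprintf("%.4f", changes$mz) %in% null_mz)
  matched <- !is.na(hit_rows)
  list(sensitivity = mean(hits),
       n_true_positive = sum(hits),
       n_false_positive = fp,
       direction_match = all(
         changes$direction[hit_rows[matched]] == truth$direction[matched]),
       hits = hits)
}
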