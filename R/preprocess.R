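# Spectral preprocessing chain. Canonical order is fixed:
# align -> top-hat baseline removal -> TIC normalization -> peak extraction.
# Swapping baseline removal and normalization changes results (normalizing
# first rescales the baseline differently per pixel); a regression test pins
# the canonical order.

#' Morphological top-hat baseline removal
#'
#' Replaces every spectrum by `spectrum - opening(spectrum)`, where the
#' opening is an erosion (running minimum) followed by a dilation (running
#' maximum) with a flat structuring element of width `window` on the m/z
#' axis. Removes smooth baseline while preserving peaks narrower than the
#' window; the result is non-negative, and the opening of a constant
#' spectrum is that constant, so constants map to zero.
#'
#' @param dataset An [msi_dataset()].
#' @param window Structuring element width in Da (default 1.5; must be well
#'   above the peak FWHM, ~0.2 Da for TOF lipid peaks, and below the
#'   baseline variation scale). Must span at least 3 channels.
#' @return The baseline-corrected [msi_dataset()].
#' @export
tophat_baseline <- function(dataset, window = 1.5) {
  if (window <= 0) stop("window must be > 0")
  step <- median(diff(dataset$mz))
  # half-width in channels; tiny epsilon keeps e.g. 1.5 Da / 0.1 Da at 15
  # channels despite floating-point division
  h <- as.integer(floor(window / (2 * step) + 1e-9))
  if (h < 1L || window / step + 1e-9 < 3)
    stop("top-hat window spans fewer than 3 channels")
  eroded <- .morph_cols(dataset$intensities, h, TRUE)
  opening <- .morph_cols(eroded, h, FALSE)
  corrected <- dataset$intensities - opening
  corrected[corrected < 0] <- 0  # guards fp round-off; opening <= spectrum
  dataset$intensities <- corrected
  dataset$metadata$tophat_window <- window
  dataset
}

#' Total ion count normalization
#'
#' Scales every on-tissue pixel spectrum so its summed intensity equals the
#' dataset's mean pre-normalization TIC. Using the mean TIC (rather than 1)
#' keeps intensities on an interpretable counts scale; percent changes are
#' invariant to this choice. Off-tissue, all-zero pixels are left untouched.
#'
#' @param dataset An [msi_dataset()].
#' @return The normalized [msi_dataset()]; `metadata$tic_target` records the
#'   common TIC.
#' @export
tic_normalize <- function(dataset) {
  tic <- pixel_tic(dataset)
  on <- tic > 0
  if (!any(on)) stop("no on-tissue pixels to normalize")
  target <- mean(tic[on])
  dataset$intensities[, on] <-
    sweep(dataset$intensities[, on, drop = FALSE], 2, target / tic[on], `*`)
  dataset$metadata$tic_target <- target
  dataset
}

#' Align a dataset to a control m/z list
#'
#' Maps each reference m/z to the axis interval `[mz - tolerance,
#' mz + tolerance]`. Windows of adjacent references are truncated at their
#' midpoint when they overlap. A reference is assigned (`present`) when the
#' mean on-tissue spectrum has a local maximum inside its window; an apex
#' sitting on the window edge with the signal still rising beyond it does
#' not count. References outside the axis range are marked absent, not an
#' error. Apex ties break toward lower m/z.
#'
#' @param dataset An [msi_dataset()].
#' @param ref A [ref_mz_list()].
#' @param tolerance Half-window in Da (default 0.25, matching TOF mass
#'   accuracy at lipid masses).
#' @return Data frame with one row per reference: `ref_index`, `mz`, channel
#'   window `[lo, hi]`, apex channel `center`, and `present`.
#' @export
align_to_reference <- function(dataset, ref, tolerance = 0.25) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  mz <- dataset$mz
  nref <- nrow(ref)
  lo_mz <- ref$mz - tolerance
  hi_mz <- ref$mz + tolerance
  if (nref > 1L) {
    mid <- (ref$mz[-nref] + ref$mz[-1]) / 2
    hi_mz[-nref] <- pmin(hi_mz[-nref], mid)
    lo_mz[-1] <- pmax(lo_mz[-1], mid)
  }
  on <- on_tissue(dataset)
  mean_spec <- if (any(on))
    rowMeans(dataset$intensities[, on, drop = FALSE])
  else rowMeans(dataset$intensities)
  out <- data.frame(ref_index = seq_len(nref), mz = ref$mz,
                    lo = NA_integer_, hi = NA_integer_,
                    center = NA_integer_, present = FALSE)
  for (i in seq_len(nref)) {
    idx <- which(mz >= lo_mz[i] & mz <= hi_mz[i])
    if (length(idx) == 0L) next
    out$lo[i] <- idx[1]; out$hi[i] <- idx[length(idx)]
    apex <- idx[which.max(mean_spec[idx])]
    # apex on a window edge with signal still rising outside is not a local max
    rising_left <- apex == idx[1] && apex > 1L &&
      mean_spec[apex - 1L] > mean_spec[apex]
    rising_right <- apex == idx[length(idx)] && apex < length(mz) &&
      mean_spec[apex + 1L] > mean_spec[apex]
    if (!rising_left && !rising_right) {
      out$center[i] <- apex
      out$present[i] <- TRUE
    }
  }
  out
}

#' Extract the pixels x references peak matrix
#'
#' The value for (pixel, reference) is the sum of intensities over the
#' aligned window (an integral, robust to ~0.1 Da apex jitter, rather than
#' the apex height). References absent from the axis give zero columns.
#'
#' @param dataset A baseline-corrected, TIC-normalized [msi_dataset()].
#' @param ref A [ref_mz_list()].
#' @param tolerance Half-window in Da (default 0.25).
#' @param alignment Optional precomputed [align_to_reference()] table.
#' @return A `peak_matrix`: numeric pixels x references matrix with
#'   attributes `coords`, `ref_mz`, `shape`, `on_tissue`, `tolerance`.
#' @export
extract_peak_matrix <- function(dataset, ref, tolerance = 0.25,
                                alignment = NULL) {
  if (is.null(alignment))
    alignment <- align_to_reference(dataset, ref, tolerance)
  npix <- ncol(dataset$intensities)
  out <- matrix(0, npix, nrow(alignment))
  for (i in seq_len(nrow(alignment))) {
    if (is.na(alignment$lo[i])) next
    out[, i] <- colSums(dataset$intensities[alignment$lo[i]:alignment$hi[i], ,
                                            drop = FALSE])
  }
  colnames(out) <- sprintf("mz%.4f", alignment$mz)
  structure(out,
            coords = dataset$coords,
            ref_mz = alignment$mz,
            shape = raster_shape(dataset),
            on_tissue = on_tissue(dataset),
            tolerance = tolerance,
            class = c("peak_matrix", "matrix", "array"))
}

#' Detect references present in a dataset
#'
#' A reference counts as detected when the apex of the mean on-tissue
#' spectrum inside its window is at least `snr_threshold` times a robust
#' noise estimate: 1.4826 x the median absolute deviation of the mean
#' spectrum over channels at least `exclusion` Da away from every reference.
#'
#' @param dataset An [msi_dataset()] (baseline-corrected).
#' @param ref A [ref_mz_list()].
#' @param tolerance Alignment half-window in Da.
#' @param snr_threshold Signal-to-noise cutoff (default 3).
#' @param exclusion Off-peak distance in Da for the noise estimate (default 1).
#' @return Integer vector of detected reference indices.
#' @export
detect_peaks <- function(dataset, ref, tolerance = 0.25, snr_threshold = 3,
                         exclusion = 1.0) {
  if (snr_threshold <= 0) stop("snr_threshold must be > 0")
  on <- on_tissue(dataset)
  if (!any(on)) stop("no on-tissue pixels")
  mean_spec <- rowMeans(dataset$intensities[, on, drop = FALSE])
  off_peak <- rep(TRUE, length(dataset$mz))
  for (m in ref$mz)
    off_peak[abs(dataset$mz - m) < exclusion] <- FALSE
  if (!any(off_peak)) stop("no off-peak channels for the noise estimate")
  noise <- mad(mean_spec[off_peak], constant = 1.4826)
  noise <- max(noise, .Machine$double.eps)
  alignment <- align_to_reference(dataset, ref, tolerance)
  apex <- rep(0, nrow(alignment))
  ok <- !is.na(alignment$lo)
  apex[ok] <- vapply(which(ok), function(i)
    max(mean_spec[alignment$lo[i]:alignment$hi[i]]), numeric(1))
  which(ok & apex >= snr_threshold * noise)
}

#' Run the canonical preprocessing chain on one dataset
#'
#' Alignment windows are computed on the raw spectra, then top-hat baseline
#' removal, TIC normalization and windowed peak extraction are applied in
#' that fixed order.
#'
#' @param dataset An [msi_dataset()].
#' @param ref A [ref_mz_list()].
#' @param tolerance Alignment half-window in Da (default 0.25).
#' @param tophat_window Top-hat structuring element width in Da (default 1.5).
#' @return A `peak_matrix` (see [extract_peak_matrix()]).
#' @export
preprocess_dataset <- function(dataset, ref, tolerance = 0.25,
                               tophat_window = 1.5) {
  alignment <- align_to_reference(dataset, ref, tolerance)
  dataset <- tophat_baseline(dataset, tophat_window)
  dataset <- tic_normalize(dataset)
  extract_peak_matrix(dataset, ref, tolerance, alignment = alignment)
}
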