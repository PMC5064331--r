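#' MSI dataset container
#'
#' An `msi_dataset` holds profile spectra for one tissue section on a shared
#' m/z axis. Spectra are stored as a channels x pixels matrix (one spectrum
#' per column, the usual MSI convention), with integer raster coordinates for
#' each pixel.
#'
#' @param mz Numeric vector, strictly increasing m/z axis (Da), shared by all
#'   pixels.
#' @param intensities Numeric matrix, `length(mz)` rows by number-of-pixels
#'   columns; non-negative.
#' @param coords Data frame with integer columns `row`, `col` (0-based raster
#'   positions), one row per pixel; positions must be unique.
#' @param pixel_size Raster pitch in micrometres (default 100, typical MALDI
#'   imaging spacing).
#' @param metadata Free-form named list.
#'
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(mz, intensities, coords, pixel_size = 100,
                        metadata = list()) {
  mz <- as.numeric(mz)
  if (length(mz) < 2L || any(diff(mz) <= 0))
    stop("`mz` must be a strictly increasing vector of length >= 2")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(mz))
    stop("`intensities` must have one row per m/z channel")
  coords <- as.data.frame(coords)
  if (!all(c("row", "col") %in% names(coords)))
    stop("`coords` must have columns `row` and `col`")
  if (nrow(coords) != ncol(intensities))
    stop("`coords` must have one row per pixel")
  if (anyDuplicated(coords[, c("row", "col")]))
    stop("pixel coordinates must be unique")
  if (any(intensities < 0))
    stop("intensities must be non-negative")
  structure(
    list(mz = mz,
         intensities = intensities,
         coords = data.frame(row = as.integer(coords$row),
                             col = as.integer(coords$col)),
         pixel_size = pixel_size,
         metadata = metadata),
    class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("msi_dataset: %d pixels x %d m/z channels (m/z %.1f-%.1f)\n",
              ncol(x$intensities), length(x$mz), min(x$mz), max(x$mz)))
  cat(sprintf("  raster %d x %d, pixel size %g um, %d on-tissue pixels\n",
              max(x$coords$row) + 1L, max(x$coords$col) + 1L,
              x$pixel_size, sum(pixel_tic(x) > 0)))
  invisible(x)
}

#' Per-pixel total ion count
#'
#' @param dataset An [msi_dataset()].
#' @return Numeric vector of summed intensities, one per pixel.
#' @export
pixel_tic <- function(dataset) {
  colSums(dataset$intensities)
}

#' On-tissue pixel mask
#'
#' Pixels with zero total ion count are treated as off-tissue throughout the
#' pipeline (the phantom generator emits true zeros off tissue, and real
#' acquisitions are cropped to the tissue outline upstream).
#'
#' @param dataset An [msi_dataset()].
#' @return Logical vector, one entry per pixel.
#' @export
on_tissue <- function(dataset) {
  pixel_tic(dataset) > 0
}

#' Image raster dimensions of a dataset
#' @param dataset An [msi_dataset()].
#' @return Integer `c(rows, cols)`.
#' @export
raster_shape <- function(dataset) {
  c(max(dataset$coords$row) + 1L, max(dataset$coords$col) + 1L)
}

# canonical row-major pixel order (row, then col)
canonical_pixel_order <- function(coords) {
  order(coords$row, coords$col)
}

#' ROI label map
#'
#' Integer label raster assigning each pixel to background (label 0) or a
#' named anatomical region, plus a legend mapping labels to region names.
#'
#' @param raster Integer matrix of labels (rows x cols).
#' @param legend Named character vector mapping label (as character) to region
#'   name; must cover every label present and map `"0"` to `"background"`.
#' @return An object of class `roi_labels`.
#' @export
roi_labels <- function(raster, legend) {
  raster <- as.matrix(raster)
  storage.mode(raster) <- "integer"
  present <- sort(unique(as.vector(raster)))
  missing <- setdiff(as.character(present), names(legend))
  if (length(missing) > 0L)
    stop("legend is missing label(s): ", paste(missing, collapse = ", "))
  if (any(present < 0L)) stop("labels must be non-negative")
  if (!identical(unname(legend["0"]), "background") && 0L %in% present)
    stop("label 0 must map to 'background'")
  structure(list(raster = raster, legend = legend), class = "roi_labels")
}

#' @export
print.roi_labels <- function(x, ...) {
  tab <- table(factor(x$legend[as.character(x$raster)],
                      levels = unique(unname(x$legend))))
  cat("roi_labels:", nrow(x$raster), "x", ncol(x$raster), "raster\n")
  for (nm in names(tab)) cat(sprintf("  %-14s %d px\n", nm, tab[[nm]]))
  invisible(x)
}

#' Region name for each pixel of a dataset
#'
#' @param labels An [roi_labels()] map.
#' @param coords Pixel coordinate data frame (`row`, `col`, 0-based).
#' @return Character vector of region names, one per pixel.
#' @export
pixel_regions <- function(labels, coords) {
  lab <- labels$raster[cbind(coords$row + 1L, coords$col + 1L)]
  unname(labels$legend[as.character(lab)])
}
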