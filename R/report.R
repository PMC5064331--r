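# Ion-image rendering and m/z annotation, following the presentation
# conventions of subfield MSI studies: automatic hotspot removal by upper
# quantile clipping, weak edge-preserving denoising, rainbow intensity
# scale with a physical scale bar.

#' Build an ion image with hotspot removal and denoising
#'
#' Intensities above the `clip_quantile` order statistic of the on-tissue
#' values are clipped to it ("automatic hotspot removal", so a few saturated
#' pixels cannot dominate the color scale; clipping is monotone and
#' idempotent), then a weak 3x3 median denoise is applied unless disabled.
#' `clip_quantile = 1` clips nothing.
#'
#' @param matrix A `peak_matrix` from [extract_peak_matrix()].
#' @param ref_index Reference column index.
#' @param clip_quantile Upper clipping quantile (default 0.99); the clip
#'   level is the order statistic `ceiling(q * n)` of the n on-tissue values.
#' @param denoise `"weak"`, `"strong"` or `"off"`.
#' @return Object of class `ion_image`: `values` raster, `mz`,
#'   `pixel_size`, `clip_level`, `clip_quantile`, `denoise`.
#' @export
ion_image <- function(matrix, ref_index, clip_quantile = 0.99,
                      denoise = c("weak", "strong", "off")) {
  denoise <- match.arg(denoise)
  if (ref_index < 1L || ref_index > ncol(matrix)) stop("invalid ref_index")
  coords <- attr(matrix, "coords")
  shape <- attr(matrix, "shape")
  on <- attr(matrix, "on_tissue")
  v <- matrix[, ref_index]
  clip_level <- if (clip_quantile >= 1) max(v[on]) else
    quantile(v[on], clip_quantile, type = 1, names = FALSE)
  v[v > clip_level] <- clip_level
  img <- feature_image(v, coords, shape)
  if (denoise != "off") {
    img <- median_filter2d(img, if (denoise == "weak") 3L else 5L)
    off_img <- feature_image(as.numeric(!on), coords, shape) > 0
    img[off_img] <- 0
  }
  structure(list(values = img, mz = attr(matrix, "ref_mz")[ref_index],
                 pixel_size = attr(matrix, "pixel_size") %||% 100,
                 clip_level = clip_level, clip_quantile = clip_quantile,
                 denoise = denoise),
            class = "ion_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot an ion image
#'
#' Renders the raster with a rainbow intensity colormap (per-image scale,
#' minimum to clip level) and a scale bar derived from the pixel size.
#'
#' @param x An `ion_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.ion_image <- function(x, ...) {
  df <- expand.grid(row = seq_len(nrow(x$values)),
                    col = seq_len(ncol(x$values)))
  df$value <- as.vector(x$values)
  bar_px <- max(1, round(1000 / x$pixel_size))  # 1 mm scale bar
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = grDevices::rainbow(7, end = 0.7,
                                                               rev = TRUE),
                                  name = "intensity") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::annotate("segment", x = 2, xend = 2 + bar_px,
                      y = nrow(x$values) - 1, yend = nrow(x$values) - 1,
                      linewidth = 1.2) +
    ggplot2::annotate("text", x = 2 + bar_px / 2, y = nrow(x$values) - 2.2,
                      label = "1 mm", size = 3) +
    ggplot2::labs(title = sprintf("m/z %.1f", x$mz)) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5))
}

#' @importFrom ggplot2 .data
NULL

#' Annotate reference m/z values against a lipid table
#'
#' Assigns each reference the nearest lipid-table entry within `tolerance`
#' Da; unmatched references are labeled `"unassigned"`. Ties break to the
#' nearest entry, then to the lower table m/z.
#'
#' @param ref A [ref_mz_list()].
#' @param lipid_table Data frame with columns `mz` and `name` (e.g. the
#'   packaged assignment fixture, [lipid_assignments()]).
#' @param tolerance Match tolerance in Da (default 0.25).
#' @return Named character vector: `sprintf("%.4f", ref$mz)` -> assignment.
#' @export
annotate_mz <- function(ref, lipid_table, tolerance = 0.25) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  tab <- lipid_table[order(lipid_table$mz), , drop = FALSE]
  out <- vapply(ref$mz, function(m) {
    d <- abs(tab$mz - m)
    ok <- which(d <= tolerance)
    if (length(ok) == 0L) return("unassigned")
    best <- ok[order(d[ok], tab$mz[ok])][1]  # nearest, then lower m/z
    tab$name[best]
  }, character(1))
  names(out) <- sprintf("%.4f", ref$mz)
  out
}

#' Packaged lipid assignment table
#'
#' The putative lipid identities shipped with the package (negative- and
#' positive-mode assignments of hippocampal lipid species from the published
#' mammalian brain lipidome), used for annotation and its tests.
#'
#' @return Data frame with columns `mz`, `name`, `polarity`.
#' @export
lipid_assignments <- function() {
  path <- system.file("extdata", "lipid_assignments.tsv", package = "msidiff")
  read.delim(path, check.names = FALSE)
}

#' Horizontal bar plot of consistent percent changes in one region
#'
#' One bar per consistently changed reference, ordered by m/z, signed and
#' colored by direction — the standard per-region summary graphic.
#'
#' @param changes Change report from [build_change_report()].
#' @param region Region name to plot.
#' @return A ggplot object (empty axes when no changes exist).
#' @export
change_barplot <- function(changes, region) {
  df <- changes[changes$region == region, , drop = FALSE]
  df <- df[order(df$mz), , drop = FALSE]
  df$label <- factor(sprintf("%.1f", df$mz),
                     levels = rev(sprintf("%.1f", df$mz)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_percent_change,
                                        y = .data$label,
                                        fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#2980b9"),
                               drop = TRUE) +
    ggplot2::labs(x = "% change from control", y = "m/z", title = region) +
    ggplot2::theme_minimal()
  p
}
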