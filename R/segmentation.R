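# Spatial segmentation: k-means over per-pixel peak vectors after
# edge-preserving median denoising of the per-m/z feature images. This
# approximates the proprietary "group areas with a similar m/z profile"
# segmentation of commercial MSI software; downstream statistics use the
# traced ROI label maps, so segmentation serves white/gray-matter QC only.

feature_image <- function(values, coords, shape) {
  img <- matrix(0, shape[1], shape[2])
  img[cbind(coords$row + 1L, coords$col + 1L)] <- values
  img
}

median_filter2d <- function(img, k) {
  if (k == 1L) return(img)
  h <- (k - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  stack <- array(NA_real_, c(nr, nc, k * k))
  s <- 0L
  for (dr in -h:h) for (dc in -h:h) {
    s <- s + 1L
    r_src <- pmin(pmax(seq_len(nr) + dr, 1L), nr)  # replicate edges
    c_src <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    stack[, , s] <- img[r_src, c_src]
  }
  apply(stack, c(1, 2), median)
}

#' Edge-preserving denoising of feature images
#'
#' Reshapes each reference's column to its 2D ion image and applies a median
#' filter (`weak`: 3x3, `strong`: 5x5, `off`: identity). Median filtering
#' preserves step edges while removing impulse noise. Off-tissue pixels are
#' reset to zero afterwards, so the on-tissue pixel set never changes.
#'
#' @param matrix A `peak_matrix` from [extract_peak_matrix()].
#' @param strength `"off"`, `"weak"` or `"strong"`.
#' @return The denoised `peak_matrix`.
#' @export
denoise_feature_images <- function(matrix, strength = c("weak", "strong", "off")) {
  strength <- match.arg(strength)
  if (strength == "off") return(matrix)
  k <- if (strength == "weak") 3L else 5L
  coords <- attr(matrix, "coords")
  shape <- attr(matrix, "shape")
  on <- attr(matrix, "on_tissue")
  idx <- cbind(coords$row + 1L, coords$col + 1L)
  for (j in seq_len(ncol(matrix))) {
    img <- median_filter2d(feature_image(matrix[, j], coords, shape), k)
    v <- img[idx]
    v[!on] <- 0
    matrix[, j] <- v
  }
  matrix
}

#' k-means spatial segmentation
#'
#' Clusters per-pixel peak vectors (columns scaled to unit variance over
#' on-tissue pixels) with k-means, deterministically for a given seed.
#' Noiseless phantoms collapse regions to duplicate profiles, which the
#' default Hartigan-Wong algorithm rejects, so Lloyd's algorithm is run from
#' `nstart` sets of distinct pixel profiles and the lowest within-cluster
#' sum of squares wins.
#'
#' @param matrix A `peak_matrix`.
#' @param k Number of clusters (>= 2; default 3: background rim, white and
#'   gray matter).
#' @param seed Integer seed (default 42).
#' @param nstart Number of random restarts (default 10).
#' @return Object of class `segmentation_result`: `cluster_map` (integer
#'   raster, 0 off tissue), `k`, `cluster_profiles` (k x references mean
#'   peak vectors), `pixel_cluster`, and empty `assignment` (see
#'   [map_clusters()]).
#' @export
segment_spatial <- function(matrix, k = 3L, seed = 42L, nstart = 10L) {
  if (k < 2L) stop("k must be >= 2")
  on <- attr(matrix, "on_tissue")
  if (sum(on) < k) stop("fewer on-tissue pixels than clusters")
  x <- matrix[on, , drop = FALSE]
  sds <- apply(x, 2, sd)
  sds[sds == 0 | is.na(sds)] <- 1
  xs <- sweep(x, 2, sds, `/`)
  distinct <- unique(xs)
  if (nrow(distinct) < k)
    stop("fewer distinct pixel profiles than clusters")
  set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- distinct[sample.int(nrow(distinct), k), , drop = FALSE]
    km <- suppressWarnings(
      kmeans(xs, centers = centers, iter.max = 200L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  coords <- attr(matrix, "coords")
  shape <- attr(matrix, "shape")
  pixel_cluster <- integer(nrow(matrix))
  pixel_cluster[on] <- best$cluster
  cluster_map <- feature_image(pixel_cluster, coords, shape)
  storage.mode(cluster_map) <- "integer"
  profiles <- do.call(rbind, lapply(seq_len(k), function(ci)
    colMeans(x[best$cluster == ci, , drop = FALSE])))
  structure(list(cluster_map = cluster_map, k = k,
                 cluster_profiles = profiles,
                 pixel_cluster = pixel_cluster,
                 ref_mz = attr(matrix, "ref_mz"),
                 assignment = NULL),
            class = "segmentation_result")
}

#' Name segmentation clusters as white matter, gray matter or background
#'
#' The cluster with the highest mean intensity over the marker references
#' (by default white-matter sulfatide-like markers) is labeled
#' `white_matter`; the lowest-TIC cluster is labeled `background` when its
#' mean TIC falls below 10% of the global mean; every other cluster is
#' `gray_matter`. A tie in marker means breaks deterministically toward the
#' lower cluster index, with a warning.
#'
#' @param result A `segmentation_result` from [segment_spatial()].
#' @param marker_refs Integer indices (into the reference list) of
#'   white-matter marker species.
#' @param background_frac TIC fraction below which the dimmest cluster is
#'   background (default 0.1).
#' @return The `segmentation_result` with `assignment` filled (named
#'   character vector, cluster index -> region).
#' @export
map_clusters <- function(result, marker_refs, background_frac = 0.1) {
  if (length(marker_refs) == 0L) stop("marker_refs must be non-empty")
  prof <- result$cluster_profiles
  marker_mean <- rowMeans(prof[, marker_refs, drop = FALSE])
  top <- which(marker_mean == max(marker_mean))
  if (length(top) > 1L)
    warning("tie in marker means; assigning white_matter to cluster ", top[1])
  assignment <- rep("gray_matter", result$k)
  assignment[top[1]] <- "white_matter"
  tic <- rowSums(prof)
  dim_cluster <- which.min(tic)
  if (tic[dim_cluster] < background_frac * mean(tic) &&
      dim_cluster != top[1])
    assignment[dim_cluster] <- "background"
  names(assignment) <- as.character(seq_len(result$k))
  result$assignment <- assignment
  result
}
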