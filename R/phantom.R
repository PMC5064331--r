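#' Species panel for a phantom study
#'
#' Bundles the simulated lipid species: centroid m/z, Gaussian peak width, a
#' base-abundance matrix (species x regions, apex counts in the control
#' condition) and a fold-change matrix applied to the case member of each
#' pair (1 = unchanged).
#'
#' @param mz Numeric vector of species centroid m/z (Da).
#' @param peak_sigma Gaussian peak sigma (Da); scalar or per-species vector.
#' @param abundance Numeric matrix, species x regions, apex amplitude in
#'   counts; column names are region names.
#' @param fold Numeric matrix, species x regions, case/control fold change;
#'   defaults to all 1 (no change). All entries must be > 0.
#' @return An object of class `species_set`.
#' @export
species_set <- function(mz, peak_sigma, abundance, fold = NULL) {
  mz <- as.numeric(mz)
  n <- length(mz)
  peak_sigma <- rep_len(as.numeric(peak_sigma), n)
  abundance <- as.matrix(abundance)
  if (nrow(abundance) != n) stop("`abundance` needs one row per species")
  if (is.null(colnames(abundance))) stop("`abundance` needs region column names")
  if (is.null(fold)) {
    fold <- abundance * 0 + 1
  }
  fold <- as.matrix(fold)
  if (!identical(dim(fold), dim(abundance)))
    stop("`fold` must match `abundance` in shape")
  colnames(fold) <- colnames(abundance)
  if (any(peak_sigma <= 0)) stop("peak_sigma must be > 0")
  if (any(abundance < 0)) stop("abundances must be >= 0")
  if (any(fold <= 0)) stop("fold changes must be > 0")
  structure(list(mz = mz, peak_sigma = peak_sigma,
                 abundance = abundance, fold = fold),
            class = "species_set")
}

#' Default species panel for the six-pair phantom study
#'
#' Forty species on the lipid m/z range: ten carry planted region-specific
#' changes (two per subfield-level region, one increased and one decreased,
#' with offsetting summed abundance so per-pixel TIC is preserved between
#' case and control, mirroring the mixed increase/decrease pattern real
#' subfield studies report) and thirty are null. Planted m/z values reuse
#' prominent hippocampal lipid species; null species are spread over
#' m/z 520-1000 with region profiles that make some white-matter enriched
#' (sulfatide-like), some gray-matter enriched, and the rest uniform.
#'
#' @return A [species_set()] over regions white_matter, CA1, CA2/3, CA4, DG.
#' @export
species_panel_default <- function() {
  regions <- c("white_matter", "CA1", "CA2/3", "CA4", "DG")
  planted <- data.frame(
    mz     = c(786.6, 794.6, 885.6, 906.7, 600.5, 791.6, 843.7, 779.6, 918.7, 778.6),
    region = c("CA1", "CA1", "DG", "DG", "CA4", "CA4", "CA2/3", "CA2/3",
               "white_matter", "white_matter"),
    abund  = c(2000, 3000, 4000, 3000, 3000, 3000, 4000, 4000, 4000, 4000),
    fold   = c(1.75, 0.50, 1.30, 0.60, 1.40, 0.60, 1.35, 0.65, 1.45, 0.55))
  # per-region balance: sum of abund * (fold - 1) is 0 within each region
  # (the fold applies only in each species' own region, where `abund` above
  # is its abundance; the sulfatide-like species get white-matter-enriched
  # profiles below without touching those in-region abundances)
  null_mz <- c(520.3, 534.4, 548.2, 562.6, 576.3, 590.4, 616.4, 632.5, 660.4,
               674.5, 688.3, 702.4, 716.3, 724.5, 732.4, 744.5, 752.3, 760.4,
               772.3, 800.5, 806.3, 820.6, 828.4, 836.5, 852.6, 860.4, 868.5,
               876.4, 894.5, 930.6)
  all_mz <- c(planted$mz, null_mz)
  n <- length(all_mz)
  ab <- matrix(0, n, length(regions), dimnames = list(NULL, regions))
  fold <- ab + 1
  for (i in seq_len(nrow(planted))) {
    ab[i, ] <- planted$abund[i]
    fold[i, planted$region[i]] <- planted$fold[i]
  }
  # sulfatides are myelin lipids: strongly white-matter enriched, usable as
  # segmentation markers; their in-region (DG / white matter) abundances stay
  # as listed so the planted deltas remain balanced
  ab[planted$mz == 906.7, ] <- c(9000, 3000, 3000, 3000, 3000)
  ab[planted$mz == 918.7, ] <- c(4000, 1500, 1500, 1500, 1500)
  # null species profiles: 10 white-matter enriched, 10 gray enriched, 10 flat
  base <- rep(c(900, 1400, 2200, 1100, 1800), length.out = length(null_mz))
  for (k in seq_along(null_mz)) {
    i <- nrow(planted) + k
    prof <- rep(base[k], length(regions))
    names(prof) <- regions
    grp <- (k - 1L) %% 3L
    if (grp == 0L) {                      # white-matter enriched
      prof["white_matter"] <- base[k] * 4
    } else if (grp == 1L) {               # gray-matter enriched
      prof[c("CA1", "CA2/3", "CA4", "DG")] <- base[k] * 3
      prof["white_matter"] <- base[k] * 0.5
    }
    ab[i, ] <- prof
  }
  species_set(all_mz, peak_sigma = 0.08, abundance = ab, fold = fold)
}

#' Phantom study specification
#'
#' Describes a synthetic paired MALDI imaging study: raster geometry, region
#' layout, species panel, acquisition axis, baseline and noise model, and
#' pixel-level TIC variability. Defaults reproduce the study conditions the
#' pipeline is validated under: 100 um raster pitch and an m/z 400-2000 axis.
#'
#' @param image_shape Integer `c(rows, cols)` of the raster (>= 8 x 8).
#' @param region_layout `"subfields"` (background, white matter and the CA1,
#'   CA2/3, CA4, DG gray-matter subfields as concentric curved bands) or
#'   `"halves"` (background plus white/gray half-discs, for segmentation
#'   benchmarks).
#' @param species A [species_set()]; its region names must match the layout.
#' @param mz_range m/z axis limits in Da (default 400-2000).
#' @param mz_step Axis spacing in Da (default 0.1, ~16k channels).
#' @param raster_pitch Pixel spacing in micrometres (default 100).
#' @param baseline_amplitude Chemical-baseline amplitude at the low-mass axis
#'   end, counts (default 150).
#' @param baseline_decay Baseline exponential decay rate, 1/Da (default 0.01).
#' @param tic_cv Coefficient of variation of the per-pixel multiplicative
#'   (log-normal) TIC factor (default 0.15).
#' @param noise_sd Off-signal channel noise sd in counts; channel noise is
#'   Gaussian with signal-dependent variance `noise_sd^2 * (1 + intensity)`
#'   (shot-noise-like counting statistics). `0` disables noise entirely.
#' @param pair_scale_range Range of the uniform per-pair global intensity
#'   factor (default +/-10%), emulating section-to-section acquisition
#'   variability; both members of a pair share the factor because each matched
#'   pair is acquired in one dataset.
#' @param seed Default random seed used when none is passed to the simulators.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(48L, 48L),
                         region_layout = c("subfields", "halves"),
                         species = species_panel_default(),
                         mz_range = c(400, 2000),
                         mz_step = 0.1,
                         raster_pitch = 100,
                         baseline_amplitude = 150,
                         baseline_decay = 0.01,
                         tic_cv = 0.15,
                         noise_sd = 2,
                         pair_scale_range = c(0.9, 1.1),
                         seed = 1L) {
  region_layout <- match.arg(region_layout)
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 8L))
    stop("image_shape must be at least 8 x 8")
  if (mz_step <= 0) stop("mz_step must be > 0")
  if (baseline_amplitude < 0 || tic_cv < 0 || noise_sd < 0)
    stop("amplitudes, tic_cv and noise_sd must be >= 0")
  if (!inherits(species, "species_set")) stop("`species` must be a species_set")
  if (any(species$mz < mz_range[1] | species$mz > mz_range[2]))
    stop("species m/z outside mz_range")
  layout_regions <- layout_region_names(region_layout)
  missing <- setdiff(colnames(species$abundance), layout_regions)
  if (length(missing) > 0L)
    stop("species regions not in layout: ", paste(missing, collapse = ", "))
  structure(
    list(image_shape = image_shape, region_layout = region_layout,
         species = species, mz_range = as.numeric(mz_range),
         mz_step = mz_step, raster_pitch = raster_pitch,
         baseline_amplitude = baseline_amplitude,
         baseline_decay = baseline_decay, tic_cv = tic_cv,
         noise_sd = noise_sd, pair_scale_range = pair_scale_range,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

layout_region_names <- function(layout) {
  switch(layout,
         subfields = c("white_matter", "CA1", "CA2/3", "CA4", "DG"),
         halves = c("white_matter", "gray_matter"))
}

#' Build the ROI label raster of a phantom
#'
#' Deterministic for a given spec. The `"subfields"` layout places the
#' dentate gyrus at the centre of a tissue disc, wrapped by CA4, CA2/3 and
#' CA1 bands and an outer white-matter ring (alveus/fimbria-like); only label
#' identity matters downstream, not anatomical fidelity. Every named region
#' must receive at least 16 pixels, otherwise a configuration error names the
#' offending region.
#'
#' @param spec A [phantom_spec()].
#' @return An [roi_labels()] map.
#' @export
make_phantom_labels <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
  rows <- matrix(seq_len(nr) - 1L, nr, nc)
  cols <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)
  r <- sqrt(((rows - cr) / (nr / 2))^2 + ((cols - cc) / (nc / 2))^2)
  raster <- matrix(0L, nr, nc)
  if (spec$region_layout == "subfields") {
    edges <- c(0.25, 0.42, 0.58, 0.74, 1.0) * 0.95
    regions <- c("DG", "CA4", "CA2/3", "CA1", "white_matter")
    lower <- c(0, edges[-5])
    legend <- c("0" = "background")
    for (i in seq_along(regions)) {
      raster[r >= lower[i] & r < edges[i]] <- i
      legend[as.character(i)] <- regions[i]
    }
    # re-map labels so legend order is stable: keep as built
  } else {
    inside <- r < 0.95
    raster[inside & cols < cc] <- 1L
    raster[inside & cols >= cc] <- 2L
    legend <- c("0" = "background", "1" = "white_matter", "2" = "gray_matter")
  }
  counts <- table(factor(raster, levels = 0:max(raster)))
  named <- setdiff(unname(legend), "background")
  for (nm in named) {
    lab <- names(legend)[match(nm, legend)]
    if (is.na(lab) || counts[[lab]] < 16L)
      stop(sprintf("region '%s' has fewer than 16 pixels in this layout", nm))
  }
  roi_labels(raster, legend)
}

# region -> per-channel clean spectrum template for one role
region_templates <- function(spec, role) {
  mz <- phantom_mz_axis(spec)
  regions <- layout_region_names(spec$region_layout)
  sp <- spec$species
  base <- spec$baseline_amplitude * exp(-spec$baseline_decay * (mz - spec$mz_range[1]))
  out <- matrix(0, length(mz), length(regions), dimnames = list(NULL, regions))
  for (g in regions) {
    tmpl <- base
    amp <- if (g %in% colnames(sp$abundance)) sp$abundance[, g] else rep(0, length(sp$mz))
    fc <- if (g %in% colnames(sp$fold)) sp$fold[, g] else rep(1, length(sp$mz))
    if (role == "case") amp <- amp * fc
    for (s in seq_along(sp$mz)) {
      if (amp[s] == 0) next
      sig <- sp$peak_sigma[s]
      idx <- which(mz >= sp$mz[s] - 5 * sig & mz <= sp$mz[s] + 5 * sig)
      tmpl[idx] <- tmpl[idx] + amp[s] * exp(-(mz[idx] - sp$mz[s])^2 / (2 * sig^2))
    }
    out[, g] <- tmpl
  }
  out
}

#' m/z axis of a phantom spec
#' @param spec A [phantom_spec()].
#' @return Numeric vector from `mz_range[1]` to `mz_range[2]` by `mz_step`.
#' @export
phantom_mz_axis <- function(spec) {
  seq(spec$mz_range[1], spec$mz_range[2], by = spec$mz_step)
}

#' Simulate one phantom section
#'
#' Each on-tissue pixel spectrum is the sum of the Gaussian species peaks of
#' its region (case amplitudes multiplied by the planted fold changes), plus
#' a decaying-exponential chemical baseline, scaled by a per-pixel log-normal
#' TIC factor (mean 1, CV `tic_cv`) and an optional global `scale`, with
#' Gaussian channel noise of variance `noise_sd^2 * (1 + intensity)` added
#' and the result clipped at zero. Off-tissue (background) pixels are zero.
#' Reproducible for a given seed.
#'
#' @param spec A [phantom_spec()].
#' @param labels An [roi_labels()] matching `spec$image_shape`.
#' @param role `"control"` or `"case"`.
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param scale Global intensity factor (e.g. a per-pair acquisition factor).
#' @return An [msi_dataset()] with `metadata$role` and `metadata$shape` set.
#' @export
simulate_dataset <- function(spec, labels, role = c("control", "case"),
                             seed = spec$seed, scale = 1) {
  role <- match.arg(role)
  if (!identical(dim(labels$raster), as.integer(spec$image_shape)))
    stop("labels do not match spec image_shape")
  set.seed(seed)
  mz <- phantom_mz_axis(spec)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  coords <- data.frame(row = rep(0:(nr - 1L), each = nc),
                       col = rep(0:(nc - 1L), times = nr))
  npix <- nrow(coords)
  region <- pixel_regions(labels, coords)
  templates <- region_templates(spec, role)
  x <- matrix(0, length(mz), npix)
  tissue <- which(region != "background")
  if (length(tissue) > 0L) {
    sdlog <- sqrt(log(1 + spec$tic_cv^2))
    fac <- if (spec$tic_cv > 0)
      rlnorm(length(tissue), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else rep(1, length(tissue))
    for (g in colnames(templates)) {
      sel <- which(region[tissue] == g)
      if (length(sel) == 0L) next
      x[, tissue[sel]] <- outer(templates[, g], scale * fac[sel])
    }
    if (spec$noise_sd > 0) {
      sub <- x[, tissue, drop = FALSE]
      noise <- rnorm(length(sub), mean = 0,
                     sd = spec$noise_sd * sqrt(1 + sub))
      x[, tissue] <- pmax(sub + noise, 0)
    }
  }
  msi_dataset(mz, x, coords, pixel_size = spec$raster_pitch,
              metadata = list(role = role, seed = seed, scale = scale,
                              shape = c(nr, nc)))
}

#' Ground-truth table of planted changes
#'
#' @param spec A [phantom_spec()].
#' @return Data frame with columns `mz`, `region`, `direction` (`up`/`down`)
#'   and `fold`, one row per planted (species, region) change (fold != 1),
#'   ordered by m/z then region.
#' @export
phantom_ground_truth <- function(spec) {
  sp <- spec$species
  idx <- which(sp$fold != 1, arr.ind = TRUE)
  out <- data.frame(
    mz = sp$mz[idx[, 1]],
    region = colnames(sp$fold)[idx[, 2]],
    direction = ifelse(sp$fold[idx] > 1, "up", "down"),
    fold = sp$fold[idx])
  out <- out[order(out$mz, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a paired case/control study
#'
#' Generates `n_pairs` independent (control, case) section pairs sharing one
#' [phantom_spec()] but with per-pair noise realizations and a per-pair
#' global intensity factor drawn uniformly from `spec$pair_scale_range`
#' (shared by both members of a pair, since each matched pair is acquired in
#' a single dataset).
#'
#' @param spec A [phantom_spec()].
#' @param n_pairs Number of matched pairs (>= 1; the reference study design
#'   uses 6 age- and gender-matched pairs).
#' @param seed Integer seed.
#' @return A list of class `paired_study` with elements `pairs` (each a list
#'   `pair_id`, `control`, `case`, `labels`) and `ground_truth`
#'   (see [phantom_ground_truth()]).
#' @export
simulate_paired_study <- function(spec, n_pairs = 6L, seed = spec$seed) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  labels <- make_phantom_labels(spec)
  plan <- study_plan(spec, n_pairs, seed)
  pairs <- lapply(seq_len(n_pairs), function(p) {
    list(pair_id = sprintf("pair%02d", p),
         control = simulate_dataset(spec, labels, "control",
                                    seed = plan$seeds[p, 1], scale = plan$scales[p]),
         case = simulate_dataset(spec, labels, "case",
                                 seed = plan$seeds[p, 2], scale = plan$scales[p]),
         labels = labels)
  })
  structure(list(pairs = pairs, ground_truth = phantom_ground_truth(spec)),
            class = "paired_study")
}

# shared derivation of per-pair seeds and scale factors, so that streaming
# pipelines and simulate_paired_study agree for the same (spec, n_pairs, seed)
study_plan <- function(spec, n_pairs, seed) {
  set.seed(seed)
  list(seeds = matrix(sample.int(.Machine$integer.max - 1L, 2L * n_pairs),
                      ncol = 2L),
       scales = runif(n_pairs, spec$pair_scale_range[1], spec$pair_scale_range[2]))
}

#' Control m/z list implied by a phantom spec
#'
#' @param spec A [phantom_spec()].
#' @return A [ref_mz_list()] of the panel's species m/z values.
#' @export
phantom_reference_list <- function(spec) {
  ref_mz_list(data.frame(mz = spec$species$mz, label = NA_character_,
                         polarity = "-"))
}
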