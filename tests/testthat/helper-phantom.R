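# Small phantom builders shared across tests. Sizes are kept small so the
# suite stays fast; the acceptance tests run the full-scale conditions.

# minimal species set on the subfields layout
mini_species <- function(mz = c(520.0, 560.0, 600.0),
                         sigma = 0.08,
                         abundance = 1000,
                         fold_region = NULL, fold = 1) {
  regions <- c("white_matter", "CA1", "CA2/3", "CA4", "DG")
  ab <- matrix(abundance, length(mz), length(regions),
               dimnames = list(NULL, regions))
  fd <- ab * 0 + 1
  if (!is.null(fold_region)) fd[1, fold_region] <- fold
  species_set(mz, sigma, ab, fd)
}

tiny_spec <- function(species = mini_species(), image_shape = c(24, 24),
                      mz_range = c(500, 650), noise_sd = 2, tic_cv = 0.15,
                      baseline_amplitude = 150, ...) {
  phantom_spec(image_shape = image_shape, species = species,
               mz_range = mz_range, noise_sd = noise_sd, tic_cv = tic_cv,
               baseline_amplitude = baseline_amplitude, ...)
}

# two-region (white/gray halves) phantom for segmentation benchmarks:
# four species per half, no baseline so noise_sd is the whole noise model
two_region_spec <- function(image_shape = c(64, 64), amplitude = 30,
                            noise_sd = 0) {
  mz <- seq(420, 560, by = 20)
  ab <- matrix(0, length(mz), 2,
               dimnames = list(NULL, c("white_matter", "gray_matter")))
  ab[1:4, "white_matter"] <- amplitude
  ab[5:8, "gray_matter"] <- amplitude
  phantom_spec(image_shape = image_shape, region_layout = "halves",
               species = species_set(mz, 0.08, ab),
               mz_range = c(400, 600), baseline_amplitude = 0,
               tic_cv = 0, noise_sd = noise_sd)
}

# a fake preprocessed pair with fully controlled region means, for exercising
# the differential stage without simulation
fake_pair <- function(pair_id, mean_control, mean_case, n_px = 30,
                      ref_mz = c(700.0, 800.0)) {
  raster <- matrix(0L, 2, n_px)
  raster[1, ] <- 1L
  labels <- roi_labels(raster, c("0" = "background", "1" = "CA1"))
  coords <- data.frame(row = rep(0:1, each = n_px), col = rep(0:(n_px - 1), 2))
  on <- coords$row == 0
  build <- function(m) {
    x <- matrix(0, 2 * n_px, length(ref_mz))
    for (j in seq_along(ref_mz)) x[on, j] <- m[j]
    structure(x, coords = coords, ref_mz = ref_mz, shape = c(2L, n_px),
              on_tissue = on, tolerance = 0.25,
              class = c("peak_matrix", "matrix", "array"))
  }
  list(pair_id = pair_id, control = build(mean_control),
       case = build(mean_case), labels = labels)
}

# hand-rolled ROC record table for consistency-filter tests
fake_records <- function(directions, ref_index = 1L, mz = 700.0,
                         region = "CA1") {
  data.frame(ref_index = ref_index, mz = mz, region = region,
             pair_id = sprintf("pair%02d", seq_along(directions)),
             auc = ifelse(directions == "up", 0.9,
                          ifelse(directions == "down", 0.1, 0.5)),
             n_control_pixels = 50L, n_case_pixels = 50L,
             direction = directions)
}

# minimal processed-mode imzML writer (per-pixel m/z axes) used to test the
# reader's resampling path against a direct interpolation oracle
write_processed_imzml <- function(spectra, path) {
  ibd <- sub("\\.imzML$", ".ibd", path)
  con <- file(ibd, "wb")
  writeBin(as.raw(rep(1, 16)), con)
  offset <- 16
  meta <- list()
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    mz_off <- offset
    writeBin(as.numeric(s$mz), con, size = 8, endian = "little")
    offset <- offset + 8 * length(s$mz)
    int_off <- offset
    writeBin(as.numeric(s$int), con, size = 4, endian = "little")
    offset <- offset + 4 * length(s$int)
    meta[[i]] <- list(mz_off = mz_off, int_off = int_off, n = length(s$mz),
                      x = s$x, y = s$y)
  }
  close(con)
  spectrum_xml <- vapply(seq_along(meta), function(i) {
    m <- meta[[i]]
    paste0(
      sprintf('<spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">', i, i - 1L, m$n),
      '<scanList count="1"><scan>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>', m$x),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>', m$y),
      '</scan></scanList><binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', m$n),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>', 8L * m$n),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>', m$mz_off),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', m$n),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>', 4L * m$n),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>', m$int_off),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<run id="run1"><spectrumList count="2">',
    spectrum_xml,
    '</spectrumList></run></mzML>'), path)
  path
}
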