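# imzML exchange format: XML descriptor (*.imzML) plus binary companion
# (*.ibd). Continuous mode stores one shared m/z axis and one intensity
# vector per pixel; processed mode stores per-pixel axes. We write continuous
# mode (m/z float64, intensities float32) and read both modes.

ibd_path_for <- function(path) {
  sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
}

format_uuid <- function(bytes) {
  hex <- paste(sprintf("%02x", as.integer(bytes)), collapse = "")
  paste(substr(hex, 1, 8), substr(hex, 9, 12), substr(hex, 13, 16),
        substr(hex, 17, 20), substr(hex, 21, 32), sep = "-")
}

#' Write a dataset to imzML (continuous mode)
#'
#' Emits `path` (XML) and the binary companion `.ibd` next to it. The m/z
#' axis is stored once as 64-bit floats; per-pixel intensities as 32-bit
#' floats (so intensities round-trip to float32 precision). Internal 0-based
#' (row, col) coordinates are converted to 1-based imzML (x = col + 1,
#' y = row + 1) positions.
#'
#' @param dataset An [msi_dataset()].
#' @param path Output path ending in `.imzML`.
#' @return Invisibly, `path`.
#' @export
write_imzml <- function(dataset, path) {
  if (!grepl("\\.imzml$", path, ignore.case = TRUE))
    stop("path must end in .imzML")
  ibd <- ibd_path_for(path)
  npix <- ncol(dataset$intensities)
  if (npix == 0L) stop("dataset has no pixels")
  nchan <- length(dataset$mz)

  uuid_bytes <- as.raw(sample.int(256L, 16L) - 1L)
  con <- file(ibd, "wb")
  writeBin(uuid_bytes, con)
  writeBin(as.numeric(dataset$mz), con, size = 8, endian = "little")
  mz_offset <- 16
  int_offsets <- mz_offset + 8 * nchan + (seq_len(npix) - 1) * 4 * nchan
  for (p in seq_len(npix))
    writeBin(as.numeric(dataset$intensities[, p]), con, size = 4,
             endian = "little")
  close(con)

  xs <- dataset$coords$col + 1L
  ys <- dataset$coords$row + 1L
  spectra <- vapply(seq_len(npix), function(p) {
    paste0(
      sprintf('      <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">\n',
              p, p - 1L, nchan),
      '        <scanList count="1">\n          <scan>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n', xs[p]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n', ys[p]),
      '          </scan>\n        </scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="mzArray"/>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', nchan),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', 8L * nchan),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n', mz_offset),
      '            <binary/>\n          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="intensityArray"/>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', nchan),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', 4L * nchan),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n', int_offsets[p]),
      '            <binary/>\n          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n      </spectrum>')
  }, character(1))

  header <- c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '  <cvList count="2">',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '  </cvList>',
    '  <fileDescription>',
    '    <fileContent>',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>',
            format_uuid(uuid_bytes)),
    '    </fileContent>',
    '  </fileDescription>',
    '  <referenceableParamGroupList count="2">',
    '    <referenceableParamGroup id="mzArray">',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '    <referenceableParamGroup id="intensityArray">',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '  </referenceableParamGroupList>',
    '  <softwareList count="1">',
    '    <software id="msidiff" version="0.1.0">',
    '      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="msidiff"/>',
    '    </software>',
    '  </softwareList>',
    '  <scanSettingsList count="1">',
    '    <scanSettings id="scanSettings1">',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', max(xs)),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', max(ys)),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g"/>', dataset$pixel_size),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g"/>', dataset$pixel_size),
    '    </scanSettings>',
    '  </scanSettingsList>',
    '  <instrumentConfigurationList count="1">',
    '    <instrumentConfiguration id="IC1"/>',
    '  </instrumentConfigurationList>',
    '  <dataProcessingList count="1">',
    '    <dataProcessing id="export">',
    '      <processingMethod order="1" softwareRef="msidiff">',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '      </processingMethod>',
    '    </dataProcessing>',
    '  </dataProcessingList>',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="export">', npix))
  footer <- c('    </spectrumList>', '  </run>', '</mzML>')
  writeLines(c(header, spectra, footer), path)
  invisible(path)
}

# pull the first cvParam value for an accession below a node
cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) NA_character_ else xml2::xml_attr(p, "value")
}

read_ibd_array <- function(con, offset, n, encoded_len) {
  size <- as.integer(round(encoded_len / n))
  if (!size %in% c(4L, 8L)) stop("unsupported ibd element size: ", size)
  seek(con, where = offset, origin = "start")
  readBin(con, "numeric", n = n, size = size, endian = "little")
}

#' Read an imzML dataset
#'
#' Continuous-mode files are read directly. Processed-mode files (per-pixel
#' m/z axes) are resampled by linear interpolation onto a uniform axis
#' spanning the union m/z range at the median channel spacing. Pixels are
#' returned in canonical row-major order regardless of file order.
#'
#' @param path Path to the `.imzML` XML file; the `.ibd` companion must sit
#'   next to it.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path) {
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd))
    stop("missing ibd companion file: ", ibd)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  mode <- if (!inherits(xml2::xml_find_first(
    doc, "//fileContent/cvParam[@accession='IMS:1000031']"), "xml_missing"))
    "processed" else "continuous"

  # which referenceableParamGroup is the m/z array?
  groups <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  gid <- vapply(groups, xml2::xml_attr, character(1), attr = "id")
  is_mz_group <- vapply(groups, function(g) {
    !inherits(xml2::xml_find_first(g, "./cvParam[@accession='MS:1000514']"),
              "xml_missing")
  }, logical(1))
  mz_group <- gid[is_mz_group][1]
  if (is.na(mz_group)) stop("format error: no m/z array param group")

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  if (length(spectra) == 0L) stop("format error: empty pixel list")

  pixel_size <- suppressWarnings(as.numeric(
    cv_value(doc, "IMS:1000046")))
  if (is.na(pixel_size)) pixel_size <- 100

  con <- file(ibd, "rb")
  on.exit(close(con))
  parse_arrays <- function(sp) {
    x <- as.integer(cv_value(sp, "IMS:1000050"))
    y <- as.integer(cv_value(sp, "IMS:1000051"))
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    out <- list(x = x, y = y)
    for (a in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(a, "./referenceableParamGroupRef"), "ref")
      info <- list(
        offset = as.numeric(cv_value(a, "IMS:1000102")),
        n = as.integer(cv_value(a, "IMS:1000103")),
        enc = as.numeric(cv_value(a, "IMS:1000104")))
      if (identical(ref, mz_group)) out$mz <- info else out$int <- info
    }
    out
  }
  meta <- lapply(spectra, parse_arrays)

  if (mode == "continuous") {
    m1 <- meta[[1]]$mz
    mz <- read_ibd_array(con, m1$offset, m1$n, m1$enc)
    if (any(diff(mz) <= 0)) stop("format error: non-monotone m/z axis")
    ints <- vapply(meta, function(m)
      read_ibd_array(con, m$int$offset, m$int$n, m$int$enc),
      numeric(m1$n))
  } else {
    spec <- lapply(meta, function(m) {
      list(mz = read_ibd_array(con, m$mz$offset, m$mz$n, m$mz$enc),
           int = read_ibd_array(con, m$int$offset, m$int$n, m$int$enc))
    })
    for (s in spec)
      if (any(diff(s$mz) <= 0)) stop("format error: non-monotone m/z axis")
    spacing <- median(unlist(lapply(spec, function(s) diff(s$mz))))
    lo <- min(vapply(spec, function(s) s$mz[1], numeric(1)))
    hi <- max(vapply(spec, function(s) s$mz[length(s$mz)], numeric(1)))
    mz <- seq(lo, hi, by = spacing)
    ints <- vapply(spec, function(s)
      approx(s$mz, s$int, xout = mz, yleft = 0, yright = 0)$y,
      numeric(length(mz)))
  }
  ints[ints < 0] <- 0
  coords <- data.frame(
    row = vapply(meta, function(m) m$y, integer(1)) - 1L,
    col = vapply(meta, function(m) m$x, integer(1)) - 1L)
  ord <- canonical_pixel_order(coords)
  msi_dataset(mz, ints[, ord, drop = FALSE], coords[ord, , drop = FALSE],
              pixel_size = pixel_size,
              metadata = list(source = path, mode = mode))
}
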