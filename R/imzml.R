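#' Read a continuous-mode imzML imaging dataset
#'
#' Parses the imzML 1.1.0 XML index and pulls each pixel's m/z and intensity
#' arrays from the binary `.ibd` companion. One [msi_spectrum] is returned
#' per pixel, in the file's pixel order, with 1-based imzML coordinates
#' preserved.
#'
#' @param path path to the `.imzML` file; the `.ibd` companion must sit next
#'   to it with the same base name.
#' @param tma_id dataset identifier attached to every spectrum; defaults to
#'   the file base name.
#' @return List of [msi_spectrum] objects (possibly empty).
#' @export
read_imzml <- function(path, tma_id = NULL) {
  if (!file.exists(path)) stop("imzML file not found: ", path)
  ibd <- ibd_companion(path)
  if (is.null(tma_id)) tma_id <- sub("\\.[iI]mz[mM][lL]$", "", basename(path))

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (length(nodes) == 0L) return(list())

  cv_value <- function(node, accession, xpath_prefix = ".") {
    v <- xml2::xml_attr(xml2::xml_find_first(
      node, sprintf("%s//cvParam[@accession='%s']", xpath_prefix, accession)),
      "value")
    v
  }

  con <- file(ibd, "rb")
  on.exit(close(con))
  spectra <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    node <- nodes[[i]]
    px <- as.integer(cv_value(node, "IMS:1000050"))
    py <- as.integer(cv_value(node, "IMS:1000051"))
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    got <- list(mz = NULL, intensity = NULL)
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, "./referenceableParamGroupRef"), "ref")
      kind <- if (!is.na(ref) && grepl("mz", ref, ignore.case = TRUE)) "mz"
        else if (!is.na(ref)) "intensity"
        else if (!is.na(cv_value(arr, "MS:1000514"))) "mz"
        else "intensity"
      offset <- as.numeric(cv_value(arr, "IMS:1000102"))
      alen <- as.integer(cv_value(arr, "IMS:1000103"))
      if (is.na(offset) || is.na(alen)) {
        stop("pixel ", i, ": binary array without external offset/length")
      }
      seek(con, where = offset, origin = "start")
      got[[kind]] <- readBin(con, "double", n = alen, size = 8,
                             endian = "little")
    }
    if (is.null(got$mz) || is.null(got$intensity)) {
      stop("pixel ", i, ": missing m/z or intensity array")
    }
    if (length(got$mz) != length(got$intensity)) {
      stop("pixel ", i, ": m/z and intensity array lengths differ (",
           length(got$mz), " vs ", length(got$intensity), ")")
    }
    if (length(got$mz) > 1L && any(diff(got$mz) <= 0)) {
      stop("pixel ", i, ": m/z axis is not strictly increasing")
    }
    spectra[[i]] <- msi_spectrum(got$mz, got$intensity, c(px, py), tma_id)
  }
  spectra
}

ibd_companion <- function(path) {
  base <- sub("\\.[iI]mz[mM][lL]$", "", path)
  for (ext in c(".ibd", ".IBD")) {
    if (file.exists(paste0(base, ext))) return(paste0(base, ext))
  }
  stop("binary companion (.ibd) missing for ", path)
}

#' Write spectra sharing one m/z axis as a continuous-mode imzML dataset
#'
#' All spectra must have identical m/z axes (the continuous imzML dialect
#' stores the axis once). Arrays are written as uncompressed little-endian
#' 64-bit floats so a read/write round trip is bit-identical.
#'
#' @param spectra non-empty list of [msi_spectrum] with identical `mz`.
#' @param path output `.imzML` path; the `.ibd` is placed alongside.
#' @return `path`, invisibly.
#' @export
write_imzml_file <- function(spectra, path) {
  stopifnot(length(spectra) > 0L)
  mz <- spectra[[1]]$mz
  for (s in spectra) {
    if (!identical(s$mz, mz)) {
      stop("continuous-mode writer requires identical m/z axes across pixels")
    }
  }
  if (!grepl("\\.imzML$", path)) path <- paste0(path, ".imzML")
  ibd <- sub("\\.imzML$", ".ibd", path)
  L <- length(mz)
  n <- length(spectra)
  uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)

  con <- file(ibd, "wb")
  writeBin(uuid, con)
  writeBin(mz, con, size = 8, endian = "little")
  for (s in spectra) writeBin(s$intensity, con, size = 8, endian = "little")
  close(con)

  mz_offset <- 16
  int_offset <- function(i) 16 + 8 * L + (i - 1) * 8 * L
  uuid_str <- paste0("{", paste(sprintf("%02x", as.integer(uuid)),
                                collapse = ""), "}")
  xs <- vapply(spectra, function(s) s$coords[1], integer(1))
  ys <- vapply(spectra, function(s) s$coords[2], integer(1))

  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '  <cvList count="3">',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '  </cvList>',
    '  <fileDescription>',
    '    <fileContent>',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>', uuid_str),
    '    </fileContent>',
    '  </fileDescription>',
    '  <referenceableParamGroupList count="2">',
    '    <referenceableParamGroup id="mzArray">',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '    <referenceableParamGroup id="intensityArray">',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '  </referenceableParamGroupList>',
    '  <softwareList count="1">',
    '    <software id="msitma" version="0.1.0">',
    '      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="msitma"/>',
    '    </software>',
    '  </softwareList>',
    '  <scanSettingsList count="1">',
    '    <scanSettings id="scanSettings1">',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', max(xs)),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', max(ys)),
    '    </scanSettings>',
    '  </scanSettingsList>',
    '  <instrumentConfigurationList count="1">',
    '    <instrumentConfiguration id="IC1"/>',
    '  </instrumentConfigurationList>',
    '  <dataProcessingList count="1">',
    '    <dataProcessing id="export">',
    '      <processingMethod order="1" softwareRef="msitma">',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '      </processingMethod>',
    '    </dataProcessing>',
    '  </dataProcessingList>',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="export">', n)
  )

  spec_xml <- vapply(seq_len(n), function(i) paste0(
    sprintf('      <spectrum id="spectrum=%d" defaultArrayLength="%d" index="%d">\n', i, L, i - 1L),
    '        <scanList count="1">\n',
    '          <scan>\n',
    sprintf('            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n', xs[i]),
    sprintf('            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n', ys[i]),
    '          </scan>\n',
    '        </scanList>\n',
    '        <binaryDataArrayList count="2">\n',
    '          <binaryDataArray encodedLength="0">\n',
    '            <referenceableParamGroupRef ref="mzArray"/>\n',
    sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', L),
    sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', 8L * L),
    sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n', mz_offset),
    '            <binary/>\n',
    '          </binaryDataArray>\n',
    '          <binaryDataArray encodedLength="0">\n',
    '            <referenceableParamGroupRef ref="intensityArray"/>\n',
    sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', L),
    sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', 8L * L),
    sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n', int_offset(i)),
    '            <binary/>\n',
    '          </binaryDataArray>\n',
    '        </binaryDataArrayList>\n',
    '      </spectrum>'), character(1))

  tail <- c('    </spectrumList>', '  </run>', '</mzML>')
  writeLines(c(head, spec_xml, tail), path)
  invisible(path)
}
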