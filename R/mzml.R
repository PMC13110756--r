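# Minimal mzML reader/writer for centroided spectra.
#
# The installed stack has no mzML library, so the package carries a small
# self-contained implementation: uncompressed 64-bit little-endian binary
# arrays, base64-encoded, with the controlled-vocabulary accessions needed
# for MS level, scan start time (minutes), selected precursor m/z and the
# m/z / intensity arrays. It reads what it writes and any mzML restricted
# to those encodings.

.b64_doubles_enc <- function(x) {
  jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                endian = "little"))
}

.b64_doubles_dec <- function(s) {
  r <- jsonlite::base64_dec(gsub("\\s", "", s))
  readBin(r, "double", n = length(r) / 8, size = 8, endian = "little")
}

.binary_array_xml <- function(values, accession, name) {
  enc <- .b64_doubles_enc(values)
  paste0(
    '<binaryDataArray encodedLength="', nchar(enc), '">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="MS" accession="', accession, '" name="', name, '"/>',
    '<binary>', enc, '</binary></binaryDataArray>')
}

#' Write a centroided run to mzML
#'
#' @param run A [centroid_run()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "centroid_run"))
  scans <- run$scans
  sp <- character(nrow(scans))
  for (i in seq_len(nrow(scans))) {
    prec <- ""
    if (scans$ms_level[i] > 1 && !is.na(scans$precursor_mz[i])) {
      prec <- paste0(
        '<precursorList count="1"><precursor><selectedIonList count="1">',
        '<selectedIon><cvParam cvRef="MS" accession="MS:1000744" ',
        'name="selected ion m/z" value="', scans$precursor_mz[i],
        '"/></selectedIon></selectedIonList></precursor></precursorList>')
    }
    sp[i] <- paste0(
      '<spectrum index="', i - 1, '" id="scan=', i,
      '" defaultArrayLength="', length(scans$mz[[i]]), '">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="',
      scans$ms_level[i], '"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" ',
      'value="', scans$rt[i],
      '" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/>',
      '</scan></scanList>', prec,
      '<binaryDataArrayList count="2">',
      .binary_array_xml(scans$mz[[i]], "MS:1000514", "m/z array"),
      .binary_array_xml(scans$intensity[[i]], "MS:1000515",
                        "intensity array"),
      '</binaryDataArrayList></spectrum>')
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="', run$id, '">',
    '<spectrumList count="', nrow(scans), '">',
    paste(sp, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(doc, path)
  invisible(path)
}

.read_binary_array <- function(node) {
  params <- xml2::xml_find_all(node, "./d1:cvParam")
  acc <- xml2::xml_attr(params, "accession")
  if (!"MS:1000523" %in% acc) {
    stop("unsupported binary encoding (only 64-bit float is handled)")
  }
  if (!"MS:1000576" %in% acc) {
    stop("unsupported binary compression (only 'no compression' is handled)")
  }
  kind <- if ("MS:1000514" %in% acc) "mz"
          else if ("MS:1000515" %in% acc) "intensity"
          else "other"
  values <- .b64_doubles_dec(
    xml2::xml_text(xml2::xml_find_first(node, "./d1:binary")))
  list(kind = kind, values = values)
}

#' Read a centroided mzML file
#'
#' @param path mzML path (uncompressed 64-bit float arrays).
#' @param id Run id (default: file name).
#' @param polarity Run polarity (metadata only).
#' @return A [centroid_run()].
#' @export
read_mzml <- function(path, id = NULL, polarity = "positive") {
  doc <- xml2::read_xml(path)
  spectra <- xml2::xml_find_all(doc, "//d1:spectrum")
  if (length(spectra) == 0) stop("no spectra found in '", path, "'")
  rows <- purrr::map(spectra, function(sp) {
    params <- xml2::xml_find_all(sp, "./d1:cvParam")
    acc <- xml2::xml_attr(params, "accession")
    val <- xml2::xml_attr(params, "value")
    ms_level <- as.integer(val[acc == "MS:1000511"][1])
    rt_node <- xml2::xml_find_first(
      sp, ".//d1:scan/d1:cvParam[@accession='MS:1000016']")
    rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
    unit <- xml2::xml_attr(rt_node, "unitName")
    if (!is.na(unit) && unit == "second") rt <- rt / 60
    prec_node <- xml2::xml_find_first(
      sp, ".//d1:selectedIon/d1:cvParam[@accession='MS:1000744']")
    prec <- if (inherits(prec_node, "xml_missing")) NA_real_ else {
      as.numeric(xml2::xml_attr(prec_node, "value"))
    }
    arrays <- purrr::map(
      xml2::xml_find_all(sp, ".//d1:binaryDataArray"), .read_binary_array)
    mz <- intensity <- numeric(0)
    for (a in arrays) {
      if (a$kind == "mz") mz <- a$values
      if (a$kind == "intensity") intensity <- a$values
    }
    list(rt = rt, ms_level = ms_level, mz = mz, intensity = intensity,
         precursor_mz = prec)
  })
  scans <- tibble::tibble(
    rt = purrr::map_dbl(rows, "rt"),
    ms_level = purrr::map_int(rows, "ms_level"),
    mz = purrr::map(rows, "mz"),
    intensity = purrr::map(rows, "intensity"),
    precursor_mz = purrr::map_dbl(rows, "precursor_mz"))
  scans <- scans[order(scans$rt), ]
  centroid_run(scans, id = id %||% basename(path), polarity = polarity)
}
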