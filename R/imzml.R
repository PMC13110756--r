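# Minimal imzML (processed mode) writer/reader: XML index + external .ibd
# binary with 64-bit little-endian m/z and intensity arrays per pixel.
# Hand-rolled because the installed stack has no imzML library.

#' Write an MSI run to imzML (processed mode)
#'
#' Writes `<path>.imzML` plus the external binary `<path>.ibd`.
#'
#' @param run An [msi_run()].
#' @param path Output path without extension (or ending in `.imzML`).
#' @return The imzML path, invisibly.
#' @export
write_imzml <- function(run, path) {
  stopifnot(inherits(run, "msi_run"))
  path <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  ibd_path <- paste0(path, ".ibd")
  xml_path <- paste0(path, ".imzML")
  px <- run$pixels
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  uuid <- as.raw(1:16)
  writeBin(uuid, con)
  offset <- 16
  entries <- character(nrow(px))
  for (i in seq_len(nrow(px))) {
    mz <- as.double(px$mz[[i]])
    it <- as.double(px$intensity[[i]])
    writeBin(mz, con, size = 8, endian = "little")
    mz_off <- offset
    offset <- offset + 8 * length(mz)
    writeBin(it, con, size = 8, endian = "little")
    it_off <- offset
    offset <- offset + 8 * length(it)
    entries[i] <- paste0(
      '<spectrum index="', i - 1, '" id="spectrum=', i,
      '" defaultArrayLength="', length(mz), '">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" ',
      'value="', px$x[i], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" ',
      'value="', px$y[i], '"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray>',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" ',
      'value="', mz_off, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" ',
      'name="external array length" value="', length(mz), '"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray>',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" ',
      'value="', it_off, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" ',
      'name="external array length" value="', length(it), '"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    '</fileContent></fileDescription>',
    '<scanSettingsList count="1"><scanSettings id="s1">',
    '<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" ',
    'value="', run$pitch, '"/>',
    '</scanSettings></scanSettingsList>',
    '<run id="', run$id, '"><spectrumList count="', nrow(px), '">',
    paste(entries, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(doc, xml_path)
  invisible(xml_path)
}

#' Read a processed-mode imzML file
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit beside it).
#' @param id Run id (default: file name).
#' @param polarity Metadata polarity.
#' @return An [msi_run()].
#' @export
read_imzml <- function(path, id = NULL, polarity = "positive") {
  stem <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  ibd_path <- paste0(stem, ".ibd")
  if (!file.exists(ibd_path)) stop("missing binary file '", ibd_path, "'")
  doc <- xml2::read_xml(path)
  pitch_node <- xml2::xml_find_first(
    doc, "//d1:cvParam[@accession='IMS:1000046']")
  pitch <- if (inherits(pitch_node, "xml_missing")) 30 else {
    as.numeric(xml2::xml_attr(pitch_node, "value"))
  }
  spectra <- xml2::xml_find_all(doc, "//d1:spectrum")
  if (length(spectra) == 0) stop("no spectra found in '", path, "'")
  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd), add = TRUE)
  read_at <- function(offset, n) {
    seek(ibd, where = offset, origin = "start")
    readBin(ibd, "double", n = n, size = 8, endian = "little")
  }
  rows <- purrr::map(spectra, function(sp) {
    x <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      sp, ".//d1:cvParam[@accession='IMS:1000050']"), "value"))
    y <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      sp, ".//d1:cvParam[@accession='IMS:1000051']"), "value"))
    arrays <- xml2::xml_find_all(sp, ".//d1:binaryDataArray")
    mz <- intensity <- numeric(0)
    for (arr in arrays) {
      params <- xml2::xml_find_all(arr, "./d1:cvParam")
      acc <- xml2::xml_attr(params, "accession")
      val <- xml2::xml_attr(params, "value")
      off <- as.numeric(val[acc == "IMS:1000102"][1])
      len <- as.integer(val[acc == "IMS:1000103"][1])
      values <- read_at(off, len)
      if ("MS:1000514" %in% acc) mz <- values
      if ("MS:1000515" %in% acc) intensity <- values
    }
    list(x = x, y = y, mz = mz, intensity = intensity)
  })
  pixels <- tibble::tibble(
    x = purrr::map_int(rows, "x"), y = purrr::map_int(rows, "y"),
    mz = purrr::map(rows, "mz"), intensity = purrr::map(rows, "intensity"))
  msi_run(pixels, pitch = pitch, id = id %||% basename(path),
          polarity = polarity)
}
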