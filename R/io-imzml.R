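## Continuous-mode imzML interchange: one shared m/z axis (the compressed
## calibration curve) plus per-pixel intensity arrays in the binary .ibd
## companion. Writer and reader are deterministic: the ibd UUID is derived
## from the payload, so identical inputs give byte-identical files.
## Internal pixel (0,0) maps to imzML position (1,1).

.IMZML_HEADER <- paste0(
  '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
  '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
  '  <cvList count="3">\n',
  '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.cvs.sourceforge.net/*checkout*/psidev/psi/psi-ms/mzML/controlledVocabulary/psi-ms.obo"/>\n',
  '    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
  '    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
  '  </cvList>\n')

.fmtNum <- function(x) formatC(x, digits = 9, format = "g")

#' Export compressed spectra to continuous-mode imzML
#'
#' Writes `<path>.imzML` (XML index) and `<path>.ibd` (binary arrays):
#' the shared m/z axis once as float64, then one float32 intensity array
#' per pixel, pixels in row-major order with x fastest and 1-based imzML
#' coordinates.
#'
#' @param cs a [CompressedSpectra-class].
#' @param path output path; the `.imzML`/`.ibd` extensions are appended
#'   to its base name.
#' @return The `.imzML` path, invisibly.
#' @export
exportImzML <- function(cs, path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  xmlPath <- paste0(base, ".imzML")
  ibdPath <- paste0(base, ".ibd")
  n <- ncol(cs@matrix)
  if (n == 0L) warning("exporting empty (0-point) spectra")
  npix <- cs@nx * cs@ny

  ## ibd payload: uuid (16 bytes, content-derived) + mz float64 + per-pixel
  ## float32 intensities
  mzRaw <- writeBin(as.numeric(cs@mzMap), raw(), size = 8L, endian = "little")
  intRaw <- writeBin(as.numeric(t(cs@matrix)), raw(), size = 4L,
                     endian = "little")
  tmp <- tempfile()
  writeBin(c(mzRaw, intRaw), tmp)
  uuid <- substr(tools::md5sum(tmp)[[1]], 1, 32)
  file.remove(tmp)
  con <- file(ibdPath, "wb")
  writeBin(as.raw(strtoi(substring(uuid, seq(1, 31, 2), seq(2, 32, 2)),
                         16L)), con)
  writeBin(c(mzRaw, intRaw), con)
  close(con)
  md5 <- tools::md5sum(ibdPath)[[1]]

  mzOffset <- 16
  intOffset0 <- 16 + 8 * n
  uuidFmt <- sprintf("{%s-%s-%s-%s-%s}", substr(uuid, 1, 8),
                     substr(uuid, 9, 12), substr(uuid, 13, 16),
                     substr(uuid, 17, 20), substr(uuid, 21, 32))

  out <- file(xmlPath, "wb")
  w <- function(...) writeLines(sprintf(...), out, sep = "\n")
  cat(.IMZML_HEADER, file = out)
  w('  <fileDescription>')
  w('    <fileContent>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>', uuidFmt)
  w('      <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>', toupper(md5))
  w('    </fileContent>')
  w('  </fileDescription>')
  w('  <referenceableParamGroupList count="2">')
  w('    <referenceableParamGroup id="mzArray">')
  w('      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>')
  w('      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>')
  w('      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>')
  w('    </referenceableParamGroup>')
  w('    <referenceableParamGroup id="intensityArray">')
  w('      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>')
  w('      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>')
  w('      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>')
  w('    </referenceableParamGroup>')
  w('  </referenceableParamGroupList>')
  w('  <softwareList count="1">')
  w('    <software id="TopoSIMS" version="0.1.0"/>')
  w('  </softwareList>')
  w('  <scanSettingsList count="1">')
  w('    <scanSettings id="scansettings1">')
  w('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', cs@nx)
  w('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', cs@ny)
  w('    </scanSettings>')
  w('  </scanSettingsList>')
  w('  <instrumentConfigurationList count="1">')
  w('    <instrumentConfiguration id="IC1"/>')
  w('  </instrumentConfigurationList>')
  w('  <dataProcessingList count="1">')
  w('    <dataProcessing id="export">')
  w('      <processingMethod order="1" softwareRef="TopoSIMS">')
  w('        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>')
  w('      </processingMethod>')
  w('    </dataProcessing>')
  w('  </dataProcessingList>')
  w('  <run id="run1" defaultInstrumentConfigurationRef="IC1">')
  w('    <spectrumList count="%d">', npix)
  for (p in seq_len(npix)) {
    ix <- (p - 1L) %% cs@nx + 1L
    iy <- (p - 1L) %/% cs@nx + 1L
    w('      <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">', p, p - 1L, n)
    w('        <scanList count="1">')
    w('          <scan>')
    w('            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>', ix)
    w('            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>', iy)
    w('          </scan>')
    w('        </scanList>')
    w('        <binaryDataArrayList count="2">')
    w('          <binaryDataArray encodedLength="0">')
    w('            <referenceableParamGroupRef ref="mzArray"/>')
    w('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', n)
    w('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>', mzOffset)
    w('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>', 8L * n)
    w('            <binary/>')
    w('          </binaryDataArray>')
    w('          <binaryDataArray encodedLength="0">')
    w('            <referenceableParamGroupRef ref="intensityArray"/>')
    w('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', n)
    w('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>', intOffset0 + (p - 1L) * 4L * n)
    w('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>', 4L * n)
    w('            <binary/>')
    w('          </binaryDataArray>')
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  close(out)
  invisible(xmlPath)
}

#' Import continuous-mode imzML into compressed spectra
#'
#' Reads files written by [exportImzML()] or other continuous-mode imzML
#' with a shared m/z axis. The segment table cannot be recovered from
#' imzML; the result carries one synthetic segment spanning all points
#' and an index map re-derived from the m/z axis via the supplied
#' geometry's calibration.
#'
#' @param path path to the `.imzML` file (the `.ibd` companion must sit
#'   next to it).
#' @param geom an [InstrumentGeometry-class] used to rebuild the
#'   point-to-raw-bin map from m/z.
#' @return A [CompressedSpectra-class].
#' @export
importImzML <- function(path, geom = instrumentGeometry()) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mode <- xml2::xml_find_first(doc, ".//fileContent/cvParam[@accession='IMS:1000030']")
  if (inherits(mode, "xml_missing")) {
    proc <- xml2::xml_find_first(doc, ".//fileContent/cvParam[@accession='IMS:1000031']")
    if (!inherits(proc, "xml_missing"))
      stop("processed-mode imzML with per-pixel axes is not supported")
  }
  ibdPath <- paste0(sub("\\.imzML$", "", path, ignore.case = TRUE), ".ibd")
  if (!file.exists(ibdPath)) stop("companion .ibd file not found: ", ibdPath)
  ibd <- readBin(ibdPath, "raw", file.info(ibdPath)$size)

  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  getv <- function(node, acc) {
    n <- xml2::xml_find_first(node,
      sprintf(".//cvParam[@accession='%s']", acc))
    as.numeric(xml2::xml_attr(n, "value"))
  }
  nspec <- length(spectra)
  xs <- ys <- integer(nspec)
  mz <- NULL
  ints <- vector("list", nspec)
  readArr <- function(offset, len, size) {
    bytes <- ibd[(offset + 1):(offset + len * size)]
    readBin(bytes, "numeric", len, size = size, endian = "little")
  }
  for (s in seq_len(nspec)) {
    node <- spectra[[s]]
    xs[s] <- as.integer(getv(node, "IMS:1000050"))
    ys[s] <- as.integer(getv(node, "IMS:1000051"))
    arrs <- xml2::xml_find_all(node, ".//binaryDataArray")
    for (a in arrs) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(a, ".//referenceableParamGroupRef"), "ref")
      off <- getv(a, "IMS:1000102")
      len <- getv(a, "IMS:1000103")
      if (identical(ref, "mzArray")) {
        if (is.null(mz)) mz <- readArr(off, len, 8L)
      } else {
        ints[[s]] <- readArr(off, len, 4L)
      }
    }
  }
  nx <- max(xs); ny <- max(ys)
  n <- length(mz)
  mat <- matrix(0, nrow = nx * ny, ncol = n)
  for (s in seq_len(nspec))
    mat[xs[s] + (ys[s] - 1L) * nx, ] <- ints[[s]]
  idx <- .quantBin(tofFromMass(mz, geom), geom)
  ## segmentation is recovered from runs of consecutive raw bins (labels
  ## and totals are not representable in imzML)
  if (n) {
    brk <- c(TRUE, diff(idx) != 1L)
    grp <- cumsum(brk)
    s <- as.integer(tapply(idx, grp, min))
    e <- as.integer(tapply(idx, grp, max))
    seg <- IRanges(start = s, end = e)
    mcols(seg)$totalCounts <- as.numeric(
      tapply(colSums(mat), grp, sum))
    mcols(seg)$label <- rep(NA_character_, length(seg))
    ptSeg <- as.integer(grp)
  } else {
    seg <- .emptySegments()
    ptSeg <- integer(0)
  }
  new("CompressedSpectra", matrix = mat, indexMap = idx,
      mzMap = as.numeric(mz), segments = seg,
      pointSegment = ptSeg, geom = geom,
      nx = as.integer(nx), ny = as.integer(ny))
}
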