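## Threshold-based identification of informative mass segments from the
## summed spectrum, and lossless restriction of the cube onto those
## segments at full TDC resolution. The point-index -> raw-bin -> m/z maps
## make the compressed axis interpretable ("calibration curve").

#' Summed (averaged) spectrum of a raw cube
#'
#' Element-wise sum of all pixel spectra; the reference used to identify
#' informative mass segments.
#'
#' @param raw a [RawSpectrumImage-class].
#' @return Numeric vector of length `nBins(geometry(raw))`.
#' @export
sumSpectrum <- function(raw) {
  as.numeric(Matrix::colSums(raw@counts))
}

#' Find informative mass segments by count thresholding
#'
#' Candidate segments are maximal runs of nonzero bins in the summed
#' spectrum; runs separated by fewer than `minGap` zero bins are merged,
#' each candidate is padded by `pad` bins on both sides (clipped to the
#' axis, overlaps re-merged), and a candidate is retained iff its total
#' counts reach `threshold`. The default `minGap` (40 bins = 2 ns) and
#' `pad` keep a peak and its topographically shifted copies inside one
#' segment, which the correction stage relies on.
#'
#' @param total summed spectrum (counts per raw bin).
#' @param threshold minimum total counts per retained segment (>= 1). The
#'   conventional working range is 500-1000 counts; at 256 x 256 pixels a
#'   1000-count threshold corresponds to roughly one ion per 65 pixels.
#' @param minGap zero-run length (bins) below which adjacent runs merge.
#' @param pad padding added to each side of a candidate, bins.
#' @return An `IRanges` (1-based, closed) with metadata columns
#'   `totalCounts` (numeric) and `label` (character, `NA` until labelled).
#' @examples
#' tot <- numeric(1000); tot[500:505] <- 200
#' findSegments(tot, threshold = 1000)
#' @export
findSegments <- function(total, threshold, minGap = 40L, pad = 10L) {
  if (threshold < 1) stop("threshold must be >= 1 count")
  nb <- length(total)
  r <- rle(total > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(.emptySegments())
  s <- starts[runs]; e <- ends[runs]
  ## merge runs separated by < minGap zero bins
  if (length(s) > 1L) {
    gap <- s[-1L] - e[-length(e)] - 1L
    newgrp <- c(TRUE, gap >= minGap)
    grp <- cumsum(newgrp)
    s <- tapply(s, grp, min)
    e <- tapply(e, grp, max)
  }
  ## pad, clip, re-merge overlaps/adjacency
  s <- pmax(1L, as.integer(s) - as.integer(pad))
  e <- pmin(nb, as.integer(e) + as.integer(pad))
  if (length(s) > 1L) {
    newgrp <- c(TRUE, s[-1L] > e[-length(e)] + 1L)
    grp <- cumsum(newgrp)
    s <- as.integer(tapply(s, grp, min))
    e <- as.integer(tapply(e, grp, max))
  }
  cs <- cumsum(total)
  tot <- cs[e] - ifelse(s > 1L, cs[s - 1L], 0)
  keep <- tot >= threshold
  seg <- IRanges(start = s[keep], end = e[keep])
  mcols(seg)$totalCounts <- as.numeric(tot[keep])
  mcols(seg)$label <- rep(NA_character_, sum(keep))
  seg
}

.emptySegments <- function() {
  seg <- IRanges()
  mcols(seg)$totalCounts <- numeric(0)
  mcols(seg)$label <- character(0)
  seg
}

#' Label segments by matching known species masses
#'
#' Assigns each species to the segment nearest its substrate-level TOF
#' bin, within `tolerance` bins. The tolerance accommodates the
#' topographic shift: a species confined to elevated regions peaks below
#' its substrate-level bin, by up to its full shift. Multiple species
#' falling in one segment append with "+".
#'
#' @param segments an `IRanges` from [findSegments()].
#' @param species a data.frame with columns `label` and `mass` (u), e.g.
#'   [defaultSpeciesTable()].
#' @param geom an [InstrumentGeometry-class].
#' @param tolerance maximum distance (bins) between the substrate-level
#'   bin and the segment; the default covers the shift of a heavy
#'   (Cs2-scale) ion over a few hundred micrometres of topography.
#' @return The segments with the `label` metadata column filled in.
#' @export
labelSegments <- function(segments, species, geom = instrumentGeometry(),
                          tolerance = 150L) {
  if (!length(segments)) return(segments)
  lab <- mcols(segments)$label
  for (i in seq_len(nrow(species))) {
    b <- .quantBin(tofFromMass(species$mass[i], geom), geom)
    d <- pmax(0L, start(segments) - b, b - end(segments))
    hit <- which.min(d)
    if (d[hit] <= tolerance) {
      lab[hit] <- if (is.na(lab[hit])) species$label[i] else
        paste(lab[hit], species$label[i], sep = "+")
    }
  }
  mcols(segments)$label <- lab
  segments
}

#' Losslessly compress a cube onto mass segments
#'
#' Restriction of the raw cube to the concatenated segment bins at full
#' TDC resolution: within segments the compressed counts are identical to
#' the raw counts. The m/z map applies the quadratic calibration to the
#' bin-center time `t = (i - 0.5) * tof_bin` of each retained bin.
#'
#' @param raw a [RawSpectrumImage-class].
#' @param segments disjoint, sorted `IRanges` of retained segments.
#' @return A [CompressedSpectra-class].
#' @export
compressCube <- function(raw, segments) {
  nb <- nBins(raw@geom)
  if (length(segments)) {
    if (min(start(segments)) < 1L || max(end(segments)) > nb)
      stop("segment out of the raw bin range")
    if (length(segments) > 1L &&
        (is.unsorted(start(segments), strictly = TRUE) ||
         any(start(segments)[-1L] <= end(segments)[-length(segments)])))
      stop("segments must be sorted and disjoint")
  }
  cols <- as.integer(unlist(lapply(seq_along(segments), function(k)
    seq.int(start(segments)[k], end(segments)[k]))))
  ptSeg <- rep.int(seq_along(segments), width(segments))
  mat <- as.matrix(raw@counts[, cols, drop = FALSE])
  dimnames(mat) <- NULL
  mz <- if (length(cols)) massFromTof(.binCenterTime(cols, raw@geom), raw@geom)
        else numeric(0)
  new("CompressedSpectra", matrix = mat, indexMap = cols, mzMap = mz,
      segments = segments, pointSegment = as.integer(ptSeg),
      geom = raw@geom, nx = raw@nx, ny = raw@ny)
}

#' Scatter compressed spectra back onto the raw bin axis
#'
#' Inverse of [compressCube()] for the retained bins; all non-segment
#' bins are zero. Re-compressing the result is the identity.
#'
#' @param cs a [CompressedSpectra-class].
#' @return A [RawSpectrumImage-class].
#' @export
decompressCube <- function(cs) {
  nb <- nBins(cs@geom)
  npix <- cs@nx * cs@ny
  nz <- which(cs@matrix != 0, arr.ind = TRUE)
  counts <- sparseMatrix(i = nz[, 1L], j = cs@indexMap[nz[, 2L]],
                         x = cs@matrix[nz], dims = c(npix, nb))
  new("RawSpectrumImage", counts = counts, geom = cs@geom,
      nx = cs@nx, ny = cs@ny, metadata = "decompressCube")
}

#' Spatial map of a peak's area
#'
#' Per-pixel sum of counts inside one mass segment, optionally normalized
#' by the pixel's total counts (the classical per-peak imaging mode).
#' Pixels with zero total counts map to 0 and are flagged in the
#' `"valid"` attribute.
#'
#' @param data a [RawSpectrumImage-class] or [CompressedSpectra-class].
#' @param segment a single-range `IRanges` (raw-bin coordinates).
#' @param normalize divide by per-pixel total counts.
#' @return nx-by-ny numeric matrix with a logical `"valid"` attribute.
#' @export
peakMap <- function(data, segment, normalize = FALSE) {
  stopifnot(length(segment) == 1L)
  if (is(data, "RawSpectrumImage")) {
    nb <- nBins(data@geom)
    if (start(segment) < 1L || end(segment) > nb)
      stop("segment outside the raw bin axis")
    cols <- seq.int(start(segment), end(segment))
    v <- Matrix::rowSums(data@counts[, cols, drop = FALSE])
    tot <- Matrix::rowSums(data@counts)
  } else if (is(data, "CompressedSpectra")) {
    sel <- data@indexMap >= start(segment) & data@indexMap <= end(segment)
    if (!any(sel)) stop("segment contains no compressed points")
    v <- rowSums(data@matrix[, sel, drop = FALSE])
    tot <- rowSums(data@matrix)
  } else stop("unsupported data type")
  valid <- tot > 0
  if (normalize) {
    v <- ifelse(valid, v / tot, 0)
  }
  m <- matrix(as.numeric(v), nrow = data@nx)
  attr(m, "valid") <- matrix(valid, nrow = data@nx)
  m
}

#' Compressed-axis accessors
#'
#' `compressedMatrix()` returns the pixels-by-points matrix, `indexMap()`
#' the point-to-raw-bin map, `mzMap()` the point-to-m/z calibration curve
#' and `segmentTable()` the segment table as a data.frame (0-based
#' half-open `start_bin`/`end_bin` plus m/z bounds, the documented export
#' convention).
#'
#' @param cs a [CompressedSpectra-class].
#' @return See individual descriptions.
#' @name compressed-accessors
NULL

#' @rdname compressed-accessors
#' @export
compressedMatrix <- function(cs) cs@matrix

#' @rdname compressed-accessors
#' @export
indexMap <- function(cs) cs@indexMap

#' @rdname compressed-accessors
#' @export
mzMap <- function(cs) cs@mzMap

#' @rdname compressed-accessors
#' @export
segmentTable <- function(cs) {
  seg <- cs@segments
  geom <- cs@geom
  data.frame(
    start_bin = start(seg) - 1L,          # 0-based, inclusive
    end_bin = end(seg),                   # 0-based, exclusive
    start_mz = massFromTof(.binCenterTime(start(seg), geom), geom),
    end_mz = massFromTof(.binCenterTime(end(seg), geom), geom),
    total_counts = mcols(seg)$totalCounts,
    label = mcols(seg)$label,
    stringsAsFactors = FALSE
  )
}

#' Segments of a compressed cube
#' @param cs a [CompressedSpectra-class].
#' @return The `IRanges` of retained segments.
#' @export
cubeSegments <- function(cs) cs@segments
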