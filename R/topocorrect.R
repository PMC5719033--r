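## Reference-peak tracking, the per-pixel correction factor
## D(x,y) = T_ref^sub / T_ref(x,y), time-axis correction T' = T * D, and
## quantitative topography reconstruction from the reference shift.
##
## Because both the acceleration time and the total flight time scale as
## sqrt(m), the relative shift T(m,dh)/T(m,0) is mass-independent, so one
## reference-derived factor D corrects every species in the spectrum.

#' Track a reference peak's time of flight per pixel
#'
#' Computes, for each pixel, the intensity-weighted centroid of bin-center
#' times inside the reference segment. The centroid gives sub-bin
#' precision, which is what pushes the topographic height floor down to
#' the few-micrometre scale at 50 ps timing. Pixels with fewer than
#' `minCounts` counts in the segment are marked invalid and excluded from
#' all downstream statistics.
#'
#' @param data a [RawSpectrumImage-class] or [CompressedSpectra-class].
#' @param refSegment single-range `IRanges` containing the reference peak
#'   (raw-bin coordinates).
#' @param minCounts minimum counts per pixel for a valid track.
#' @param refSpecies optional [IonSpecies-class] recorded as provenance.
#' @return A [ReferenceTrack-class].
#' @export
trackReference <- function(data, refSegment, minCounts = 5,
                           refSpecies = ionSpecies("Cs")) {
  stopifnot(length(refSegment) == 1L)
  geom <- data@geom
  if (is(data, "RawSpectrumImage")) {
    cols <- seq.int(start(refSegment), end(refSegment))
    sub <- as.matrix(data@counts[, cols, drop = FALSE])
    bins <- cols
  } else if (is(data, "CompressedSpectra")) {
    sel <- data@indexMap >= start(refSegment) & data@indexMap <= end(refSegment)
    if (!any(sel)) stop("reference segment contains no compressed points")
    sub <- data@matrix[, sel, drop = FALSE]
    bins <- data@indexMap[sel]
  } else stop("unsupported data type")
  tot <- rowSums(sub)
  if (all(tot == 0))
    stop("reference segment is empty in every pixel")
  tctr <- .binCenterTime(bins, geom)
  tRef <- as.numeric(sub %*% tctr)
  valid <- tot >= minCounts & tot > 0
  tRef <- ifelse(valid, tRef / ifelse(tot > 0, tot, 1), 0)
  new("ReferenceTrack",
      tRef = matrix(tRef, nrow = data@nx),
      valid = matrix(valid, nrow = data@nx),
      refSpecies = refSpecies, refSegment = refSegment)
}

#' Estimate the substrate-level reference TOF
#'
#' With `percentile = 1` (the default rule) returns the maximum tracked
#' TOF over valid pixels: the substrate is the lowest surface, so its
#' ions fly longest. A `percentile < 1` returns that quantile instead, a
#' robust option for noisy data where the strict maximum is biased upward
#' by extreme centroid noise.
#'
#' @param track a [ReferenceTrack-class].
#' @param percentile fraction in (0, 1]; 1 = strict maximum.
#' @return Substrate reference TOF, seconds.
#' @export
estimateSubstrateTof <- function(track, percentile = 1.0) {
  v <- track@tRef[track@valid]
  if (!length(v)) stop("no valid pixels in the reference track")
  if (percentile >= 1) max(v)
  else as.numeric(stats::quantile(v, percentile, names = FALSE, type = 7))
}

#' Per-pixel correction factor D(x,y)
#'
#' `D = t_ref_sub / t_ref` on valid pixels; invalid pixels get D = 1,
#' dT = 0 and stay flagged so they pass through later stages unchanged.
#'
#' @param track a [ReferenceTrack-class].
#' @param tRefSub substrate-level reference TOF, seconds (> 0), e.g. from
#'   [estimateSubstrateTof()].
#' @return A [CorrectionField-class].
#' @export
correctionField <- function(track, tRefSub) {
  if (tRefSub <= 0) stop("tRefSub must be positive")
  v <- track@valid
  D <- ifelse(v, tRefSub / ifelse(track@tRef > 0, track@tRef, 1), 1)
  dT <- ifelse(v, tRefSub - track@tRef, 0)
  new("CorrectionField", D = D, tRefSub = tRefSub, dT = dT, valid = v)
}

## Redistribute counts after scaling each input bin's time support
## [t_i, t_{i+1}) by the per-pixel factor D: overlap-proportional linear
## rebinning onto the output grid, count-conserving. `px`, `bin`, `x` are
## parallel triplets (1-based raw bins); returns new triplets plus the
## number of counts that fell off the axis.
.rebinScaled <- function(px, bin, x, Dpix, nb) {
  if (!length(px))
    return(list(px = integer(0), bin = integer(0), x = numeric(0), lost = 0))
  D <- Dpix[px]
  s <- (bin - 1) * D                     # scaled support, bin units, 0-based
  e <- bin * D
  j0 <- floor(s)
  span <- max(ceiling(e - j0))           # bins any interval can touch
  outp <- integer(0); outb <- numeric(0); outx <- numeric(0)
  for (k in seq_len(span) - 1) {
    j <- j0 + k
    ov <- pmax(0, pmin(e, j + 1) - pmax(s, j))
    sel <- ov > 0
    if (!any(sel)) next
    outp <- c(outp, px[sel])
    outb <- c(outb, j[sel] + 1)          # back to 1-based
    outx <- c(outx, x[sel] * ov[sel] / (e[sel] - s[sel]))
  }
  keep <- outb >= 1 & outb <= nb
  lost <- sum(outx[!keep])
  list(px = outp[keep], bin = as.integer(outb[keep]), x = outx[keep],
       lost = lost)
}

## Largest-remainder rounding of v to integers preserving round(sum(v)).
.largestRemainder <- function(v) {
  fl <- floor(v)
  need <- round(sum(v)) - sum(fl)
  if (need > 0) {
    ord <- order(v - fl, decreasing = TRUE)
    fl[ord[seq_len(need)]] <- fl[ord[seq_len(need)]] + 1
  }
  fl
}

#' Apply a topographic correction field to a cube
#'
#' Scales each pixel's time axis by its correction factor D: every bin's
#' time support `[t_i, t_{i+1})` maps to `[t_i D, t_{i+1} D)` and its
#' counts are redistributed onto the output bin grid proportionally to
#' overlap length (count-conserving linear rebinning). Invalid pixels
#' pass through unchanged. For compressed data, counts pushed outside the
#' retained segments (or, for raw data, beyond the acquisition window)
#' are dropped, counted in the `"lostCounts"` attribute, and reported
#' with a warning.
#'
#' @param data a [RawSpectrumImage-class] or [CompressedSpectra-class].
#' @param field a [CorrectionField-class] on the same grid.
#' @param integerCounts keep counts integral per pixel via
#'   largest-remainder rounding (per-pixel totals preserved exactly);
#'   default `FALSE` keeps the exact fractional redistribution.
#' @return An object of the same class as `data`.
#' @export
applyCorrection <- function(data, field, integerCounts = FALSE) {
  if (!all(dim(field@D) == c(data@nx, data@ny)))
    stop("correction field grid does not match the data grid")
  Dpix <- as.vector(field@D)
  Dpix[!as.vector(field@valid)] <- 1
  nb <- nBins(data@geom)

  if (is(data, "RawSpectrumImage")) {
    tri <- Matrix::summary(data@counts)
    rb <- .rebinScaled(tri$i, tri$j, tri$x, Dpix, nb)
    agg <- .aggTriplets(rb$px, rb$bin, rb$x)
    if (integerCounts)
      agg$x <- .roundPerPixel(agg$px, agg$x)
    out <- sparseMatrix(i = agg$px, j = agg$bin, x = agg$x,
                        dims = dim(data@counts))
    res <- new("RawSpectrumImage", counts = out, geom = data@geom,
               nx = data@nx, ny = data@ny,
               metadata = c(data@metadata, "applyCorrection"))
  } else if (is(data, "CompressedSpectra")) {
    nz <- which(data@matrix != 0, arr.ind = TRUE)
    rb <- .rebinScaled(nz[, 1L], data@indexMap[nz[, 2L]], data@matrix[nz],
                       Dpix, nb)
    ## map output raw bins back onto the compressed axis
    col <- match(rb$bin, data@indexMap)
    outside <- is.na(col)
    lostSeg <- sum(rb$x[outside])
    rb$lost <- rb$lost + lostSeg
    mat <- matrix(0, nrow = nrow(data@matrix), ncol = ncol(data@matrix))
    if (any(!outside)) {
      idx <- cbind(rb$px[!outside], col[!outside])
      agg <- .aggTriplets(idx[, 1L], idx[, 2L], rb$x[!outside])
      if (integerCounts)
        agg$x <- .roundPerPixel(agg$px, agg$x)
      mat[cbind(agg$px, agg$bin)] <- agg$x
    }
    res <- new("CompressedSpectra", matrix = mat, indexMap = data@indexMap,
               mzMap = data@mzMap, segments = data@segments,
               pointSegment = data@pointSegment, geom = data@geom,
               nx = data@nx, ny = data@ny)
  } else stop("unsupported data type")

  if (rb$lost > 0.5)
    warning(sprintf("correction dropped %.6g counts outside the retained axis",
                    rb$lost))
  attr(res, "lostCounts") <- rb$lost
  res
}

.aggTriplets <- function(px, bin, x) {
  if (!length(px)) return(list(px = integer(0), bin = integer(0), x = numeric(0)))
  key <- paste(px, bin)
  first <- !duplicated(key)
  xs <- rowsum(x, key, reorder = FALSE)
  list(px = px[first], bin = bin[first], x = as.numeric(xs))
}

.roundPerPixel <- function(px, x) {
  out <- x
  for (p in unique(px)) {
    sel <- px == p
    out[sel] <- .largestRemainder(x[sel])
  }
  out
}

#' Reconstruct surface topography from the reference shift
#'
#' Closed-form inversion of the shift law: with `t_ac(0)` the
#' substrate-level acceleration time of the reference ion (estimated from
#' the instrument geometry; it cannot be measured directly),
#' \deqn{\Delta h = h_{ex}\bigl(1 - ((t_{ac}(0) - \Delta T)/t_{ac}(0))^2\bigr).}
#' Tiny negative shifts (within one TDC bin, centroid noise) clamp to 0;
#' shifts at or beyond `t_ac(0)` are unphysical and invalidate the pixel.
#'
#' @param field a [CorrectionField-class].
#' @param ref reference [IonSpecies-class] (its mass sets t_ac(0)).
#' @param geom an [InstrumentGeometry-class].
#' @return A [TopographyMap-class].
#' @export
reconstructTopography <- function(field, ref = ionSpecies("Cs"),
                                  geom = instrumentGeometry()) {
  tac0 <- accelerationTime(ref@mass, geom, 0)
  dT <- field@dT
  valid <- field@valid
  bad <- valid & (dT >= tac0)
  if (any(bad)) {
    warning(sprintf("%d pixel(s) with unphysical shift >= t_ac(0) invalidated",
                    sum(bad)))
    valid[bad] <- FALSE
  }
  dT <- pmax(dT, 0)                      # clamp centroid-noise negatives
  dT[!valid] <- 0
  dh <- geom@h_ex * (1 - ((tac0 - dT) / tac0)^2)
  dh[!valid] <- 0
  new("TopographyMap", dh = dh, valid = valid, refSpecies = ref, geom = geom)
}

#' Accessors for correction and topography objects
#'
#' `heightMap()` returns the reconstructed height matrix (meters),
#' `correctionFactor()` the D(x,y) matrix, `referenceTof()` the tracked
#' per-pixel reference TOF, and `validMask()` the validity mask of any of
#' these objects.
#'
#' @param x a [TopographyMap-class], [CorrectionField-class] or
#'   [ReferenceTrack-class].
#' @return A numeric or logical nx-by-ny matrix.
#' @name topo-accessors
NULL

#' @rdname topo-accessors
#' @export
heightMap <- function(x) x@dh

#' @rdname topo-accessors
#' @export
correctionFactor <- function(x) x@D

#' @rdname topo-accessors
#' @export
referenceTof <- function(x) x@tRef

#' @rdname topo-accessors
#' @export
validMask <- function(x) x@valid

#' Line profile across a map
#'
#' Extracts one row (fixed y) of a map as a two-column data.frame of
#' position (meters) versus value, the standard way to present a
#' topography cross-section.
#'
#' @param map nx-by-ny numeric matrix (e.g. [heightMap()]).
#' @param y row index (1-based); default the middle row.
#' @param pixelPitch pixel pitch in meters.
#' @return data.frame with columns `x` (m) and `value`.
#' @export
lineProfile <- function(map, y = ceiling(ncol(map) / 2),
                        pixelPitch = 500e-6 / 256) {
  data.frame(x = (seq_len(nrow(map)) - 1) * pixelPitch, value = map[, y])
}
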