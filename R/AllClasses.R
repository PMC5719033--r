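#' @import methods
#' @importFrom Matrix sparseMatrix colSums rowSums
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors mcols mcols<-
NULL

## Physical constants (SI)
.UAMU <- 1.66053906660e-27   # unified atomic mass unit, kg
.ECHARGE <- 1.602176634e-19  # elementary charge, C

#' Monoisotopic and conventional ion masses (u)
#'
#' Named constants for the ion species used throughout: monoisotopic
#' masses for spectral peaks, plus the standard atomic weight of
#' potassium, which reproduces the conventional ~30.2 ns acceleration
#' time of K+ in a 2 kV / 1.5 mm extraction gap.
#'
#' @format Named numeric vector of masses in unified atomic mass units.
#' @export
ionMasses <- c(
  K   = 38.9637,   # 39K monoisotopic
  K_atomic = 39.098, # standard atomic weight of potassium
  Na  = 22.9898,
  Mg  = 23.9850,
  Ca  = 39.9626,
  Si  = 27.9769,
  Si2 = 55.9539,
  Cs  = 132.9055,
  Cs2 = 265.8109
)

# ---------------------------------------------------------------------------
# InstrumentGeometry
# ---------------------------------------------------------------------------

#' InstrumentGeometry: reflectron ToF-SIMS extraction geometry and calibration
#'
#' Holds the extraction-gap parameters and the time-of-flight calibration
#' anchor shared by the physics, simulator, compression and correction
#' layers. All fields are SI (seconds, meters, volts); ion masses are in
#' unified atomic mass units and converted at the physics boundary.
#'
#' @slot U_ex extractor potential, volts.
#' @slot h_ex sample-extractor gap, meters.
#' @slot T_cal total substrate-level time of flight of the calibration ion,
#'   seconds.
#' @slot m_cal calibration ion mass, u.
#' @slot tof_bin detector (TDC) bin width, seconds.
#' @slot t_window acquisition window, seconds.
#' @slot H_ef effective flight path, meters (informational).
#' @slot z ion charge state, elementary charges (fixed 1).
#' @export
setClass("InstrumentGeometry",
  representation(
    U_ex = "numeric", h_ex = "numeric", T_cal = "numeric",
    m_cal = "numeric", tof_bin = "numeric", t_window = "numeric",
    H_ef = "numeric", z = "numeric"
  )
)

setValidity("InstrumentGeometry", function(object) {
  msg <- character()
  for (f in c("U_ex", "h_ex", "T_cal", "m_cal", "tof_bin", "t_window", "H_ef", "z")) {
    v <- slot(object, f)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", f))
  }
  if (length(msg)) return(msg)
  if (object@tof_bin >= object@t_window)
    msg <- c(msg, "tof_bin must be smaller than t_window")
  if (object@T_cal >= object@t_window)
    msg <- c(msg, "T_cal must fall inside the acquisition window")
  if (object@z != 1)
    msg <- c(msg, "only singly charged ions are modelled (z = 1)")
  tac <- sqrt(2 * object@h_ex^2 * object@m_cal * .UAMU /
                (object@U_ex * .ECHARGE))
  if (tac >= object@T_cal)
    msg <- c(msg, "acceleration time must be a small fraction of T_cal")
  if (length(msg)) msg else TRUE
})

#' Construct an instrument geometry
#'
#' Defaults describe a 2 kV extractor across a 1.5 mm gap with a 50 ps
#' time-to-digital converter over a 100 us window, calibrated on the K+
#' peak at 20.545 us.
#'
#' @param U_ex extractor potential (V).
#' @param h_ex sample-extractor gap (m).
#' @param T_cal substrate-level TOF of the calibration ion (s).
#' @param m_cal calibration ion mass (u).
#' @param tof_bin TDC bin width (s).
#' @param t_window acquisition window (s).
#' @param H_ef effective flight path (m), informational.
#' @return An [InstrumentGeometry-class] object.
#' @examples
#' geom <- instrumentGeometry()
#' nBins(geom)
#' @export
instrumentGeometry <- function(U_ex = 2000, h_ex = 1.5e-3,
                               T_cal = 20.545e-6, m_cal = ionMasses[["K"]],
                               tof_bin = 50e-12, t_window = 100e-6,
                               H_ef = 2.0) {
  new("InstrumentGeometry", U_ex = U_ex, h_ex = h_ex, T_cal = T_cal,
      m_cal = m_cal, tof_bin = tof_bin, t_window = t_window,
      H_ef = H_ef, z = 1)
}

#' Number of raw TDC bins in the acquisition window
#' @param geom an [InstrumentGeometry-class].
#' @return Integer bin count, `round(t_window / tof_bin)`.
#' @export
nBins <- function(geom) as.integer(round(geom@t_window / geom@tof_bin))

setMethod("show", "InstrumentGeometry", function(object) {
  cat("InstrumentGeometry\n")
  cat(sprintf("  extractor: %g V over %g mm gap\n",
              object@U_ex, object@h_ex * 1e3))
  cat(sprintf("  calibration: m = %.4f u at T = %.6g us\n",
              object@m_cal, object@T_cal * 1e6))
  cat(sprintf("  TDC: %g ps bins, %g us window (%d bins)\n",
              object@tof_bin * 1e12, object@t_window * 1e6, nBins(object)))
})

# ---------------------------------------------------------------------------
# IonSpecies
# ---------------------------------------------------------------------------

#' IonSpecies: a labelled singly charged ion
#'
#' @slot label species label, e.g. "Cs".
#' @slot mass monoisotopic mass, u.
#' @slot charge charge state in elementary charges (fixed 1).
#' @export
setClass("IonSpecies",
  representation(label = "character", mass = "numeric", charge = "numeric"))

setValidity("IonSpecies", function(object) {
  if (length(object@mass) != 1L || !is.finite(object@mass) || object@mass <= 0)
    return("mass must be a single positive number (u)")
  if (object@charge != 1) return("only singly charged ions are modelled")
  TRUE
})

#' Construct an ion species
#' @param label species label.
#' @param mass monoisotopic mass in u; defaults to `ionMasses[label]` when
#'   the label is known.
#' @return An [IonSpecies-class].
#' @examples
#' ionSpecies("Cs")
#' ionSpecies("org1", 166.0)
#' @export
ionSpecies <- function(label, mass = ionMasses[[label]]) {
  new("IonSpecies", label = as.character(label), mass = mass, charge = 1)
}

setMethod("show", "IonSpecies", function(object) {
  cat(sprintf("IonSpecies %s+ (%.4f u)\n", object@label, object@mass))
})

# ---------------------------------------------------------------------------
# Simulator scene types
# ---------------------------------------------------------------------------

#' SpeciesLayer: one chemical component of a synthetic scene
#'
#' @slot species the [IonSpecies-class].
#' @slot meanYield expected counts per pixel at unit abundance.
#' @slot abundance nx-by-ny abundance map in [0, 1] (x is the first,
#'   fastest-varying dimension).
#' @export
setClass("SpeciesLayer",
  representation(species = "IonSpecies", meanYield = "numeric",
                 abundance = "matrix"))

setValidity("SpeciesLayer", function(object) {
  if (object@meanYield < 0) return("meanYield must be >= 0")
  a <- object@abundance
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    return("abundance values must lie in [0, 1]")
  TRUE
})

#' @rdname SpeciesLayer-class
#' @param species an [IonSpecies-class].
#' @param meanYield expected counts/pixel at unit abundance.
#' @param abundance nx-by-ny matrix in [0,1].
#' @export
speciesLayer <- function(species, meanYield, abundance) {
  new("SpeciesLayer", species = species, meanYield = meanYield,
      abundance = abundance)
}

#' SyntheticScene: ground-truth topography and composition
#'
#' A pixel grid with a known height map and a list of species layers;
#' the forward simulator renders it into a raw time-of-flight cube.
#'
#' @slot nx,ny grid size (x fastest).
#' @slot pixelPitch pixel pitch, meters.
#' @slot topography nx-by-ny height map dh, meters.
#' @slot layers list of [SpeciesLayer-class].
#' @slot resolutionR instrument mass resolving power m/dm.
#' @slot seed integer RNG seed for stochastic rendering.
#' @export
setClass("SyntheticScene",
  representation(nx = "integer", ny = "integer", pixelPitch = "numeric",
                 topography = "matrix", layers = "list",
                 resolutionR = "numeric", seed = "integer"))

setValidity("SyntheticScene", function(object) {
  if (!all(dim(object@topography) == c(object@nx, object@ny)))
    return("topography must be an nx-by-ny matrix")
  if (any(object@topography < 0))
    return("topography heights must be non-negative")
  if (object@resolutionR < 500 || object@resolutionR > 50000)
    return("resolutionR outside the sane range [500, 50000]")
  for (l in object@layers) {
    if (!is(l, "SpeciesLayer")) return("layers must be SpeciesLayer objects")
    if (!all(dim(l@abundance) == c(object@nx, object@ny)))
      return(sprintf("abundance grid of layer '%s' does not match the scene grid",
                     l@species@label))
  }
  TRUE
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene %d x %d px (pitch %.3g um), %d layers\n",
              object@nx, object@ny, object@pixelPitch * 1e6,
              length(object@layers)))
  cat(sprintf("  max height %.3g um, m/dm = %g, seed %d\n",
              max(object@topography) * 1e6, object@resolutionR, object@seed))
  cat("  species:", paste(vapply(object@layers,
        function(l) l@species@label, ""), collapse = ", "), "\n")
})

#' RawSpectrumImage: per-pixel time-of-flight histograms on a 2-D grid
#'
#' Counts are held as a sparse pixels-by-bins matrix; pixel order is
#' row-major with x fastest, so pixel (ix, iy) (1-based) is row
#' ix + (iy-1)*nx.
#'
#' @slot counts dgCMatrix, n_pixels x n_bins, non-negative integers.
#' @slot geom the [InstrumentGeometry-class].
#' @slot nx,ny grid size.
#' @slot metadata provenance strings.
#' @export
setClass("RawSpectrumImage",
  representation(counts = "dgCMatrix", geom = "InstrumentGeometry",
                 nx = "integer", ny = "integer", metadata = "character"))

setValidity("RawSpectrumImage", function(object) {
  if (nrow(object@counts) != object@nx * object@ny)
    return("counts must have nx*ny rows")
  if (ncol(object@counts) != nBins(object@geom))
    return("counts must have round(t_window/tof_bin) columns")
  x <- object@counts@x
  if (length(x) && (any(x < 0) || any(abs(x - round(x)) > 1e-9)))
    return("counts must be non-negative integers")
  TRUE
})

setMethod("show", "RawSpectrumImage", function(object) {
  cat(sprintf("RawSpectrumImage %d x %d px, %d raw bins, %d total counts\n",
              object@nx, object@ny, ncol(object@counts),
              as.integer(sum(object@counts))))
})

# ---------------------------------------------------------------------------
# Compression types
# ---------------------------------------------------------------------------

#' CompressedSpectra: cube restricted to informative mass segments
#'
#' Lossless restriction of a raw cube onto concatenated above-threshold
#' mass segments, at full TDC resolution, with the point-index to raw-bin
#' and point-index to m/z calibration maps.
#'
#' @slot matrix dense n_pixels x n_points count matrix.
#' @slot indexMap integer vector: point index -> raw bin (1-based).
#' @slot mzMap numeric vector: point index -> m/z.
#' @slot segments an `IRanges` of retained segments (1-based, closed) with
#'   metadata columns `totalCounts` and `label`.
#' @slot pointSegment integer vector: point index -> segment number.
#' @slot geom the [InstrumentGeometry-class].
#' @slot nx,ny grid size.
#' @export
setClass("CompressedSpectra",
  representation(matrix = "matrix", indexMap = "integer", mzMap = "numeric",
                 segments = "IRanges", pointSegment = "integer",
                 geom = "InstrumentGeometry", nx = "integer", ny = "integer"))

setValidity("CompressedSpectra", function(object) {
  n <- ncol(object@matrix)
  if (length(object@indexMap) != n || length(object@mzMap) != n ||
      length(object@pointSegment) != n)
    return("indexMap, mzMap and pointSegment must have one entry per point")
  if (n && is.unsorted(object@indexMap, strictly = TRUE))
    return("indexMap must be strictly increasing")
  if (n != sum(width(object@segments)))
    return("n_points must equal the summed segment widths")
  if (nrow(object@matrix) != object@nx * object@ny)
    return("matrix must have nx*ny rows")
  TRUE
})

setMethod("show", "CompressedSpectra", function(object) {
  cat(sprintf("CompressedSpectra %d x %d px, %d points in %d segments (of %d raw bins)\n",
              object@nx, object@ny, ncol(object@matrix),
              length(object@segments), nBins(object@geom)))
})

# ---------------------------------------------------------------------------
# Topography correction types
# ---------------------------------------------------------------------------

#' ReferenceTrack: per-pixel reference-peak time of flight
#'
#' @slot tRef nx-by-ny map of reference-peak TOF centroids, seconds.
#' @slot valid nx-by-ny logical mask; invalid pixels carry no statistics.
#' @slot refSpecies the reference [IonSpecies-class] (may be a placeholder
#'   when tracked from an unlabelled segment).
#' @slot refSegment the `IRanges` segment that was tracked.
#' @export
setClass("ReferenceTrack",
  representation(tRef = "matrix", valid = "matrix",
                 refSpecies = "IonSpecies", refSegment = "IRanges"))

setValidity("ReferenceTrack", function(object) {
  if (!all(dim(object@tRef) == dim(object@valid)))
    return("tRef and valid must have identical dimensions")
  if (any(object@tRef[object@valid] <= 0))
    return("tRef must be positive on valid pixels")
  TRUE
})

setMethod("show", "ReferenceTrack", function(object) {
  v <- object@valid
  cat(sprintf("ReferenceTrack (%s+): %d x %d px, %d/%d valid\n",
              object@refSpecies@label, nrow(v), ncol(v), sum(v), length(v)))
  if (any(v))
    cat(sprintf("  t_ref range %.6g - %.6g us\n",
                min(object@tRef[v]) * 1e6, max(object@tRef[v]) * 1e6))
})

#' CorrectionField: per-pixel topographic correction factor D(x,y)
#'
#' D multiplies all of a pixel's flight times to restore substrate-level
#' times; dT is the reference-peak shift relative to the substrate.
#'
#' @slot D nx-by-ny dimensionless correction factor.
#' @slot tRefSub substrate-level reference TOF, seconds.
#' @slot dT nx-by-ny map of reference shifts, seconds.
#' @slot valid logical mask.
#' @export
setClass("CorrectionField",
  representation(D = "matrix", tRefSub = "numeric", dT = "matrix",
                 valid = "matrix"))

setValidity("CorrectionField", function(object) {
  if (!all(dim(object@D) == dim(object@dT)) ||
      !all(dim(object@D) == dim(object@valid)))
    return("D, dT and valid must share dimensions")
  if (length(object@tRefSub) != 1L || object@tRefSub <= 0)
    return("tRefSub must be a single positive time")
  TRUE
})

setMethod("show", "CorrectionField", function(object) {
  v <- object@valid
  cat(sprintf("CorrectionField %d x %d px, t_ref^sub = %.6g us\n",
              nrow(v), ncol(v), object@tRefSub * 1e6))
  if (any(v))
    cat(sprintf("  D range %.8g - %.8g (%d valid px)\n",
                min(object@D[v]), max(object@D[v]), sum(v)))
})

#' TopographyMap: surface height reconstructed from spectral shifts
#'
#' @slot dh nx-by-ny height map, meters.
#' @slot valid logical mask.
#' @slot refSpecies reference ion used.
#' @slot geom geometry used for the acceleration-time estimate.
#' @export
setClass("TopographyMap",
  representation(dh = "matrix", valid = "matrix",
                 refSpecies = "IonSpecies", geom = "InstrumentGeometry"))

setValidity("TopographyMap", function(object) {
  if (!all(dim(object@dh) == dim(object@valid)))
    return("dh and valid must share dimensions")
  d <- object@dh[object@valid]
  if (length(d) && (any(d < 0) || any(d >= object@geom@h_ex)))
    return("valid heights must satisfy 0 <= dh < h_ex")
  TRUE
})

setMethod("show", "TopographyMap", function(object) {
  v <- object@valid
  cat(sprintf("TopographyMap %d x %d px (%s+ reference), %d valid\n",
              nrow(v), ncol(v), object@refSpecies@label, sum(v)))
  if (any(v))
    cat(sprintf("  height range %.3g - %.3g um\n",
                min(object@dh[v]) * 1e6, max(object@dh[v]) * 1e6))
})

# ---------------------------------------------------------------------------
# MVA types
# ---------------------------------------------------------------------------

#' SpectraMatrix: pixels-by-points matrix prepared for decomposition
#'
#' @slot matrix n_pixels x n_points intensities.
#' @slot included logical point-inclusion mask; excluded points carry no
#'   influence on any decomposition.
#' @slot mzMap point index -> m/z.
#' @slot nx,ny grid size.
#' @export
setClass("SpectraMatrix",
  representation(matrix = "matrix", included = "logical", mzMap = "numeric",
                 nx = "integer", ny = "integer"))

setValidity("SpectraMatrix", function(object) {
  if (length(object@included) != ncol(object@matrix))
    return("inclusion mask length must equal n_points")
  if (length(object@mzMap) != ncol(object@matrix))
    return("mzMap length must equal n_points")
  if (!any(object@included))
    return("all points excluded: empty matrix")
  if (nrow(object@matrix) != object@nx * object@ny)
    return("matrix must have nx*ny rows")
  TRUE
})

setMethod("show", "SpectraMatrix", function(object) {
  cat(sprintf("SpectraMatrix %d px x %d points (%d included)\n",
              nrow(object@matrix), ncol(object@matrix), sum(object@included)))
})

#' PCAResult: principal components of an image spectra matrix
#'
#' @slot eigenvectors n_included_points x k matrix, orthonormal columns.
#' @slot loadings n_pixels x k projection coefficients.
#' @slot explainedVariance fractions for all singular values (sums to 1);
#'   the first k belong to the retained components.
#' @slot centered whether the matrix was mean-centered first.
#' @slot center the column means subtracted (length n_included, or 0).
#' @slot includedIdx indices of included points in the parent matrix.
#' @slot mzIncluded m/z of the included points.
#' @slot nx,ny grid size.
#' @export
setClass("PCAResult",
  representation(eigenvectors = "matrix", loadings = "matrix",
                 explainedVariance = "numeric", centered = "logical",
                 center = "numeric", includedIdx = "integer",
                 mzIncluded = "numeric", nx = "integer", ny = "integer"))

setValidity("PCAResult", function(object) {
  k <- ncol(object@eigenvectors)
  if (ncol(object@loadings) != k)
    return("loadings and eigenvectors must agree on component count")
  ev <- object@explainedVariance
  if (length(ev) && is.unsorted(rev(sort(ev, decreasing = TRUE))))
    return("explainedVariance must be sortable")  # ordering checked below
  if (length(ev) > 1 && any(diff(ev) > 1e-12))
    return("explainedVariance must be non-increasing")
  if (sum(ev) > 1 + 1e-8)
    return("explainedVariance fractions must sum to <= 1")
  g <- crossprod(object@eigenvectors)
  if (max(abs(g - diag(k))) > 1e-8)
    return("eigenvectors must be orthonormal")
  TRUE
})

setMethod("show", "PCAResult", function(object) {
  k <- ncol(object@eigenvectors)
  cat(sprintf("PCAResult: %d components over %d points (%scentered)\n",
              k, nrow(object@eigenvectors),
              if (object@centered) "" else "un"))
  cat("  explained variance:",
      paste(sprintf("%.3g", object@explainedVariance[seq_len(min(k, 6))]),
            collapse = ", "), "\n")
})
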