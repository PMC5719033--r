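## Forward simulator: renders a SyntheticScene with known topography and
## composition into a raw time-of-flight cube, so every downstream stage
## (compression, correction, topography reconstruction, PCA) can be tested
## against ground truth.

## TDC quantization: floor to the 50 ps grid (a time-to-digital converter
## truncates). The 1e-9-bin guard keeps exact integer time/bin ratios such
## as the 20.545 us anchor stable against floating-point representation;
## it corresponds to ~5e-21 s and is physically nil. Returns 1-based bins.
.quantBin <- function(t, geom) {
  as.integer(floor(t / geom@tof_bin + 1e-9)) + 1L
}

## Bin-center time of a 1-based raw bin: t = (i - 0.5) * tof_bin.
.binCenterTime <- function(bin, geom) {
  (bin - 0.5) * geom@tof_bin
}

#' Default species palette of the root-on-substrate scene
#'
#' Substrate species (Si, Si2) are confined to the bare substrate, the
#' alkali/alkaline-earth ions and three organics to the root footprint,
#' and the implanted sputter ions (Cs, Cs2) cover the whole field with
#' Cs+ globally the most intense peak. Yields are expected counts per
#' pixel at unit abundance.
#'
#' @return A data.frame with columns `label`, `mass`, `yield`, `where`.
#' @export
defaultSpeciesTable <- function() {
  data.frame(
    label = c("Si", "Si2", "Na", "Mg", "K", "Ca",
              "org1", "org2", "org3", "Cs", "Cs2"),
    mass  = c(ionMasses[["Si"]], ionMasses[["Si2"]], ionMasses[["Na"]],
              ionMasses[["Mg"]], ionMasses[["K"]], ionMasses[["Ca"]],
              166.0, 212.0, 255.0,
              ionMasses[["Cs"]], ionMasses[["Cs2"]]),
    yield = c(20, 5, 40, 20, 100, 30, 15, 12, 10, 200, 50),
    where = c("substrate", "substrate", "root", "root", "root", "root",
              "root", "root", "root", "everywhere", "everywhere"),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic root-on-substrate scene
#'
#' Emulates a dried cylindrical root lying on a flat substrate: the
#' topography is a half-cylinder ridge along y, dh = height *
#' sqrt(1 - (2d/w)^2) within the footprint (d = distance from the
#' centerline, w = footprint width) and 0 outside. Species placement
#' follows [defaultSpeciesTable()].
#'
#' @param nx,ny grid size in pixels (x fastest; default 256 x 256).
#' @param height maximum ridge height, meters (default 200 um).
#' @param rootWidthPx footprint width in pixels. The default, 0.8*nx,
#'   is the geometrically consistent width of a semicircular cross
#'   section of 200 um radius on a 500 um field (width = 2*height).
#' @param pixelPitch pixel pitch, meters (default: a 500 um field
#'   divided by nx).
#' @param resolutionR mass resolving power m/dm (default 7000).
#' @param seed RNG seed for stochastic rendering.
#' @param species species table as from [defaultSpeciesTable()].
#' @param geom geometry used only to validate dh < h_ex.
#' @return A [SyntheticScene-class].
#' @examples
#' sc <- makeRootScene(nx = 32, ny = 32, seed = 7)
#' max(topography(sc)) # 200 um
#' @export
makeRootScene <- function(nx = 256L, ny = 256L, height = 200e-6,
                          rootWidthPx = as.integer(round(0.8 * nx)),
                          pixelPitch = 500e-6 / nx, resolutionR = 7000,
                          seed = 1L, species = defaultSpeciesTable(),
                          geom = instrumentGeometry()) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (height < 0 || height >= geom@h_ex)
    stop("root height must satisfy 0 <= height < h_ex")
  if (rootWidthPx > nx)
    stop("root footprint wider than the grid")
  cx <- (nx - 1) / 2                     # centerline, 0-based coordinates
  d <- abs(seq_len(nx) - 1 - cx)         # distance from centerline, px
  inside <- d <= rootWidthPx / 2
  prof <- numeric(nx)
  prof[inside] <- height * sqrt(pmax(0, 1 - (2 * d[inside] / rootWidthPx)^2))
  topo <- matrix(rep(prof, ny), nrow = nx)
  rootMask <- matrix(rep(as.numeric(inside), ny), nrow = nx)

  layers <- lapply(seq_len(nrow(species)), function(i) {
    ab <- switch(species$where[i],
      substrate  = 1 - rootMask,
      root       = rootMask,
      everywhere = matrix(1, nx, ny),
      stop("unknown placement '", species$where[i], "'"))
    speciesLayer(ionSpecies(species$label[i], species$mass[i]),
                 species$yield[i], ab)
  })
  new("SyntheticScene", nx = nx, ny = ny, pixelPitch = pixelPitch,
      topography = topo, layers = layers, resolutionR = resolutionR,
      seed = as.integer(seed))
}

#' @describeIn makeRootScene Accessor for the ground-truth height map.
#' @param scene a [SyntheticScene-class].
#' @export
topography <- function(scene) scene@topography

#' Logical root-footprint mask of a root scene
#' @param scene a [SyntheticScene-class] built by [makeRootScene()].
#' @return nx-by-ny logical matrix, TRUE inside the root footprint.
#' @export
rootMask <- function(scene) scene@topography > 0 |
  .firstRootAbundance(scene) > 0

.firstRootAbundance <- function(scene) {
  for (l in scene@layers)
    if (l@species@label == "K") return(l@abundance)
  matrix(0, scene@nx, scene@ny)
}

#' Render a scene into a raw time-of-flight cube
#'
#' For each pixel and species layer the expected count is
#' `lambda = meanYield * abundance`, and the arrival-time centroid is
#' `totalTof(mass, dh)`. In stochastic mode counts are Poisson(lambda)
#' and each ion receives Gaussian timing jitter with
#' `sigma_t = T / (2 R * 2.3548)` (the FWHM mass resolution m/dm = R
#' mapped to time via dt/t = dm/2m); times are floor-quantized to the
#' TDC grid. In noiseless mode `round(lambda)` counts are deposited at
#' the quantized centroid bin with no jitter, which is fully
#' deterministic.
#'
#' @param scene a [SyntheticScene-class].
#' @param geom an [InstrumentGeometry-class].
#' @param noiseless logical; deterministic delta-peak mode.
#' @param seed RNG seed; defaults to the scene's own seed.
#' @return A [RawSpectrumImage-class].
#' @examples
#' sc <- makeRootScene(nx = 16, ny = 16, seed = 3)
#' raw <- renderScene(sc, noiseless = TRUE)
#' @export
renderScene <- function(scene, geom = instrumentGeometry(),
                        noiseless = FALSE, seed = scene@seed) {
  validObject(scene)
  if (max(scene@topography) >= geom@h_ex)
    stop("scene topography reaches the extraction gap (dh >= h_ex)")
  npix <- scene@nx * scene@ny
  nb <- nBins(geom)
  if (!noiseless) set.seed(as.integer(seed))

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  dh <- as.vector(scene@topography)   # pixel order: x fastest
  for (l in scene@layers) {
    lam <- l@meanYield * as.vector(l@abundance)
    tof <- totalTof(l@species@mass, dh, geom)
    if (any(tof >= geom@t_window))
      stop(sprintf("species '%s' centroid lies beyond the acquisition window",
                   l@species@label))
    if (noiseless) {
      n <- round(lam)
      keep <- n > 0
      if (!any(keep)) next
      ii <- c(ii, which(keep))
      jj <- c(jj, .quantBin(tof[keep], geom))
      xx <- c(xx, n[keep])
    } else {
      n <- stats::rpois(npix, lam)
      tot <- sum(n)
      if (tot == 0) next
      px <- rep.int(seq_len(npix), n)
      sigma <- tof / (2 * scene@resolutionR * 2.3548)
      t <- rep.int(tof, n) + stats::rnorm(tot, 0, rep.int(sigma, n))
      b <- .quantBin(t, geom)
      keep <- b >= 1L & b <= nb
      ii <- c(ii, px[keep]); jj <- c(jj, b[keep])
      xx <- c(xx, rep.int(1, sum(keep)))
    }
  }
  counts <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(npix, nb))
  new("RawSpectrumImage", counts = counts, geom = geom,
      nx = scene@nx, ny = scene@ny,
      metadata = sprintf("renderScene(noiseless=%s, seed=%d, R=%g)",
                         noiseless, as.integer(seed), scene@resolutionR))
}

#' Grid dimensions of an image object
#' @param x a RawSpectrumImage, CompressedSpectra or SpectraMatrix.
#' @return Integer vector c(nx, ny).
#' @export
gridDim <- function(x) c(x@nx, x@ny)

#' Raw count matrix of a cube
#' @param x a [RawSpectrumImage-class].
#' @return The sparse pixels-by-bins count matrix.
#' @export
rawCounts <- function(x) x@counts

#' Instrument geometry of a data object
#' @param x an object carrying a geometry slot.
#' @return The [InstrumentGeometry-class].
#' @export
geometry <- function(x) x@geom
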