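# Shared fixtures, built in code. Expensive ones are memoized per test run.

.fixtures <- new.env(parent = emptyenv())

# A small geometry with a coarse (10 ns) TDC so whole-axis operations fit
# in memory: 2500 raw bins over a 25 us window.
coarseGeometry <- function() {
  instrumentGeometry(tof_bin = 1e-8, t_window = 25e-6)
}

# Uniform flat scene with the named species everywhere at the given yields.
flatScene <- function(nx, ny, labels, yields, resolutionR = 7000, seed = 1) {
  tab <- defaultSpeciesTable()
  layers <- lapply(seq_along(labels), function(i) {
    m <- tab$mass[match(labels[i], tab$label)]
    speciesLayer(ionSpecies(labels[i], m), yields[i],
                 matrix(1, nx, ny))
  })
  new("SyntheticScene", nx = as.integer(nx), ny = as.integer(ny),
      pixelPitch = 500e-6 / nx, topography = matrix(0, nx, ny),
      layers = layers, resolutionR = resolutionR, seed = as.integer(seed))
}

# Stochastic 64x64 root scene processed end to end (compress at the
# standard 1000-count threshold, Cs-referenced correction with the robust
# substrate quantile). Memoized: several test files share it.
stochRootPipeline <- function(seed = 11) {
  key <- sprintf("stoch_%d", seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  geom <- instrumentGeometry()
  sc <- makeRootScene(nx = 64, ny = 64, seed = seed)
  raw <- renderScene(sc, geom)
  seg <- labelSegments(findSegments(sumSpectrum(raw), threshold = 1000),
                       defaultSpeciesTable(), geom)
  cs <- compressCube(raw, seg)
  lab <- S4Vectors::mcols(cubeSegments(cs))$label
  track <- trackReference(cs, cubeSegments(cs)[which(lab == "Cs")])
  tsub <- estimateSubstrateTof(track, percentile = 0.9)
  field <- correctionField(track, tsub)
  corrected <- suppressWarnings(applyCorrection(cs, field))
  out <- list(geom = geom, scene = sc, raw = raw, cs = cs, track = track,
              field = field, corrected = corrected)
  .fixtures[[key]] <- out
  out
}

# Noiseless 32x32 root pipeline with a pad wide enough that delta peaks of
# root-confined species stay inside their segments after correction.
noiselessRootPipeline <- function() {
  if (!is.null(.fixtures$noiseless)) return(.fixtures$noiseless)
  geom <- instrumentGeometry()
  sc <- makeRootScene(nx = 32, ny = 32, seed = 1)
  raw <- renderScene(sc, geom, noiseless = TRUE)
  seg <- labelSegments(findSegments(sumSpectrum(raw), threshold = 500,
                                    pad = 120),
                       defaultSpeciesTable(), geom)
  cs <- compressCube(raw, seg)
  lab <- S4Vectors::mcols(cubeSegments(cs))$label
  track <- trackReference(cs, cubeSegments(cs)[which(lab == "Cs")])
  field <- correctionField(track, estimateSubstrateTof(track))
  corrected <- applyCorrection(cs, field)
  out <- list(geom = geom, scene = sc, raw = raw, cs = cs, track = track,
              field = field, corrected = corrected,
              labels = lab)
  .fixtures$noiseless <- out
  out
}

segmentByLabel <- function(cs, label) {
  lab <- S4Vectors::mcols(cubeSegments(cs))$label
  cubeSegments(cs)[which(lab == label)]
}
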