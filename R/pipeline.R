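## End-to-end pipeline: simulate -> compress -> correct -> topo -> pca,
## driven by a validated JSON config with reproducible seeds. Each stage
## writes its artifacts plus a JSON log (parameters, seed, counters);
## identical config + seed give identical outputs. A thin command-line
## wrapper lives in inst/cli/toposims.

.CONFIG_SCHEMA <- list(
  outDir = "character", seed = "numeric", noiseless = "logical",
  simulate = list(nx = "numeric", ny = "numeric", height = "numeric",
                  rootWidthPx = "numeric", pixelPitch = "numeric",
                  resolutionR = "numeric"),
  compress = list(threshold = "numeric", minGap = "numeric",
                  pad = "numeric"),
  correct = list(reference = "character", minCounts = "numeric",
                 percentile = "numeric", integerCounts = "logical"),
  pca = list(nComponents = "numeric", center = "logical",
             exclude = "character")
)

.DEFAULT_CONFIG <- list(
  outDir = ".", seed = 1, noiseless = FALSE,
  simulate = list(nx = 64, ny = 64, height = 200e-6, rootWidthPx = 51,
                  pixelPitch = 500e-6 / 64, resolutionR = 7000),
  compress = list(threshold = 1000, minGap = 40, pad = 10),
  correct = list(reference = "Cs", minCounts = 5, percentile = 1.0,
                 integerCounts = FALSE),
  pca = list(nComponents = 6, center = FALSE,
             exclude = c("K", "Cs", "Cs2"))
)

.validateConfigLevel <- function(cfg, schema, path = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(cfg)) {
    spec <- schema[[nm]]
    if (is.list(spec)) {
      if (!is.list(cfg[[nm]]))
        stop("config key '", path, nm, "' must be a section")
      .validateConfigLevel(cfg[[nm]], spec, paste0(path, nm, "."))
    } else {
      ok <- switch(spec,
        numeric = is.numeric(cfg[[nm]]),
        character = is.character(cfg[[nm]]),
        logical = is.logical(cfg[[nm]]))
      if (!ok)
        stop("config key '", path, nm, "' must be ", spec)
    }
  }
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      .mergeConfig(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Build and validate a pipeline configuration
#'
#' Starts from the shipped defaults (a 64 x 64 root scene, 1000-count
#' compression threshold, Cs+ reference, 6 uncentered components with
#' K/Cs/Cs2 excluded) and overlays the supplied values. Unknown keys are
#' rejected before any stage runs.
#'
#' @param ... named overrides matching the config schema, or a single
#'   `config` list.
#' @param file optional path to a JSON config file (applied before
#'   `...`).
#' @return A validated config list.
#' @examples
#' cfg <- pipelineConfig(seed = 7, compress = list(threshold = 500))
#' @export
pipelineConfig <- function(..., file = NULL) {
  cfg <- .DEFAULT_CONFIG
  if (!is.null(file)) {
    j <- jsonlite::fromJSON(file, simplifyVector = TRUE)
    .validateConfigLevel(j, .CONFIG_SCHEMA)
    cfg <- .mergeConfig(cfg, j)
  }
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1L]]))
    dots <- dots[[1L]]
  .validateConfigLevel(dots, .CONFIG_SCHEMA)
  cfg <- .mergeConfig(cfg, dots)
  .validateConfigLevel(cfg, .CONFIG_SCHEMA)
  cfg
}

.writeStageLog <- function(outDir, stage, params, counters = list()) {
  log <- list(stage = stage, package = "TopoSIMS",
              version = as.character(utils::packageVersion("TopoSIMS")),
              parameters = params, counters = counters)
  jsonlite::write_json(log, file.path(outDir, sprintf("%s_log.json", stage)),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log
}

#' Run the processing pipeline
#'
#' Executes the requested stages in order; later stages read the
#' in-memory results of earlier ones (or the container files in
#' `outDir` from a previous run). Artifacts written per stage:
#' \describe{
#'   \item{simulate}{`raw_cube.bin` (container).}
#'   \item{compress}{`compressed.bin`, `segments.csv`.}
#'   \item{correct}{`corrected.bin`.}
#'   \item{topo}{`topography.tif` (+ `.json` scale sidecar),
#'     `topography.csv`, `topography_profile.csv`.}
#'   \item{pca}{`eigenvectors.csv`, `scree.csv`,
#'     `loading_map_<k>.csv`.}
#' }
#' Each stage also writes `<stage>_log.json`. On error the failing stage
#' is named and an `incomplete.marker` file is left in `outDir`.
#'
#' @param config a config list from [pipelineConfig()].
#' @param stages character vector of stages to run, in pipeline order.
#' @return Invisibly, a list with the final objects (`raw`, `compressed`,
#'   `corrected`, `topography`, `pca`).
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("simulate", "compress", "correct",
                                   "topo", "pca")) {
  valid <- c("simulate", "compress", "correct", "topo", "pca")
  bad <- setdiff(stages, valid)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(outDir, "incomplete.marker")
  file.create(marker)
  state <- list()
  geom <- instrumentGeometry()

  runStage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  if ("simulate" %in% stages) runStage("simulate", function() {
    sc <- makeRootScene(nx = as.integer(config$simulate$nx),
                        ny = as.integer(config$simulate$ny),
                        height = config$simulate$height,
                        rootWidthPx = as.integer(config$simulate$rootWidthPx),
                        pixelPitch = config$simulate$pixelPitch,
                        resolutionR = config$simulate$resolutionR,
                        seed = as.integer(config$seed), geom = geom)
    raw <- renderScene(sc, geom, noiseless = isTRUE(config$noiseless))
    writeCubeContainer(file.path(outDir, "raw_cube.bin"), raw = raw)
    state$scene <<- sc; state$raw <<- raw
    .writeStageLog(outDir, "simulate",
                   c(config$simulate, seed = config$seed,
                     noiseless = isTRUE(config$noiseless)))
  })

  getRaw <- function(stage) {
    if (!is.null(state$raw)) return(state$raw)
    p <- file.path(outDir, "raw_cube.bin")
    if (!file.exists(p))
      stop(sprintf("stage '%s' needs a raw cube: run 'simulate' first or place raw_cube.bin in outDir", stage))
    readCubeContainer(p)$raw
  }

  if ("compress" %in% stages) runStage("compress", function() {
    raw <- getRaw("compress")
    tot <- sumSpectrum(raw)
    seg <- findSegments(tot, threshold = config$compress$threshold,
                        minGap = as.integer(config$compress$minGap),
                        pad = as.integer(config$compress$pad))
    seg <- labelSegments(seg, defaultSpeciesTable(), raw@geom)
    cs <- compressCube(raw, seg)
    writeCubeContainer(file.path(outDir, "compressed.bin"), compressed = cs)
    exportSegmentsCSV(cs, file.path(outDir, "segments.csv"))
    state$compressed <<- cs
    .writeStageLog(outDir, "compress", config$compress,
                   list(n_segments = length(seg),
                        n_points = ncol(compressedMatrix(cs))))
  })

  getCompressed <- function(stage) {
    if (!is.null(state$compressed)) return(state$compressed)
    p <- file.path(outDir, "compressed.bin")
    if (!file.exists(p))
      stop(sprintf("stage '%s' needs compressed spectra: run 'compress' first or place compressed.bin in outDir", stage))
    readCubeContainer(p)$compressed
  }

  if ("correct" %in% stages) runStage("correct", function() {
    cs <- getCompressed("correct")
    seg <- cubeSegments(cs)
    lab <- mcols(seg)$label
    hit <- which(!is.na(lab) &
                 vapply(strsplit(lab, "\\+"), function(p)
                   config$correct$reference %in% p, TRUE))
    if (length(hit) != 1L)
      stop(sprintf("reference species '%s' does not label exactly one segment",
                   config$correct$reference))
    track <- trackReference(cs, seg[hit],
                            minCounts = config$correct$minCounts,
                            refSpecies = ionSpecies(config$correct$reference))
    tsub <- estimateSubstrateTof(track, config$correct$percentile)
    field <- correctionField(track, tsub)
    corrected <- applyCorrection(cs, field,
                                 integerCounts =
                                   isTRUE(config$correct$integerCounts))
    writeCubeContainer(file.path(outDir, "corrected.bin"),
                       compressed = corrected)
    state$track <<- track; state$field <<- field
    state$corrected <<- corrected
    .writeStageLog(outDir, "correct", config$correct,
                   list(t_ref_sub = tsub,
                        lost_counts = attr(corrected, "lostCounts")))
  })

  if ("topo" %in% stages) runStage("topo", function() {
    if (is.null(state$field))
      stop("no correction field available: run the 'correct' stage first")
    topo <- reconstructTopography(state$field,
                                  ionSpecies(config$correct$reference), geom)
    dh <- heightMap(topo)
    exportMapTIFF(dh, file.path(outDir, "topography.tif"))
    exportMapCSV(dh, file.path(outDir, "topography.csv"),
                 valid = validMask(topo))
    exportProfileCSV(lineProfile(dh,
                       pixelPitch = config$simulate$pixelPitch),
                     file.path(outDir, "topography_profile.csv"))
    state$topography <<- topo
    .writeStageLog(outDir, "topo",
                   list(reference = config$correct$reference),
                   list(max_height_um = max(dh) * 1e6,
                        n_valid = sum(validMask(topo))))
  })

  if ("pca" %in% stages) runStage("pca", function() {
    cs <- if (!is.null(state$corrected)) state$corrected
          else getCompressed("pca")
    excl <- intersect(config$pca$exclude,
                      stats::na.omit(mcols(cubeSegments(cs))$label))
    sm <- excludeSpecies(cs, excl)
    r <- spectraPCA(sm, nComponents = as.integer(config$pca$nComponents),
                    center = isTRUE(config$pca$center))
    exportEigenvectorsCSV(r, file.path(outDir, "eigenvectors.csv"))
    exportScreeCSV(r, file.path(outDir, "scree.csv"))
    for (k in seq_len(ncol(r@loadings)))
      exportMapCSV(loadingMap(r, k),
                   file.path(outDir, sprintf("loading_map_%d.csv", k)))
    state$pca <<- r
    .writeStageLog(outDir, "pca",
                   c(config$pca[c("nComponents", "center")],
                     list(excluded = excl)),
                   list(explained_variance_1 = scree(r)[1]))
  })

  file.remove(marker)
  invisible(state)
}
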