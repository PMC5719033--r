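## Single-file cube container: a self-described block format holding raw
## and/or compressed cubes, geometry metadata, the segment table and a
## processing log. Layout: 12-byte magic, int32 version, then named
## blocks ([int32 name length][name][int32 type][int32 element count]
## [payload]) until EOF. Types: 1 = UTF-8 JSON text, 2 = float64 array,
## 3 = int32 array. Everything little-endian; round trips are lossless.

.CONTAINER_MAGIC <- "TOPOSIMSCUBE"
.CONTAINER_VERSION <- 1L

.writeBlock <- function(con, name, type, payload) {
  nm <- charToRaw(name)
  writeBin(length(nm), con, size = 4L, endian = "little")
  writeBin(nm, con)
  writeBin(as.integer(type), con, size = 4L, endian = "little")
  if (type == 1L) {
    raw <- charToRaw(payload)
    writeBin(length(raw), con, size = 4L, endian = "little")
    writeBin(raw, con)
  } else if (type == 2L) {
    writeBin(length(payload), con, size = 4L, endian = "little")
    writeBin(as.numeric(payload), con, size = 8L, endian = "little")
  } else {
    writeBin(length(payload), con, size = 4L, endian = "little")
    writeBin(as.integer(payload), con, size = 4L, endian = "little")
  }
}

.readBlock <- function(con) {
  nlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(nlen)) return(NULL)          # clean EOF
  nm <- readBin(con, "raw", nlen)
  if (length(nm) < nlen) stop("truncated container: incomplete block name")
  name <- rawToChar(nm)
  hdr <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  if (length(hdr) < 2L)
    stop("truncated container: incomplete header of block '", name, "'")
  type <- hdr[1L]; n <- hdr[2L]
  payload <- switch(as.character(type),
    "1" = { r <- readBin(con, "raw", n)
            if (length(r) < n)
              stop("truncated container: block '", name, "' cut short")
            rawToChar(r) },
    "2" = { v <- readBin(con, "numeric", n, size = 8L, endian = "little")
            if (length(v) < n)
              stop("truncated container: block '", name, "' cut short")
            v },
    "3" = { v <- readBin(con, "integer", n, size = 4L, endian = "little")
            if (length(v) < n)
              stop("truncated container: block '", name, "' cut short")
            v },
    stop("unknown block type ", type, " in block '", name, "'"))
  list(name = name, payload = payload)
}

.segmentsToJSON <- function(seg) {
  jsonlite::toJSON(list(start = start(seg), end = end(seg),
                        totalCounts = mcols(seg)$totalCounts,
                        label = mcols(seg)$label),
                   auto_unbox = FALSE, digits = NA, na = "null")
}

.segmentsFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json)
  seg <- IRanges(start = as.integer(x$start), end = as.integer(x$end))
  mcols(seg)$totalCounts <- as.numeric(x$totalCounts)
  lab <- if (length(x$label)) as.character(x$label) else character(0)
  lab[lab == "NULL"] <- NA_character_
  mcols(seg)$label <- if (length(seg)) lab else character(0)
  seg
}

#' Write a cube container
#'
#' Stores a raw cube and/or a compressed cube together with geometry
#' metadata and a processing log in a single self-described binary file.
#' Round trips are lossless (see [readCubeContainer()]).
#'
#' @param path output file path.
#' @param raw optional [RawSpectrumImage-class].
#' @param compressed optional [CompressedSpectra-class].
#' @param log named list of processing-log entries (stored as JSON).
#' @return `path`, invisibly.
#' @export
writeCubeContainer <- function(path, raw = NULL, compressed = NULL,
                               log = list()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.CONTAINER_MAGIC), con)
  writeBin(.CONTAINER_VERSION, con, size = 4L, endian = "little")
  geom <- if (!is.null(raw)) raw@geom
          else if (!is.null(compressed)) compressed@geom else NULL
  if (!is.null(geom))
    .writeBlock(con, "geometry", 1L, as.character(geometryToJSON(geom)))
  if (!is.null(raw)) {
    tri <- Matrix::summary(raw@counts)
    .writeBlock(con, "raw_grid", 1L, as.character(jsonlite::toJSON(
      list(nx = raw@nx, ny = raw@ny, metadata = raw@metadata),
      auto_unbox = TRUE)))
    .writeBlock(con, "raw_i", 3L, tri$i)
    .writeBlock(con, "raw_j", 3L, tri$j)
    .writeBlock(con, "raw_x", 2L, tri$x)
  }
  if (!is.null(compressed)) {
    .writeBlock(con, "cmp_grid", 1L, as.character(jsonlite::toJSON(
      list(nx = compressed@nx, ny = compressed@ny,
           npoints = ncol(compressed@matrix)), auto_unbox = TRUE)))
    .writeBlock(con, "cmp_matrix", 2L, as.numeric(compressed@matrix))
    .writeBlock(con, "cmp_index_map", 3L, compressed@indexMap)
    .writeBlock(con, "cmp_mz_map", 2L, compressed@mzMap)
    .writeBlock(con, "cmp_point_segment", 3L, compressed@pointSegment)
    .writeBlock(con, "cmp_segments", 1L,
                as.character(.segmentsToJSON(compressed@segments)))
  }
  .writeBlock(con, "log", 1L, as.character(jsonlite::toJSON(
    log, auto_unbox = TRUE, digits = NA, null = "null")))
  invisible(path)
}

#' Read a cube container
#'
#' @param path a file written by [writeCubeContainer()].
#' @return A list with elements `raw` ([RawSpectrumImage-class] or NULL),
#'   `compressed` ([CompressedSpectra-class] or NULL) and `log` (list).
#' @export
readCubeContainer <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(.CONTAINER_MAGIC)))
  if (!identical(magic, .CONTAINER_MAGIC))
    stop("not a cube container (bad magic)")
  ver <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(ver) || ver != .CONTAINER_VERSION)
    stop(sprintf("container version mismatch: found %s, expected %d",
                 if (length(ver)) ver else "<none>", .CONTAINER_VERSION))
  blocks <- list()
  repeat {
    b <- .readBlock(con)
    if (is.null(b)) break
    blocks[[b$name]] <- b$payload
  }
  out <- list(raw = NULL, compressed = NULL, log = list())
  hasRaw <- !is.null(blocks$raw_grid)
  hasCmp <- !is.null(blocks$cmp_grid)
  if ((hasRaw || hasCmp) && is.null(blocks$geometry))
    stop("container is missing its 'geometry' block")
  geom <- if (!is.null(blocks$geometry)) geometryFromJSON(blocks$geometry)
  if (hasRaw) {
    g <- jsonlite::fromJSON(blocks$raw_grid)
    counts <- sparseMatrix(i = blocks$raw_i, j = blocks$raw_j,
                           x = blocks$raw_x,
                           dims = c(g$nx * g$ny, nBins(geom)))
    out$raw <- new("RawSpectrumImage", counts = counts, geom = geom,
                   nx = as.integer(g$nx), ny = as.integer(g$ny),
                   metadata = as.character(g$metadata))
  }
  if (hasCmp) {
    g <- jsonlite::fromJSON(blocks$cmp_grid)
    mat <- matrix(blocks$cmp_matrix, nrow = g$nx * g$ny)
    out$compressed <- new("CompressedSpectra", matrix = mat,
                          indexMap = as.integer(blocks$cmp_index_map),
                          mzMap = as.numeric(blocks$cmp_mz_map),
                          segments = .segmentsFromJSON(blocks$cmp_segments),
                          pointSegment = as.integer(blocks$cmp_point_segment),
                          geom = geom,
                          nx = as.integer(g$nx), ny = as.integer(g$ny))
  }
  if (!is.null(blocks$log))
    out$log <- jsonlite::fromJSON(blocks$log, simplifyVector = TRUE)
  out
}
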