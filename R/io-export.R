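## Deterministic table and image exports. All CSV numbers are written
## with 9 significant digits (round-trip stable for float32-scale data);
## field order is fixed, so identical inputs give byte-identical files.

.writeCSV <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) {
    intcol <- all(is.finite(df[[j]])) && all(df[[j]] == round(df[[j]]))
    df[[j]] <- if (intcol) format(df[[j]], scientific = FALSE, trim = TRUE)
               else .fmtNum(df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a spatial map to CSV
#'
#' Long-format CSV with 0-based pixel coordinates (`x` fastest), the map
#' value and the validity flag; the exact-value counterpart of the TIFF
#' export.
#'
#' @param map nx-by-ny numeric matrix.
#' @param path output path.
#' @param valid optional logical matrix; defaults to the map's `"valid"`
#'   attribute or all-TRUE.
#' @return `path`, invisibly.
#' @export
exportMapCSV <- function(map, path, valid = NULL) {
  if (is.null(valid)) valid <- attr(map, "valid")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(map), ncol(map))
  nx <- nrow(map); ny <- ncol(map)
  df <- data.frame(
    x = rep(seq_len(nx) - 1L, ny),
    y = rep(seq_len(ny) - 1L, each = nx),
    value = as.vector(map),
    valid = as.integer(as.vector(valid)))
  .writeCSV(df, path)
}

#' Export a spatial map as 32-bit float TIFF
#'
#' The map is normalized to [0, 1] by its maximum absolute value before
#' writing (float TIFF samples outside [0, 1] are not portable across
#' writers); the scale factor and offset are recorded in a JSON sidecar
#' `<path>.json`, so `value = tiff * scale`. Use [exportMapCSV()] for
#' exact values.
#'
#' @param map nx-by-ny numeric matrix.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
exportMapTIFF <- function(map, path) {
  scale <- max(abs(map), 1e-300)
  ## TIFF raster convention: rows = y; transpose the x-fastest map
  tiff::writeTIFF(t(map) / scale, path, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(list(scale = scale, orientation = "rows_are_y"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export the segment table to CSV
#'
#' Columns `start_bin`/`end_bin` use the documented 0-based half-open
#' raw-bin convention.
#'
#' @param cs a [CompressedSpectra-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportSegmentsCSV <- function(cs, path) {
  .writeCSV(segmentTable(cs), path)
}

#' Export PCA eigenvectors to CSV
#'
#' One row per included point: point index (0-based), m/z, then one
#' column per component.
#'
#' @param r a [PCAResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportEigenvectorsCSV <- function(r, path) {
  df <- data.frame(point_index = r@includedIdx - 1L, mz = r@mzIncluded)
  for (k in seq_len(ncol(r@eigenvectors)))
    df[[sprintf("component_%d", k)]] <- r@eigenvectors[, k]
  .writeCSV(df, path)
}

#' Export the scree curve to CSV
#' @param r a [PCAResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportScreeCSV <- function(r, path) {
  ev <- scree(r)
  .writeCSV(data.frame(component = seq_along(ev),
                       explained_variance = ev), path)
}

#' Export a line profile to CSV
#' @param profile data.frame from [lineProfile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportProfileCSV <- function(profile, path) {
  .writeCSV(profile, path)
}
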