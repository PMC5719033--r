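## PCA over compressed (corrected) spectra: each pixel's spectrum is one
## vector; uncentered, unwhitened decomposition by default, under which
## the first component reproduces the averaged mass spectrum and later
## components separate chemically distinct regions.

#' Convert compressed spectra to a decomposition-ready matrix
#'
#' @param cs a [CompressedSpectra-class].
#' @param normalizeTIC divide each pixel spectrum by its total ion count
#'   (zero-count pixels stay zero). Off by default.
#' @return A [SpectraMatrix-class] with all points included.
#' @export
asSpectraMatrix <- function(cs, normalizeTIC = FALSE) {
  m <- cs@matrix
  if (normalizeTIC) {
    tot <- rowSums(m)
    m <- m / ifelse(tot > 0, tot, 1)
  }
  new("SpectraMatrix", matrix = m,
      included = rep(TRUE, ncol(m)), mzMap = cs@mzMap,
      nx = cs@nx, ny = cs@ny)
}

#' Exclude labelled peaks from the decomposition
#'
#' Masks out every compressed point belonging to the named segments.
#' Typical use: drop the saturated K+ peak and the Cs+/Cs2+ peaks
#' implanted by the sputter source before PCA, so the decomposition is
#' driven by sample chemistry rather than instrument artifacts.
#'
#' @param cs a [CompressedSpectra-class] with labelled segments (see
#'   [labelSegments()]).
#' @param labels character vector of segment labels to exclude.
#' @param normalizeTIC passed to [asSpectraMatrix()].
#' @return A [SpectraMatrix-class].
#' @export
excludeSpecies <- function(cs, labels, normalizeTIC = FALSE) {
  sm <- asSpectraMatrix(cs, normalizeTIC = normalizeTIC)
  if (!length(labels)) return(sm)
  known <- mcols(cs@segments)$label
  unknown <- setdiff(labels, known[!is.na(known)])
  if (length(unknown))
    stop("unknown segment label(s): ", paste(unknown, collapse = ", "),
         "; known labels: ",
         paste(stats::na.omit(known), collapse = ", "))
  segIdx <- which(known %in% labels)
  inc <- !(cs@pointSegment %in% segIdx)
  if (!any(inc)) stop("all points excluded: empty matrix")
  sm@included <- inc
  sm
}

#' Principal component analysis of image spectra
#'
#' Singular value decomposition of the (optionally mean-centered)
#' pixels-by-points matrix restricted to included points. Uncentered and
#' unwhitened by default: in that convention the first component is the
#' averaged mass spectrum, and structure appears from component 2 on.
#' Deterministic up to sign; the sign is fixed so each eigenvector's
#' largest-magnitude element is positive.
#'
#' @param m a [SpectraMatrix-class].
#' @param nComponents number of components to retain (default 6).
#' @param center subtract column means first (default `FALSE`).
#' @return A [PCAResult-class].
#' @export
spectraPCA <- function(m, nComponents = 6L, center = FALSE) {
  inc <- which(m@included)
  X <- m@matrix[, inc, drop = FALSE]
  kmax <- min(nrow(X), ncol(X))
  if (nComponents < 1L || nComponents > kmax)
    stop(sprintf("nComponents must lie in [1, %d]", kmax))
  ctr <- numeric(ncol(X))
  if (center) {
    ctr <- colMeans(X)
    X <- sweep(X, 2L, ctr)
  }
  sv <- svd(X, nu = nComponents, nv = nComponents)
  ss <- sv$d^2
  ev <- if (sum(ss) > 0) ss / sum(ss) else ss
  V <- sv$v
  L <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  ## sign convention: largest |element| of each eigenvector positive
  for (k in seq_len(nComponents)) {
    s <- sign(V[which.max(abs(V[, k])), k])
    if (s < 0) { V[, k] <- -V[, k]; L[, k] <- -L[, k] }
  }
  new("PCAResult", eigenvectors = V, loadings = L,
      explainedVariance = ev, centered = center, center = ctr,
      includedIdx = as.integer(inc), mzIncluded = m@mzMap[inc],
      nx = m@nx, ny = m@ny)
}

#' Explained-variance fractions (scree curve)
#'
#' @param r a [PCAResult-class].
#' @return Non-increasing numeric vector of variance fractions, one per
#'   singular value of the decomposed matrix (sums to 1).
#' @export
scree <- function(r) r@explainedVariance

#' Loading (abundance) map of one component
#'
#' @param r a [PCAResult-class].
#' @param k component index.
#' @return nx-by-ny numeric matrix of loading coefficients.
#' @export
loadingMap <- function(r, k) {
  if (k < 1L || k > ncol(r@loadings)) stop("component index out of range")
  matrix(r@loadings[, k], nrow = r@nx)
}

#' Eigenvector (spectral endmember) of one component
#'
#' @param r a [PCAResult-class].
#' @param k component index; omit for the full matrix.
#' @return Numeric vector over included points (or the full matrix).
#' @export
eigenSpectra <- function(r, k = NULL) {
  if (is.null(k)) r@eigenvectors else r@eigenvectors[, k]
}

#' Rank-k reconstruction of the spectra matrix
#'
#' Reconstructs the included-points matrix from the first k components
#' (adding back the column means when the decomposition was centered).
#' The Frobenius reconstruction error is non-increasing in k, and equals
#' zero (to numerical precision) at full rank.
#'
#' @param r a [PCAResult-class].
#' @param k number of components to use (default: all retained).
#' @return A [SpectraMatrix-class] over the included points.
#' @export
reconstructSpectra <- function(r, k = ncol(r@loadings)) {
  if (k < 1L || k > ncol(r@loadings)) stop("k out of range")
  X <- r@loadings[, seq_len(k), drop = FALSE] %*%
    t(r@eigenvectors[, seq_len(k), drop = FALSE])
  if (r@centered) X <- sweep(X, 2L, r@center, `+`)
  new("SpectraMatrix", matrix = X,
      included = rep(TRUE, ncol(X)), mzMap = r@mzIncluded,
      nx = r@nx, ny = r@ny)
}
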