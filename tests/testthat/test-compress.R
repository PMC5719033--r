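# Segment finding, lossless compression and peak maps.

test_that("segment finding follows the threshold/merge/pad rules", {
  # empty spectrum
  expect_length(findSegments(numeric(5000), threshold = 100), 0)
  expect_error(findSegments(numeric(10), threshold = 0), "threshold")

  # one isolated peak with 1200 total counts at threshold 1000
  tot <- numeric(5000); tot[2000:2005] <- 200
  seg <- findSegments(tot, threshold = 1000)
  expect_length(seg, 1)
  expect_true(IRanges::start(seg) <= 2000 && IRanges::end(seg) >= 2005)
  expect_equal(S4Vectors::mcols(seg)$totalCounts, 1200)

  # two 600-count peaks separated by 30 zero bins: merged under the
  # default minGap = 40 (1200 >= 1000), but separate and sub-threshold
  # under minGap = 10
  tot2 <- numeric(5000)
  tot2[1000:1002] <- 200          # 600 counts
  tot2[1033:1035] <- 200          # gap of 30 zero bins
  expect_length(findSegments(tot2, threshold = 1000, minGap = 40), 1)
  expect_length(findSegments(tot2, threshold = 1000, minGap = 10), 0)

  # padding is clipped at the axis ends
  tot3 <- numeric(100); tot3[1:3] <- 500
  seg3 <- findSegments(tot3, threshold = 100, pad = 10)
  expect_equal(IRanges::start(seg3), 1)
})

test_that("raising the threshold never adds segments or points", {
  set.seed(3)
  tot <- numeric(20000)
  for (i in 1:30) {
    at <- sample(19000, 1)
    tot[at:(at + 5)] <- tot[at:(at + 5)] + rpois(6, sample(c(5, 50, 500), 1))
  }
  prevSeg <- Inf; prevPts <- Inf
  for (thr in c(10, 100, 500, 1000, 3000)) {
    seg <- findSegments(tot, threshold = thr)
    expect_lte(length(seg), prevSeg)
    expect_lte(sum(IRanges::width(seg)), prevPts)
    prevSeg <- length(seg); prevPts <- sum(IRanges::width(seg))
  }
})

test_that("compression is lossless and decompression is its inverse", {
  fx <- stochRootPipeline()
  cs <- fx$cs
  # counts within segments identical to the raw cube
  expect_equal(compressedMatrix(cs),
               as.matrix(rawCounts(fx$raw)[, indexMap(cs)]),
               ignore_attr = TRUE)
  # decompress -> recompress is the identity
  back <- decompressCube(cs)
  cs2 <- compressCube(back, cubeSegments(cs))
  expect_equal(compressedMatrix(cs2), compressedMatrix(cs))
  expect_identical(indexMap(cs2), indexMap(cs))
  # strong reduction: thousands of points out of 2,000,000 raw bins
  expect_lt(ncol(compressedMatrix(cs)), 5000)
  expect_gt(nBins(fx$geom) / ncol(compressedMatrix(cs)), 100)
})

test_that("whole-axis compression is the identity and empty segments give zero points", {
  geom <- coarseGeometry()
  sc <- flatScene(5, 5, c("K", "Na"), c(7, 3), seed = 4)
  raw <- renderScene(sc, geom, noiseless = TRUE)
  all <- IRanges::IRanges(1, nBins(geom))
  S4Vectors::mcols(all)$totalCounts <- sum(rawCounts(raw))
  S4Vectors::mcols(all)$label <- NA_character_
  cs <- compressCube(raw, all)
  expect_equal(compressedMatrix(cs), as.matrix(rawCounts(raw)),
               ignore_attr = TRUE)
  cs0 <- compressCube(raw, IRanges::IRanges())
  expect_equal(ncol(compressedMatrix(cs0)), 0)
  bad <- IRanges::IRanges(nBins(geom), nBins(geom) + 10)
  expect_error(compressCube(raw, bad), "range")
})

test_that("the m/z calibration of a rendered species lands within one bin equivalent", {
  geom <- instrumentGeometry()
  sc <- flatScene(6, 6, "Ca", 50)
  raw <- renderScene(sc, geom, noiseless = TRUE)
  seg <- findSegments(sumSpectrum(raw), threshold = 100)
  cs <- compressCube(raw, seg)
  ctr <- which.max(colSums(compressedMatrix(cs)))
  m <- ionMasses[["Ca"]]
  binMass <- 2 * m * geom@tof_bin / totalTof(m, 0, geom)
  expect_lt(abs(mzMap(cs)[ctr] - m), binMass)
})

test_that("peak maps localize species and normalization behaves", {
  fx <- noiselessRootPipeline()
  kseg <- segmentByLabel(fx$cs, "K")
  mp <- peakMap(fx$cs, kseg)
  inRoot <- rootMask(fx$scene)
  expect_true(all(mp[!inRoot] == 0))
  expect_true(all(mp[inRoot] > 0))
  # uniform noiseless layer gives a constant map
  geom <- instrumentGeometry()
  sc <- flatScene(5, 5, "Na", 8)
  raw <- renderScene(sc, geom, noiseless = TRUE)
  seg <- findSegments(sumSpectrum(raw), threshold = 10)
  expect_true(all(peakMap(raw, seg[1]) == 8))
  # normalized single-species map is 1 wherever counts exist
  mpn <- peakMap(raw, seg[1], normalize = TRUE)
  expect_true(all(mpn == 1))
  expect_true(all(attr(mpn, "valid")))
})

test_that("segment tables export the documented 0-based half-open convention", {
  fx <- noiselessRootPipeline()
  tab <- segmentTable(fx$cs)
  seg <- cubeSegments(fx$cs)
  expect_equal(tab$start_bin, IRanges::start(seg) - 1L)
  expect_equal(tab$end_bin, IRanges::end(seg))
  expect_equal(tab$end_bin - tab$start_bin, IRanges::width(seg))
  expect_true(all(diff(tab$start_bin) > 0))
  expect_true("Cs" %in% tab$label && "K" %in% tab$label)
})
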