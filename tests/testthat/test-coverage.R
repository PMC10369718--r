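test_that("binRegion tiles regions exactly with near-equal widths", {
  b <- binRegion(GRanges("chr1", IRanges(1, 1000)), 100)
  expect_identical(length(b), 100L)
  expect_identical(start(b)[1], 1L)
  expect_identical(end(b)[1], 10L)
  expect_identical(start(b)[100], 991L)
  expect_identical(end(b)[100], 1000L)
  expect_true(all(width(b) == 10L))

  # evaluated from the floor formula: widths alternate between 1 and 2
  # and the bins tile all 150 bases
  b2 <- binRegion(GRanges("chr1", IRanges(1, 150)), 100)
  expect_setequal(unique(width(b2)), c(1L, 2L))
  expect_identical(sum(width(b2)), 150L)
  expect_identical(start(b2)[-1], end(b2)[-100] + 1L)

  expect_error(binRegion(GRanges("chr1", IRanges(1, 50)), 100), "smaller")
})

test_that("bin tiling holds for random widths and bin counts", {
  withr::with_seed(99, {
    for (i in 1:20) {
      n <- sample(2:120, 1)
      W <- n + sample(0:2000, 1)
      s0 <- sample(1:1e6, 1)
      b <- binRegion(GRanges("chr1", IRanges(s0, s0 + W - 1)), n)
      expect_identical(start(b)[1], s0)
      expect_identical(end(b)[length(b)], s0 + W - 1L)
      expect_identical(start(b)[-1], end(b)[-length(b)] + 1L)
      expect_lte(diff(range(width(b))), 1L)
    }
  })
})

test_that("subject elements count once in every bin they touch", {
  q <- RegionSet(GRanges("chr1", IRanges(1, 1000), strand = "+"),
                 name = "genes")
  atStart <- RegionSet(GRanges("chr1", IRanges(1, 10)), name = "s")
  cm <- coverageMatrix(q, atStart, nBins = 100)
  expect_identical(coverageProfile(cm), c(1, rep(0, 99)))

  spanning <- RegionSet(GRanges("chr1", IRanges(5, 25)), name = "s")
  cm2 <- coverageMatrix(q, spanning, nBins = 100)
  expect_identical(coverageProfile(cm2), c(1, 1, 1, rep(0, 97)))
})

test_that("minus-strand queries report bins 5' to 3'", {
  qm <- RegionSet(GRanges("chr1", IRanges(1, 1000), strand = "-"),
                  name = "genes")
  s <- RegionSet(GRanges("chr1", IRanges(1, 10)), name = "s")
  cm <- coverageMatrix(qm, s, nBins = 100)
  # the element sits at the genomic start = the 3' end of a minus-strand
  # gene, so it lands in the last 5'->3' bin
  expect_identical(coverageProfile(cm)[100], 1)
  expect_identical(sum(coverageProfile(cm)), 1)
  unoriented <- coverageMatrix(qm, s, nBins = 100, orient = FALSE)
  expect_identical(coverageProfile(unoriented)[1], 1)
})

test_that("flipping query strands reverses every matrix row", {
  q <- randomSet(60, seed = 51, strandProbs = c(0.5, 0.5, 0))
  s <- generateSubjectsFor(q, rate = 3, seed = 52)$subjects
  a <- coverageMatrix(q, s, nBins = 20)
  b <- coverageMatrix(flipStrands(q), s, nBins = 20)
  expect_identical(keptQueryIndices(a), keptQueryIndices(b))
  ma <- coverageValues(a); mb <- coverageValues(b)
  for (i in seq_len(nrow(ma)))
    expect_identical(mb[i, ], rev(ma[i, ]))
})

test_that("row sums are bounded by hit count and hit count x bins", {
  q <- randomSet(80, seed = 61)
  s <- randomSet(200, seed = 62, name = "s")
  nBins <- 25
  cm <- coverageMatrix(q, s, nBins = nBins)
  kept <- keptQueryIndices(cm)
  ht <- findRegionOverlaps(q[kept], s)
  hitCounts <- countOverlapsPerQuery(ht, length(kept))
  rs <- rowSums(coverageValues(cm))
  expect_true(all(rs >= hitCounts))
  expect_true(all(rs <= hitCounts * nBins))
})

test_that("too-short queries are dropped and counted", {
  q <- RegionSet(GRanges("chr1", IRanges(c(1, 2000), c(1000, 2049))),
                 name = "genes")
  s <- RegionSet(GRanges("chr1", IRanges(1, 10)), name = "s")
  expect_warning(cm <- coverageMatrix(q, s, nBins = 100), "shorter")
  expect_identical(keptQueryIndices(cm), 1L)
  expect_identical(cm@nDroppedShort, 1L)
  expect_error(coverageMatrix(q, s, nBins = 0), "nBins")
})

test_that("profile table conserves the matrix total", {
  ws <- makeToyWorkspace()
  cm <- coverageMatrix(querySet(ws), subjectSet(ws, "TFBS"), nBins = 10)
  pt <- profileTable(cm)
  expect_identical(nrow(pt), 10L)
  expect_equal(sum(pt$count), sum(coverageValues(cm)))
  zero <- coverageMatrix(querySet(ws),
                         RegionSet(GRanges(), name = "none"), nBins = 10)
  expect_true(all(profileTable(zero)$count == 0))

  p <- withr::local_tempfile(fileext = ".csv")
  writeCoverageMatrix(cm, p)
  got <- read.csv(p)
  expect_identical(ncol(got), 11L)  # queryIndex + 10 bins
  expect_equal(sum(got[, -1]), sum(coverageValues(cm)))
})

test_that("5'-biased placement enriches the first bins", {
  q <- tileRegionSet(500, width = 1000, gap = 50)
  s <- generateSubjectsFor(q, rate = 4, bias = "five_prime", seed = 17)
  cm <- coverageMatrix(q, s$subjects, nBins = 100)
  prof <- coverageProfile(cm)
  expect_gt(sum(prof[1:10]), sum(prof[91:100]))
})
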