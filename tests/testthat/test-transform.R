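gene <- function(start, end, strand = "+", chrom = "chr1") {
  RegionSet(GRanges(chrom, IRanges(start, end), strand = strand),
            name = "genes")
}

test_that("TSS windows are anchored strand-aware", {
  plus <- resizeRegions(gene(5000, 7000, "+"), "tss", upstream = 1200)
  expect_identical(start(regions(plus)), 3800L)
  expect_identical(end(regions(plus)), 5000L)

  minus <- resizeRegions(gene(5000, 7000, "-"), "tss", upstream = 1200)
  expect_identical(start(regions(minus)), 7000L)
  expect_identical(end(regions(minus)), 8200L)

  # anchor base included by default: width = upstream + downstream + 1
  expect_identical(regionWidths(plus), 1201L)
  excl <- resizeRegions(gene(5000, 7000, "+"), "tss", upstream = 1200,
                        includeAnchorBase = FALSE)
  expect_identical(start(regions(excl)), 3800L)
  expect_identical(end(regions(excl)), 4999L)
  expect_error(resizeRegions(gene(1, 10), "tss", upstream = 5,
                             downstream = 5, includeAnchorBase = FALSE),
               "one-sided")
})

test_that("TES and body anchors mirror the TSS rules", {
  tes <- resizeRegions(gene(5000, 7000, "+"), "tes", downstream = 100)
  expect_identical(start(regions(tes)), 7000L)
  expect_identical(end(regions(tes)), 7100L)
  tesm <- resizeRegions(gene(5000, 7000, "-"), "tes", downstream = 100)
  expect_identical(start(regions(tesm)), 4900L)
  expect_identical(end(regions(tesm)), 5000L)

  body <- resizeRegions(gene(5000, 7000, "-"), "body", upstream = 10,
                        downstream = 20)
  expect_identical(start(regions(body)), 4980L)  # 3' end for minus strand
  expect_identical(end(regions(body)), 7010L)
})

test_that("no-op body resize returns the input unchanged", {
  rs <- gene(5000, 7000, "-")
  expect_identical(resizeRegions(rs, "body"), rs)
})

test_that("clipping respects chromosome bounds and drops empty regions", {
  expect_message(
    clipped <- resizeRegions(gene(500, 900, "+"), "tss", upstream = 1200),
    "clipped")
  expect_identical(start(regions(clipped)), 1L)
  expect_identical(end(regions(clipped)), 500L)

  sz <- c(chr1 = 1000)
  high <- suppressMessages(
    resizeRegions(gene(800, 900, "+"), "body", downstream = 500,
                  chromSizes = sz))
  expect_identical(end(regions(high)), 1000L)

  # strictly downstream of the TES of a plus-strand gene ending at the
  # chromosome boundary: nothing is left after clipping
  expect_warning(suppressMessages(
    gone <- resizeRegions(gene(990, 1000, "+"), "tes", downstream = 50,
                          includeAnchorBase = FALSE, chromSizes = sz)),
    "dropped")
  expect_identical(nRegions(gone), 0L)
})

test_that("strand mirror: flipped regions give mirror-image windows of equal width", {
  for (seed in 1:5) {
    rs <- randomSet(40, seed = seed, strandProbs = c(0.5, 0.5, 0))
    a <- resizeRegions(rs, "tss", upstream = 300, downstream = 120)
    b <- resizeRegions(flipStrands(rs), "tss", upstream = 300,
                       downstream = 120)
    expect_identical(regionWidths(a), regionWidths(b))
    # mirror about the region body: distances from the body ends swap
    ga <- regions(a); gb <- regions(b); g0 <- regions(rs)
    expect_identical(start(g0) - start(ga), end(gb) - end(g0))
    expect_identical(end(ga) - end(g0), start(g0) - start(gb))
  }
})

test_that("unstranded regions anchor like plus strand with a warning", {
  expect_warning(star <- resizeRegions(gene(5000, 7000, "*"), "tss",
                                       upstream = 100), "unstranded")
  expect_identical(start(regions(star)), 4900L)
})

test_that("subsetRegions filters by name, chromosome, strand and score", {
  gr <- GRanges(c("chr1", "chr2", "chr1"), IRanges(1:3 * 100, 1:3 * 100 + 9),
                strand = c("+", "-", "+"))
  mcols(gr)$name <- c("EGR4", "EGR1", "EGR4")
  mcols(gr)$score <- c(200, 400, 600)
  rs <- RegionSet(gr, name = "tfbs")

  egr4 <- suppressMessages(subsetRegions(rs, namePattern = "^EGR4$"))
  expect_identical(regionNames(egr4), c("EGR4", "EGR4"))

  chr1 <- suppressMessages(subsetRegions(rs, chroms = "chr1"))
  expect_identical(nRegions(chr1), 2L)

  hi <- suppressMessages(subsetRegions(rs, minScore = 400))
  expect_identical(nRegions(hi), 2L)

  both <- suppressMessages(subsetRegions(rs, namePattern = "^EGR4$",
                                         minScore = 400))
  expect_identical(nRegions(both), 1L)

  expect_error(subsetRegions(rs, attrs = list(cell = "GC1")),
               "unknown attribute")
})
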