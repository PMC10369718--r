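# Hand-enumerated golden values for the toy workspace.
#
# The toy workspace (makeToyWorkspace) was designed so every overlap can
# be read off the coordinates directly; the tables below were written
# down by hand from those coordinates before the engine existed and are
# the reference the engine must reproduce exactly.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# gene widths: g1 1001, g2 1001, g3 2001, g4 501, g5 101,
#              g6 1001, g7 101, g8 1001, g9 51, g10 1001
goldenTfbsHits <- function() {
  data.frame(
    queryIndex = c(1L, 1L, 1L, 3L, 3L, 6L, 8L, 10L),
    subjectIndex = c(1L, 2L, 3L, 5L, 6L, 7L, 8L, 9L),
    chrom = c(rep("chr1", 5), rep("chr2", 3)),
    ovStart = c(1100L, 1500L, 1990L, 5500L, 6500L, 1000L, 5990L, 8400L),
    ovEnd = c(1110L, 1520L, 2000L, 5510L, 6600L, 1000L, 6000L, 8600L),
    ovWidth = c(11L, 21L, 11L, 11L, 101L, 1L, 11L, 201L),
    fracQuery = c(11 / 1001, 21 / 1001, 11 / 1001, 11 / 2001, 101 / 2001,
                  1 / 1001, 11 / 1001, 201 / 1001),
    fracSubject = c(1, 1, 11 / 21, 1, 1, 1, 11 / 111, 1),
    stringsAsFactors = FALSE)
}

goldenCgiHits <- function() {
  data.frame(
    queryIndex = c(1L, 2L, 3L, 6L, 7L, 10L),
    subjectIndex = c(1L, 2L, 3L, 5L, 6L, 8L),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    ovStart = c(1000L, 3000L, 6900L, 1000L, 2500L, 8900L),
    ovEnd = c(1100L, 3100L, 7000L, 1050L, 2550L, 9000L),
    ovWidth = c(101L, 101L, 101L, 51L, 51L, 101L),
    fracQuery = c(101 / 1001, 101 / 1001, 101 / 2001, 51 / 1001, 51 / 101,
                  101 / 1001),
    fracSubject = c(101 / 201, 101 / 201, 101 / 201, 51 / 101, 51 / 101,
                    101 / 201),
    stringsAsFactors = FALSE)
}

goldenPromoterHits <- function() {
  data.frame(
    queryIndex = c(4L, 8L, 9L),
    subjectIndex = c(4L, 6L, 7L),
    chrom = c("chr1", "chr2", "chr2"),
    ovStart = c(8000L, 5000L, 7000L),
    ovEnd = c(8099L, 5050L, 7050L),
    ovWidth = c(100L, 51L, 51L),
    fracQuery = c(100 / 501, 51 / 1001, 1),
    fracSubject = c(1, 51 / 151, 51 / 101),
    stringsAsFactors = FALSE)
}

# per-gene TFBS counts: [3,0,2,0,0,1,0,1,0,1]
goldenTfbsCounts <- function() c(3L, 0L, 2L, 0L, 0L, 1L, 0L, 1L, 0L, 1L)

# summary of the TFBS counts, computed by hand with the interpolation
# quartile formula h = (n-1)p + 1 on the sorted counts
# 0,0,0,0,0,1,1,1,2,3
goldenTfbsSummary <- function() {
  data.frame(nQuery = 10L, nQueryWithHit = 5L, totalHits = 8L,
             min = 0, lowerQuartile = 0, mean = 0.8, median = 0.5,
             upperQuartile = 1, max = 3)
}

goldenWideNames <- function() {
  list(TFBS = c("t1;t2;t3", "", "t5;t6", "", "", "t7", "", "t8", "", "t9"),
       CGI = c("c1", "c2", "c3", "", "", "c5", "c6", "", "", "c8"),
       promoter = c("", "", "", "p4", "", "", "", "p6", "p7", ""))
}

# small random-set builder shared by property tests
randomSet <- function(n, seed, name = "set", chromSizes = c(chr1 = 1e6),
                      strandProbs = c(0.45, 0.45, 0.1)) {
  generateRegionSet(n, chromSizes = chromSizes, lengthRange = c(50, 500),
                    strandProbs = strandProbs, seed = seed, name = name)
}

allParamCombos <- function(minOverlaps = c(1L, 10L, 60L)) {
  expand.grid(type = c("any", "within", "equal"),
              ignoreStrand = c(TRUE, FALSE),
              minOverlap = minOverlaps,
              stringsAsFactors = FALSE)
}

flipStrands <- function(rs) {
  gr <- regions(rs)
  str <- as.character(strand(gr))
  flipped <- chartr("+-", "-+", str)
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = flipped)
  mcols(out) <- mcols(gr)
  RegionSet(out, name = datasetName(rs))
}
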