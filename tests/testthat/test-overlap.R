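rs1 <- function(chrom, start, end, strand = "*", name = "set") {
  RegionSet(GRanges(chrom, IRanges(start, end), strand = strand),
            name = name)
}

test_that("a partial overlap yields the intersection and its fractions", {
  q <- rs1("chr1", 100, 200, "+", "q")
  s <- rs1("chr1", 150, 250, "+", "s")
  h <- hits(findRegionOverlaps(q, s))
  expect_identical(nrow(h), 1L)
  expect_identical(h$ovStart, 150L)
  expect_identical(h$ovEnd, 200L)
  expect_identical(h$ovWidth, 51L)
  expect_equal(h$fracQuery, 51 / 101)
  expect_equal(h$fracSubject, 51 / 101)

  none <- findRegionOverlaps(q, s, OverlapParams(minOverlap = 60))
  expect_identical(nHits(none), 0L)
})

test_that("'within' is query-inside-subject and asymmetric", {
  small <- rs1("chr1", 150, 180)
  big <- rs1("chr1", 100, 200)
  p <- OverlapParams(type = "within")
  expect_identical(nHits(findRegionOverlaps(small, big, p)), 1L)
  expect_identical(nHits(findRegionOverlaps(big, small, p)), 0L)
})

test_that("strand compatibility: equal strands or either unstranded", {
  p <- OverlapParams(ignoreStrand = FALSE)
  plus <- rs1("chr1", 100, 200, "+")
  minus <- rs1("chr1", 150, 250, "-")
  star <- rs1("chr1", 150, 250, "*")
  expect_identical(nHits(findRegionOverlaps(plus, minus, p)), 0L)
  expect_identical(nHits(findRegionOverlaps(plus, star, p)), 1L)
  expect_identical(nHits(findRegionOverlaps(plus, minus)), 1L)  # default ignores
})

test_that("brute-force oracle handles the degenerate cases", {
  q <- rs1("chr1", 1, 10)
  expect_identical(nHits(bruteForceOverlaps(q, RegionSet(GRanges(),
                                                         name = "empty"))), 0L)
  eq <- bruteForceOverlaps(q, rs1("chr1", 1, 10),
                           OverlapParams(type = "equal"))
  expect_identical(nHits(eq), 1L)
  expect_equal(hits(eq)$fracQuery, 1)
  two <- bruteForceOverlaps(q, RegionSet(
    GRanges("chr1", IRanges(c(5, 20), c(6, 30))), name = "s"))
  expect_identical(nHits(two), 1L)
})

test_that("engine equals the brute-force oracle on randomized inputs", {
  combos <- allParamCombos()
  for (seed in c(1, 2, 42)) {
    q <- randomSet(200, seed = seed * 10 + 1, name = "q",
                   chromSizes = c(chr1 = 2e5, chr2 = 1e5))
    s <- randomSet(200, seed = seed * 10 + 2, name = "s",
                   chromSizes = c(chr1 = 2e5, chr2 = 1e5))
    for (i in seq_len(nrow(combos))) {
      p <- OverlapParams(minOverlap = combos$minOverlap[i],
                         type = combos$type[i],
                         ignoreStrand = combos$ignoreStrand[i])
      expect_identical(hits(findRegionOverlaps(q, s, p)),
                       hits(bruteForceOverlaps(q, s, p)),
                       info = sprintf("seed=%d combo=%d", seed, i))
    }
  }
})

test_that("engine agrees with GenomicRanges::findOverlaps as an external reference", {
  for (seed in c(5, 6)) {
    q <- randomSet(300, seed = seed * 100 + 1, name = "q")
    s <- randomSet(300, seed = seed * 100 + 2, name = "s")
    for (type in c("any", "within", "equal")) for (ig in c(TRUE, FALSE)) {
      p <- OverlapParams(minOverlap = 25, type = type, ignoreStrand = ig)
      mine <- hits(findRegionOverlaps(q, s, p))
      ref <- GenomicRanges::findOverlaps(regions(q), regions(s),
                                         minoverlap = 25, type = type,
                                         ignore.strand = ig)
      refm <- cbind(S4Vectors::queryHits(ref), S4Vectors::subjectHits(ref))
      refm <- refm[order(refm[, 1], refm[, 2]), , drop = FALSE]
      expect_identical(unname(cbind(mine$queryIndex, mine$subjectIndex)),
                       unname(refm))
    }
  }
})

test_that("hit sets are monotone in minOverlap and nested across types", {
  q <- randomSet(150, seed = 11, name = "q")
  s <- randomSet(150, seed = 12, name = "s")
  key <- function(ht) paste(hits(ht)$queryIndex, hits(ht)$subjectIndex)
  prev <- NULL
  for (m in c(1, 25, 100, 400)) {
    cur <- key(findRegionOverlaps(q, s, OverlapParams(minOverlap = m)))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  any_ <- key(findRegionOverlaps(q, s, OverlapParams(type = "any")))
  within_ <- key(findRegionOverlaps(q, s, OverlapParams(type = "within")))
  equal_ <- key(findRegionOverlaps(q, s, OverlapParams(type = "equal")))
  expect_true(all(equal_ %in% within_))
  expect_true(all(within_ %in% any_))
})

test_that("'any' overlap counts are symmetric in query and subject", {
  q <- randomSet(120, seed = 21, name = "q")
  s <- randomSet(120, seed = 22, name = "s")
  for (m in c(1, 40)) {
    p <- OverlapParams(minOverlap = m)
    expect_identical(nHits(findRegionOverlaps(q, s, p)),
                     nHits(findRegionOverlaps(s, q, p)))
  }
})

test_that("fracQuery is 1 exactly when the query lies inside the subject", {
  q <- randomSet(150, seed = 31, name = "q")
  s <- randomSet(150, seed = 32, name = "s")
  h <- hits(findRegionOverlaps(q, s))
  qgr <- regions(q); sgr <- regions(s)
  contained <- start(qgr)[h$queryIndex] >= start(sgr)[h$subjectIndex] &
    end(qgr)[h$queryIndex] <= end(sgr)[h$subjectIndex]
  expect_identical(h$fracQuery == 1, contained)
})

test_that("annotateHits joins names, coordinates and generated identifiers", {
  ws <- makeToyWorkspace()
  ht <- findRegionOverlaps(querySet(ws), subjectSet(ws, "TFBS"))
  ann <- annotateHits(ht, querySet(ws), subjectSet(ws, "TFBS"))
  expect_identical(ann$queryName[1], "g1")
  expect_identical(ann$subjectName[1], "t1")
  expect_identical(ann$queryStart, c(1000L, 1000L, 1000L, 5000L, 5000L,
                                     1000L, 5000L, 8000L))
  # unnamed regions fall back to "<set>_<index>"
  q <- rs1("chr1", 100, 200, name = "query")
  s <- rs1("chr1", 150, 250, name = "subject")
  ann2 <- annotateHits(findRegionOverlaps(q, s), q, s)
  expect_identical(ann2$queryName, "query_1")
  expect_identical(ann2$subjectName, "subject_1")

  expect_identical(nrow(annotateHits(findRegionOverlaps(
    q, RegionSet(GRanges(), name = "e")), q,
    RegionSet(GRanges(), name = "e"))), 0L)
  expect_error(annotateHits(ht, q, s), "exceed")
})
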