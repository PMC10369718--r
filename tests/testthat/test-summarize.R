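toyTfbsTable <- function() {
  ws <- makeToyWorkspace()
  findRegionOverlaps(querySet(ws), subjectSet(ws, "TFBS"))
}

test_that("per-query counts conserve the total number of hits", {
  ht <- toyTfbsTable()
  counts <- countOverlapsPerQuery(ht, 10)
  expect_identical(counts, goldenTfbsCounts())
  expect_identical(sum(counts), nHits(ht))
  empty <- findRegionOverlaps(
    RegionSet(GRanges("chr9", IRanges(1, 10)), name = "q"),
    RegionSet(GRanges(), name = "s"))
  expect_identical(countOverlapsPerQuery(empty, 4), rep(0L, 4))
})

test_that("summary statistics use interpolated quartiles", {
  # hand evaluation of h = (n-1)p + 1 on sorted 0,1,4,30:
  # p=.25 -> h=1.75 -> 0 + 0.75*(1-0) = 0.75
  # p=.75 -> h=3.25 -> 4 + 0.25*(30-4) = 10.5
  s <- summaryStats(c(0, 1, 4, 30))
  expect_equal(s$min, 0)
  expect_equal(s$lowerQuartile, 0.75)
  expect_equal(s$mean, 8.75)
  expect_equal(s$median, 2.5)
  expect_equal(s$upperQuartile, 10.5)
  expect_equal(s$max, 30)
  expect_identical(s$nQueryWithHit, 3L)
  expect_identical(s$totalHits, 35)

  const <- summaryStats(c(5, 5, 5))
  expect_true(all(const[c("min", "lowerQuartile", "mean", "median",
                          "upperQuartile", "max")] == 5))
  expect_error(summaryStats(numeric(0)), "non-empty")
})

test_that("summary statistics are permutation invariant and ordered", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rpois(50, 3))
    perm <- withr::with_seed(seed + 100, sample(x))
    expect_equal(summaryStats(x), summaryStats(perm))
    s <- summaryStats(x)
    expect_true(s$min <= s$lowerQuartile && s$lowerQuartile <= s$median &&
                s$median <= s$upperQuartile && s$upperQuartile <= s$max)
    expect_equal(s$mean, s$totalHits / s$nQuery)
  }
})

test_that("workspace summary matches the hand-enumerated toy values", {
  ws <- makeToyWorkspace()
  hts <- overlapWorkspace(ws)
  s <- summarizeWorkspace(ws, hts)
  expect_identical(s$dataset, c("TFBS", "CGI", "promoter", "overall"))
  tf <- s[s$dataset == "TFBS", names(goldenTfbsSummary())]
  rownames(tf) <- NULL
  expect_equal(tf, goldenTfbsSummary())
  ov <- s[s$dataset == "overall", ]
  expect_identical(ov$nQueryWithHit, 9L)
  expect_equal(ov$mean, 1.7)
  expect_identical(ov$totalHits, 17L)
  expect_error(summarizeWorkspace(ws, list()), "no subject")
})

test_that("single-subject drill-down returns annotated subject regions", {
  ws <- makeToyWorkspace()
  ht <- toyTfbsTable()
  tf <- subjectsForQuery(ht, 1, subjectSet(ws, "TFBS"))
  expect_identical(tf$subjectName, c("t1", "t2", "t3"))
  expect_identical(tf$ovWidth, c(11L, 21L, 11L))
  expect_true(all(tf$chrom == "chr1"))
  expect_identical(nrow(subjectsForQuery(ht, 5, subjectSet(ws, "TFBS"))), 0L)
})

test_that("histogram binning conserves the number of queries", {
  hb <- histogramBins(c(0, 0, 1, 3, 3))
  expect_identical(hb$table$label, c("0", "1", "2", "3"))
  expect_identical(hb$table$frequency, c(2L, 1L, 0L, 2L))
  expect_equal(hb$median, 1)

  custom <- histogramBins(c(0, 1, 2, 3), edges = c(0, 2, 4))
  expect_identical(custom$table$frequency, c(2L, 2L))

  expect_error(histogramBins(c(1, 2), edges = c(4, 2, 0)), "increasing")
  expect_error(histogramBins(c(1, 9), edges = c(0, 2, 4)), "cover")

  for (seed in 1:3) {
    x <- withr::with_seed(seed, rpois(200, 10))
    expect_identical(sum(histogramBins(x)$table$frequency), length(x))
  }
  wide <- histogramBins(withr::with_seed(4, rpois(500, 60)))
  expect_identical(nrow(wide$table), 30L)  # equal-width fallback
  expect_identical(sum(wide$table$frequency), 500L)
})
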