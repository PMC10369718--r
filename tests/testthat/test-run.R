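writeToyFiles <- function(dir) {
  ws <- makeToyWorkspace()
  for (nm in names(datasets(ws)))
    writeBed(datasets(ws)[[nm]], file.path(dir, paste0(nm, ".bed")))
  dir
}

toyConfig <- function(dir, out, ...) {
  modifyList(list(directory = dir, query = "genes", outDir = out), list(...))
}

test_that("the overlap pipeline writes its complete file set", {
  d <- withr::local_tempdir(); out <- withr::local_tempdir()
  writeToyFiles(d)
  res <- suppressMessages(runOverlap(toyConfig(d, out)))
  expect_true(all(file.exists(file.path(out,
    c("long_table.csv", "wide_table.csv", "summary.csv",
      "histogram_CGI.csv", "histogram_promoter.csv",
      "histogram_TFBS.csv")))))
  expect_gte(length(res$files), 4L)
  s <- read.csv(file.path(out, "summary.csv"))
  expect_identical(s$totalHits[s$dataset == "overall"], 17L)
  long <- read.csv(file.path(out, "long_table.csv"))
  expect_identical(nrow(long), 17L)
})

test_that("reruns with the same config are byte-identical", {
  d <- withr::local_tempdir()
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  writeToyFiles(d)
  suppressMessages(runOverlap(toyConfig(d, out1)))
  suppressMessages(runOverlap(toyConfig(d, out2)))
  for (f in list.files(out1)) {
    a <- file.path(out1, f); b <- file.path(out2, f)
    expect_identical(readBin(a, "raw", file.size(a)),
                     readBin(b, "raw", file.size(b)), info = f)
  }
})

test_that("a failing run removes its partial outputs", {
  d <- withr::local_tempdir(); out <- withr::local_tempdir()
  writeToyFiles(d)
  expect_error(suppressMessages(
    runOverlap(toyConfig(d, out, query = "missing"))), "query")
  expect_identical(list.files(out), character(0))
})

test_that("the coverage pipeline honors the bin count", {
  d <- withr::local_tempdir(); out <- withr::local_tempdir()
  writeToyFiles(d)
  suppressMessages(suppressWarnings(
    runCoverage(toyConfig(d, out, nBins = 10))))
  m <- read.csv(file.path(out, "coverage_matrix_TFBS.csv"))
  expect_identical(ncol(m), 11L)  # queryIndex + 10 bins
  expect_true(file.exists(file.path(out, "profile_TFBS.csv")))

  out2 <- withr::local_tempdir()
  expect_error(suppressMessages(suppressWarnings(
    runCoverage(toyConfig(d, out2, nBins = 5000)))), "shorter")
  expect_identical(list.files(out2), character(0))
})

test_that("overlap parameters flow through the config", {
  d <- withr::local_tempdir(); out <- withr::local_tempdir()
  writeToyFiles(d)
  res <- suppressMessages(runOverlap(
    toyConfig(d, out, minOverlap = 60, type = "any")))
  # hand count of toy intersections of >= 60 bases: t6 (101), t9 (201),
  # c1-c3 and c8 (101 each), p4 (100)
  expect_identical(res$summary$totalHits[res$summary$dataset == "overall"],
                   7L)
})

test_that("YAML configs round-trip with defaults and reject unknown keys", {
  d <- withr::local_tempdir(); out <- withr::local_tempdir()
  writeToyFiles(d)
  cfgFile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    sprintf("directory: %s", d),
    "query: genes",
    sprintf("outDir: %s", out),
    "minOverlap: 2"), cfgFile)
  cfg <- readRunConfig(cfgFile)
  expect_identical(cfg$minOverlap, 2L)
  expect_identical(cfg$type, "any")      # default preserved
  suppressMessages(runOverlap(cfg))
  expect_true(file.exists(file.path(out, "long_table.csv")))

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("minOvrlap: 2", bad)
  expect_error(readRunConfig(bad), "unknown config key")
})

test_that("fixture emission is reproducible and re-ingests cleanly", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  suppressMessages(runFixtures(list(n = 40, seed = 5, outDir = out1)))
  suppressMessages(runFixtures(list(n = 40, seed = 5, outDir = out2)))
  for (f in c("query.bed", "subjects.bed")) {
    a <- file.path(out1, f); b <- file.path(out2, f)
    expect_identical(readBin(a, "raw", file.size(a)),
                     readBin(b, "raw", file.size(b)))
  }
  q <- readBed(file.path(out1, "query.bed"))
  expect_identical(nRegions(q), 40L)
  gen <- generateRegionSet(40, seed = 5, name = "query")
  expect_identical(granges(regions(q)), granges(regions(gen)))
  expect_identical(regionNames(q), regionNames(gen))

  out3 <- withr::local_tempdir()
  suppressMessages(runFixtures(list(n = 0, seed = 1, outDir = out3)))
  expect_identical(file.size(file.path(out3, "query.bed")), 0)
})
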