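# End-to-end pipeline runners behind the command-line interface
# (inst/scripts/genomic-overlaps.R). Each runner takes a plain config
# list -- typically parsed from a YAML file with readRunConfig() and
# overridden by CLI flags -- and writes its result files into the
# configured output directory. On error, partially written outputs are
# removed so a run directory is either complete or empty.

.defaultConfig <- list(
  inputs = NULL,          # list of list(path=, format=, name=, ...) entries
  directory = NULL,       # alternative: scan a directory
  query = NULL,
  subjects = NULL,
  chromStyle = NULL,      # "ucsc"/"ensembl" to normalize all datasets
  dedup = FALSE,
  resize = NULL,          # list(anchor=, upstream=, downstream=, datasets=)
  minOverlap = 1,
  type = "any",
  ignoreStrand = TRUE,
  nBins = 100,
  histEdges = NULL,
  outDir = ".",
  plots = FALSE,
  seed = 1,
  n = 100                 # fixtures only
)

#' Read a YAML run configuration
#'
#' Unknown keys are rejected so typos fail loudly; missing keys take the
#' documented defaults (see [runOverlap()]).
#'
#' @param path Path to a YAML file.
#' @return A config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.defaultConfig))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(.defaultConfig, cfg)
}

.mergeConfig <- function(config) {
  utils::modifyList(.defaultConfig, config)
}

.configParams <- function(cfg) {
  OverlapParams(minOverlap = cfg$minOverlap, type = cfg$type,
                ignoreStrand = isTRUE(cfg$ignoreStrand))
}

# Assemble the workspace a config describes: read, normalize, dedup,
# resize; every step is logged.
.buildWorkspace <- function(cfg) {
  if (!is.null(cfg$directory)) {
    ws <- scanDirectory(cfg$directory, queryName = cfg$query,
                        subjectNames = cfg$subjects)
  } else if (!is.null(cfg$inputs)) {
    ds <- list()
    for (inp in cfg$inputs) {
      fmt <- inp$format
      if (is.null(fmt)) fmt <- tolower(tools::file_ext(inp$path))
      rs <- switch(fmt,
        bed = readBed(inp$path, name = inp$name),
        gff = , gff3 = , gtf = readGff(inp$path,
          featureTypes = inp$featureTypes,
          nameAttribute = if (is.null(inp$nameAttribute)) "ID"
                          else inp$nameAttribute,
          name = inp$name, format = if (fmt == "gff") "gff3" else fmt),
        csv = , table = readRegionTable(inp$path, name = inp$name),
        stop("unsupported input format: ", fmt))
      ds[[datasetName(rs)]] <- rs
    }
    queryName <- if (is.null(cfg$query)) names(ds)[1] else cfg$query
    subjects <- if (is.null(cfg$subjects)) setdiff(names(ds), queryName)
                else cfg$subjects
    ws <- OverlapWorkspace(ds, queryName = queryName,
                           subjectNames = subjects)
  } else stop("config must set either 'inputs' or 'directory'")
  .logMsg(sprintf("datasets: %s (query: %s)",
                  paste(names(datasets(ws)), collapse = ", "), queryName(ws)))
  for (issue in validateWorkspace(ws)) .logMsg("validation: ", issue)

  if (!is.null(cfg$chromStyle))
    ws@datasets <- lapply(ws@datasets, normalizeChromNames,
                          style = cfg$chromStyle)
  if (isTRUE(cfg$dedup)) {
    ws@datasets <- lapply(ws@datasets, function(rs) {
      d <- deduplicateRegions(rs)
      d$regionSet
    })
  }
  if (!is.null(cfg$resize)) {
    r <- cfg$resize
    targets <- if (is.null(r$datasets)) queryName(ws) else r$datasets
    for (nm in targets) {
      ws@datasets[[nm]] <- resizeRegions(
        ws@datasets[[nm]],
        anchor = if (is.null(r$anchor)) "tss" else r$anchor,
        upstream = if (is.null(r$upstream)) 0 else r$upstream,
        downstream = if (is.null(r$downstream)) 0 else r$downstream)
      .logMsg("resized dataset '", nm, "'")
    }
  }
  ws
}

.withCleanup <- function(outDir, body) {
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }
  tryCatch(body(note), error = function(e) {
    suppressWarnings(file.remove(written[file.exists(written)]))
    stop("run failed (partial outputs removed): ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full overlap pipeline
#'
#' Ingests the configured datasets, applies the configured normalization,
#' deduplication and resizing, runs the overlap engine against every
#' subject dataset, and writes into `outDir`: `long_table.csv` (all hits,
#' annotated), `wide_table.csv` (one row per query region),
#' `summary.csv`, one `histogram_<subject>.csv` per subject, and -- when
#' `plots` is enabled -- `summary_bars.png` plus one
#' `histogram_<subject>.png` per subject. The summary is also logged.
#' Identical configs produce byte-identical tables.
#'
#' @param config Config list (see [readRunConfig()]); recognized keys:
#'   `inputs` or `directory`, `query`, `subjects`, `chromStyle`, `dedup`,
#'   `resize`, `minOverlap`, `type`, `ignoreStrand`, `nBins`,
#'   `histEdges`, `outDir`, `plots`.
#' @return Invisibly, a list with `files` (paths written), `summary`
#'   (the summary `data.frame`) and `hitTables`.
#' @export
runOverlap <- function(config = list()) {
  cfg <- .mergeConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  .withCleanup(cfg$outDir, function(note) {
    ws <- .buildWorkspace(cfg)
    params <- .configParams(cfg)
    .logMsg(sprintf("overlap parameters: minOverlap=%d, type=%s, ignoreStrand=%s",
                    params@minOverlap, params@type, params@ignoreStrand))
    hts <- overlapWorkspace(ws, params)
    q <- querySet(ws)
    long <- do.call(rbind, lapply(names(hts), function(sn)
      annotateHits(hts[[sn]], q, subjectSet(ws, sn))))
    files <- c(
      note(writeLongTable(long, file.path(cfg$outDir, "long_table.csv"))),
      note(writeWideTable(hts, ws, file.path(cfg$outDir, "wide_table.csv"))))
    summary <- summarizeWorkspace(ws, hts)
    files <- c(files,
      note(.writeCsv(summary, file.path(cfg$outDir, "summary.csv"))))
    for (sn in names(hts)) {
      counts <- countOverlapsPerQuery(hts[[sn]], length(regions(q)))
      hb <- histogramBins(counts, edges = cfg$histEdges)
      files <- c(files, note(.writeCsv(
        hb$table, file.path(cfg$outDir, paste0("histogram_", sn, ".csv")))))
      if (isTRUE(cfg$plots))
        files <- c(files, note(plotHistogram(
          hb, path = file.path(cfg$outDir, paste0("histogram_", sn, ".png")))))
    }
    if (isTRUE(cfg$plots))
      files <- c(files, note(plotSummaryBars(
        summary, file.path(cfg$outDir, "summary_bars.png"))))
    for (i in seq_len(nrow(summary)))
      .logMsg(sprintf(
        "summary %s: %d/%d queries with hit, %d hits, mean %.3f/query",
        summary$dataset[i], summary$nQueryWithHit[i], summary$nQuery[i],
        summary$totalHits[i], summary$mean[i]))
    invisible(list(files = files, summary = summary, hitTables = hts))
  })
}

#' Run the binned coverage pipeline
#'
#' Computes the [coverageMatrix()] of the query set against the first
#' configured subject (or each subject in `subjects`) and writes
#' `coverage_matrix_<subject>.csv`, `profile_<subject>.csv`, and
#' optionally `profile_<subject>.png`.
#'
#' @inheritParams runOverlap
#' @return Invisibly, a list with `files` and `matrices`.
#' @export
runCoverage <- function(config = list()) {
  cfg <- .mergeConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  .withCleanup(cfg$outDir, function(note) {
    ws <- .buildWorkspace(cfg)
    params <- .configParams(cfg)
    q <- querySet(ws)
    files <- character(0)
    cms <- list()
    for (sn in subjectNames(ws)) {
      cm <- coverageMatrix(q, subjectSet(ws, sn), nBins = cfg$nBins,
                           params = params)
      if (nrow(coverageValues(cm)) == 0L)
        stop("all ", length(regions(q)), " query regions are shorter than ",
             cfg$nBins, " bp; no coverage rows left")
      cms[[sn]] <- cm
      files <- c(files,
        note(writeCoverageMatrix(cm, file.path(
          cfg$outDir, paste0("coverage_matrix_", sn, ".csv")))),
        note(writeProfileTable(cm, file.path(
          cfg$outDir, paste0("profile_", sn, ".csv")))))
      if (isTRUE(cfg$plots))
        files <- c(files, note(plotCoverageProfile(cm, file.path(
          cfg$outDir, paste0("profile_", sn, ".png")))))
      .logMsg(sprintf("coverage %s: %d bins, %d kept / %d dropped queries",
                      sn, cfg$nBins, nrow(coverageValues(cm)),
                      cm@nDroppedShort))
    }
    invisible(list(files = files, matrices = cms))
  })
}

#' Emit synthetic fixture files
#'
#' Generates a random query set and a Poisson-placed subject set (see
#' [generateRegionSet()] and [generateSubjectsFor()]) and writes them as
#' BED files `query.bed` and `subjects.bed`, ready for re-ingestion.
#'
#' @inheritParams runOverlap
#' @return Invisibly, the paths written.
#' @export
runFixtures <- function(config = list()) {
  cfg <- .mergeConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  .withCleanup(cfg$outDir, function(note) {
    q <- generateRegionSet(cfg$n, seed = cfg$seed, name = "query")
    s <- generateSubjectsFor(q, rate = 2, seed = cfg$seed + 1,
                             name = "subjects")$subjects
    files <- c(note(writeBed(q, file.path(cfg$outDir, "query.bed"))),
               note(writeBed(s, file.path(cfg$outDir, "subjects.bed"))))
    .logMsg(sprintf("wrote %d query and %d subject fixture region(s)",
                    nRegions(q), nRegions(s)))
    invisible(files)
  })
}
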