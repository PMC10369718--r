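#' Column mapping for delimited region tables
#'
#' Describes how the columns of a generic delimited file (CSV/TSV) map to
#' region fields, and which coordinate convention the file uses:
#' `"onebased"` for 1-based closed intervals (GFF-style, taken verbatim)
#' or `"bed0"` for 0-based half-open intervals (BED-style, shifted to
#' 1-based closed on read).
#'
#' @param chrom,start,end Required column names.
#' @param strand,name,score Optional column names (`NULL` to omit).
#' @param convention `"onebased"` (default) or `"bed0"`.
#' @return A list with class `"ColumnMap"`.
#' @examples
#' columnMap("chrom", "start", "end", strand = "strand")
#' @export
columnMap <- function(chrom = "chrom", start = "start", end = "end",
                      strand = NULL, name = NULL, score = NULL,
                      convention = c("onebased", "bed0")) {
  convention <- match.arg(convention)
  req <- c(chrom, start, end)
  if (length(req) != 3L || any(!nzchar(req)) || anyDuplicated(req))
    stop("chrom/start/end column names must be distinct and non-empty")
  structure(list(chrom = chrom, start = start, end = end, strand = strand,
                 name = name, score = score, convention = convention),
            class = "ColumnMap")
}

.buildRegionSet <- function(chrom, start, end, strand, name, score,
                            setName, src) {
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  if (!all(is.na(name))) mcols(gr)$name <- name
  if (!all(is.na(score))) mcols(gr)$score <- score
  RegionSet(gr, name = setName, source = src)
}

#' Read a BED file into a RegionSet
#'
#' BED is 0-based, half-open: a line `chr1 99 200` covers bases 100..200
#' in 1-based closed coordinates, so `[chromStart, chromEnd)` becomes
#' `[chromStart + 1, chromEnd]` on read. Columns 4-6 (name, score, strand)
#' are used when present; a missing strand column yields `"*"`.
#'
#' @param path Path to a BED file (3-6 tab-separated columns; `track`,
#'   `browser` and `#` comment lines are skipped).
#' @param name Dataset name; defaults to the file stem.
#' @return A [RegionSet].
#' @seealso [writeBed()], [readGff()], [readRegionTable()]
#' @export
readBed <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))

  # Validate line by line before handing off to the parser, so malformed
  # input is reported with its line number and inverted intervals are
  # caught explicitly.
  lines <- readLines(path)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
  nField <- NULL
  for (i in which(!skip)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (is.null(nField)) nField <- length(f)
    else if (length(f) != nField)
      stop(sprintf(
        "malformed BED line %d in '%s': %d columns where earlier lines have %d",
        i, path, length(f), nField))
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d in '%s': fewer than 3 columns",
                   i, path))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("malformed BED line %d in '%s': non-numeric coordinates",
                   i, path))
    if (e <= s)
      stop(sprintf("malformed BED line %d in '%s': chromEnd (%s) <= chromStart (%s)",
                   i, path, f[3], f[2]))
  }
  if (all(skip)) {
    gr <- GRanges()
  } else {
    gr <- rtracklayer::import(path, format = "bed")
  }
  rs <- RegionSet(gr, name = name,
                  source = list(path = path, format = "bed"))
  validObject(rs)
  rs
}

#' Read a GFF3 or GTF file into a RegionSet
#'
#' GFF coordinates are already 1-based closed and are taken verbatim.
#' Rows may be restricted to given feature types (column 3), and the
#' region name is taken from an attribute key, falling back to a generated
#' `"row<N>"` identifier where the attribute is absent.
#'
#' @param path Path to a `.gff`/`.gff3`/`.gtf` file. The GTF attribute
#'   dialect (`key "value";`) and the GFF3 dialect (`key=value`) are both
#'   supported, chosen by file extension unless `format` is given.
#' @param featureTypes Optional character vector; keep only rows whose
#'   feature type is in this set (e.g. `"gene"`).
#' @param nameAttribute Attribute key holding the region name
#'   (default `"ID"`; use e.g. `"gene_id"` for GTF).
#' @param name Dataset name; defaults to the file stem.
#' @param format `"gff3"` or `"gtf"`; inferred from the extension.
#' @return A [RegionSet].
#' @export
readGff <- function(path, featureTypes = NULL, nameAttribute = "ID",
                    name = NULL, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gtf") "gtf" else "gff3"
  }
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e)
                   stop("failed to parse '", path, "' as ", format, ": ",
                        conditionMessage(e)))
  if (!is.null(featureTypes) && length(gr))
    gr <- gr[as.character(gr$type) %in% featureTypes]

  nm <- if (nameAttribute %in% names(mcols(gr))) {
    as.character(mcols(gr)[[nameAttribute]])
  } else {
    if (length(gr))
      warning("attribute '", nameAttribute, "' not found in '", path,
              "'; using generated row identifiers")
    rep(NA_character_, length(gr))
  }
  fallback <- paste0("row", seq_along(gr))
  nm <- ifelse(is.na(nm) | !nzchar(nm), fallback, nm)
  mc <- S4Vectors::DataFrame(name = nm)
  if ("score" %in% names(mcols(gr))) mc$score <- mcols(gr)$score
  mcols(gr) <- mc
  rs <- RegionSet(gr, name = name,
                  source = list(path = path, format = format,
                                featureTypes = featureTypes,
                                nameAttribute = nameAttribute))
  validObject(rs)
  rs
}

.detectDelimiter <- function(path) {
  header <- readLines(path, n = 1L)
  cand <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
            ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))),
            "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))))
  if (all(cand == 0)) stop("could not detect a delimiter in '", path,
                           "' (tried ',', ';', tab)")
  names(cand)[which.max(cand)]
}

#' Read a delimited table of regions
#'
#' Generic reader for CSV/TSV-like files with a header row, using a
#' [columnMap()] to locate the coordinate columns and to state the file's
#' coordinate convention.
#'
#' @param path Path to the file.
#' @param map A [columnMap()].
#' @param delimiter Field delimiter; auto-detected from `","`, `";"`,
#'   `"\t"` when `NULL`.
#' @param name Dataset name; defaults to the file stem.
#' @return A [RegionSet].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("chrom,start,end,strand", "1,100,200,+"), tf)
#' readRegionTable(tf, columnMap())
#' @export
readRegionTable <- function(path, map = columnMap(), delimiter = NULL,
                            name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!inherits(map, "ColumnMap")) stop("'map' must be a columnMap()")
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  if (is.null(delimiter)) delimiter <- .detectDelimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(map$chrom, map$start, map$end)
  opt <- c(map$strand, map$name, map$score)
  missing <- setdiff(c(need, opt), names(df))
  if (length(missing))
    stop(sprintf("column(s) %s not found in '%s'; available: %s",
                 paste(sQuote(missing), collapse = ", "), path,
                 paste(sQuote(names(df)), collapse = ", ")))
  start <- as.numeric(df[[map$start]])
  end <- as.numeric(df[[map$end]])
  if (map$convention == "bed0") start <- start + 1
  strand <- if (!is.null(map$strand)) as.character(df[[map$strand]])
            else rep("*", nrow(df))
  nm <- if (!is.null(map$name)) as.character(df[[map$name]])
        else rep(NA_character_, nrow(df))
  sc <- if (!is.null(map$score)) as.numeric(df[[map$score]])
        else rep(NA_real_, nrow(df))
  rs <- .buildRegionSet(as.character(df[[map$chrom]]), start, end, strand,
                        nm, sc, name,
                        list(path = path, format = "table",
                             delimiter = delimiter,
                             convention = map$convention))
  validObject(rs)
  rs
}

#' Scan a directory and assemble a workspace
#'
#' Every `*.bed`, `*.gff`/`*.gff3`/`*.gtf` and `*.csv` file in `dir`
#' becomes one dataset named after its file stem. Datasets are ordered
#' alphabetically; the first is designated query and the rest subjects
#' unless overridden. Unreadable files are skipped with a warning.
#'
#' @param dir Directory to scan (not recursive).
#' @param queryName Optional query dataset name (default: alphabetically
#'   first).
#' @param subjectNames Optional subject names (default: all others).
#' @param gffFeatureTypes,gffNameAttribute Passed to [readGff()].
#' @param csvMap [columnMap()] used for `.csv` files.
#' @return An [OverlapWorkspace].
#' @export
scanDirectory <- function(dir, queryName = NULL, subjectNames = NULL,
                          gffFeatureTypes = NULL, gffNameAttribute = "ID",
                          csvMap = columnMap()) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.(bed|gff|gff3|gtf|csv)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- files[order(tolower(basename(files)))]
  if (!length(files))
    stop("no region files (*.bed, *.gff, *.gff3, *.gtf, *.csv) in '", dir, "'")
  ds <- list()
  for (f in files) {
    ext <- tolower(tools::file_ext(f))
    rs <- tryCatch(
      switch(ext,
             bed = readBed(f),
             gff = , gff3 = , gtf = readGff(f, featureTypes = gffFeatureTypes,
                                            nameAttribute = gffNameAttribute),
             csv = readRegionTable(f, map = csvMap)),
      error = function(e) {
        warning("skipping unreadable file '", f, "': ", conditionMessage(e))
        NULL
      })
    if (!is.null(rs)) ds[[datasetName(rs)]] <- rs
  }
  if (!length(ds)) stop("no parseable region files in '", dir, "'")
  if (is.null(queryName)) queryName <- names(ds)[1]
  if (is.null(subjectNames)) subjectNames <- setdiff(names(ds), queryName)
  ws <- OverlapWorkspace(ds, queryName = queryName,
                         subjectNames = subjectNames)
  ws@log <- sprintf("read %d dataset(s) from %s: %s", length(ds), dir,
                    paste(names(ds), collapse = ", "))
  ws
}

#' Normalize chromosome names to one naming style
#'
#' Translates canonical chromosome names between the UCSC (`chr1`, `chrM`)
#' and Ensembl (`1`, `MT`) dialects. Names already in the target style are
#' untouched; contigs that are not canonical chromosomes (scaffolds,
#' haplotypes) are kept verbatim, each with one warning.
#'
#' @param rs A [RegionSet].
#' @param style Target style, `"ucsc"` or `"ensembl"`.
#' @return The renamed `RegionSet` with its `chromStyle` updated.
#' @examples
#' rs <- RegionSet(GenomicRanges::GRanges("1", IRanges::IRanges(1, 10)))
#' chromStyle(normalizeChromNames(rs, "ucsc"))
#' @export
normalizeChromNames <- function(rs, style = c("ucsc", "ensembl")) {
  style <- match.arg(style)
  stopifnot(is(rs, "RegionSet"))
  gr <- rs@ranges
  old <- as.character(seqnames(gr))
  new <- if (style == "ucsc") .toUcscName(old) else .toEnsemblName(old)
  recognized <- if (style == "ucsc") .isUcscName(new) else .isEnsemblName(new)
  for (u in unique(new[!recognized]))
    warning("chromosome name '", u, "' not recognized; kept verbatim")
  out <- GRanges(new, IRanges(start(gr), end(gr)), strand = strand(gr))
  mcols(out) <- mcols(gr)
  rs@ranges <- out
  rs@chromStyle <- if (all(recognized) || length(new) == 0L) style
                   else .detectChromStyle(new)
  rs
}

#' Remove duplicated intervals from a RegionSet
#'
#' Regions identical in (chromosome, start, end, strand) collapse to their
#' first occurrence; name and score are deliberately ignored, since
#' duplicates in annotation dumps typically differ only in metadata.
#' Relative order of the survivors is preserved.
#'
#' @param rs A [RegionSet].
#' @return A list with elements `regionSet` (deduplicated) and `nRemoved`.
#' @export
deduplicateRegions <- function(rs) {
  stopifnot(is(rs, "RegionSet"))
  dup <- duplicated(granges(rs@ranges))
  n <- sum(dup)
  if (n > 0) .logMsg(sprintf("removed %d duplicated region(s) from '%s'",
                             n, rs@name))
  list(regionSet = rs[!dup], nRemoved = n)
}

#' Write a RegionSet as BED
#'
#' Converts back to BED's 0-based half-open convention
#' (`chromStart = start - 1`, `chromEnd = end`); name, score and strand
#' are written when any region carries them.
#'
#' @param rs A [RegionSet].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeBed <- function(rs, path) {
  stopifnot(is(rs, "RegionSet"))
  gr <- rs@ranges
  chrom <- as.character(seqnames(gr))
  cols <- list(chrom = chrom, start = start(gr) - 1L, end = end(gr))
  nm <- mcols(gr)$name
  sc <- mcols(gr)$score
  str <- as.character(strand(gr))
  hasExtra <- !is.null(nm) || !is.null(sc) || any(str != "*")
  if (hasExtra) {
    cols$name <- if (is.null(nm)) rep(".", length(gr)) else
      ifelse(is.na(nm), ".", as.character(nm))
    cols$score <- if (is.null(sc)) rep(0, length(gr)) else
      ifelse(is.na(sc), 0, sc)
    cols$strand <- ifelse(str == "*", ".", str)
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path Two-column whitespace-delimited file: chromosome name,
#'   length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chrom.sizes file must have two columns")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Long and wide result tables
#'
#' The *long* table has one row per hit with the full coordinates of both
#' partners, the intersection interval, its width and the overlapped
#' fraction of each region (the output of [annotateHits()], possibly
#' concatenated over several subject datasets). The *wide* table has one
#' row per query region -- hit-less queries included -- and, per subject
#' dataset, a presence flag, the overlap count and a `";"`-joined list of
#' overlapping subject names. Both are written as deterministic CSV:
#' identical inputs give byte-identical files.
#'
#' @param annotated A `data.frame` from [annotateHits()] (or several
#'   `rbind`-ed together).
#' @param path Output path.
#' @return The path (writers, invisibly); the wide `data.frame`
#'   (`makeWideTable`).
#' @seealso [annotateHits()], [findRegionOverlaps()]
#' @export
writeLongTable <- function(annotated, path) {
  stopifnot(is.data.frame(annotated))
  ord <- order(annotated$subjectDataset, annotated$queryIndex,
               annotated$subjectIndex)
  .writeCsv(annotated[ord, , drop = FALSE], path)
}

#' @rdname writeLongTable
#' @param hitTables Named list of [HitTable] objects, one per subject
#'   dataset (names = dataset names).
#' @param ws The [OverlapWorkspace] the tables were computed from.
#' @export
makeWideTable <- function(hitTables, ws) {
  stopifnot(is(ws, "OverlapWorkspace"))
  q <- querySet(ws)
  gr <- regions(q)
  out <- data.frame(
    queryIndex = seq_along(gr),
    queryName = regionNames(q),
    chrom = as.character(seqnames(gr)),
    start = start(gr), end = end(gr),
    strand = as.character(strand(gr)),
    stringsAsFactors = FALSE)
  for (sn in names(hitTables)) {
    ht <- hitTables[[sn]]
    stopifnot(is(ht, "HitTable"))
    h <- ht@hits
    counts <- tabulate(h$queryIndex, nbins = length(gr))
    snames <- regionNames(subjectSet(ws, sn))
    joined <- vapply(seq_along(gr), function(i) {
      idx <- h$subjectIndex[h$queryIndex == i]
      paste(snames[idx], collapse = ";")
    }, character(1))
    out[[paste0(sn, "_present")]] <- counts > 0L
    out[[paste0(sn, "_count")]] <- counts
    out[[paste0(sn, "_names")]] <- joined
  }
  out[order(out$queryIndex), , drop = FALSE]
}

#' @rdname writeLongTable
#' @export
writeWideTable <- function(hitTables, ws, path) {
  .writeCsv(makeWideTable(hitTables, ws), path)
}
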