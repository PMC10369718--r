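#' Split a region into equally sized bins
#'
#' Tiles a region of width W into `nBins` sub-intervals: bin i (1-based)
#' covers `[start + floor((i-1) W / n), start + floor(i W / n) - 1]`. The
#' bins are disjoint, exactly cover the region, and their widths differ
#' by at most one base. Regions shorter than `nBins` cannot be tiled into
#' non-empty bins and raise an error.
#'
#' @param r A length-1 `GRanges` (or a [RegionSet] with one region).
#' @param nBins Number of bins (default 100).
#' @return An [IRanges::IRanges] of length `nBins` in genomic order.
#' @examples
#' binRegion(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000)), 100)
#' @export
binRegion <- function(r, nBins = 100) {
  if (is(r, "RegionSet")) r <- regions(r)
  stopifnot(is(r, "GRanges"), length(r) == 1L)
  nBins <- as.integer(nBins)
  if (nBins < 1L) stop("'nBins' must be >= 1")
  W <- width(r)
  if (W < nBins)
    stop("region width (", W, ") is smaller than nBins (", nBins, ")")
  i <- seq_len(nBins)
  s <- start(r) + floor((i - 1) * as.numeric(W) / nBins)
  e <- start(r) + floor(i * as.numeric(W) / nBins) - 1
  IRanges(as.integer(s), as.integer(e))
}

#' Binned coverage of subject elements across query bodies
#'
#' Splits every query region into `nBins` equally sized bins (see
#' [binRegion()]) and, for each subject element overlapping the query
#' under `params`, adds one count to every bin whose sub-interval the
#' element intersects by at least one base. An element spanning k bins
#' therefore counts once in each of the k bins.
#'
#' Bins are reported 5' to 3': with `orient = TRUE` (default) the bin
#' order of `"-"`-strand queries is reversed so that bin 1 always starts
#' at the transcription start site and bin `nBins` ends at the
#' termination site; unstranded queries are treated as `"+"`. Queries
#' shorter than `nBins` bases are dropped with a warning and counted in
#' `nDroppedShort`.
#'
#' @param query,subject [RegionSet] objects.
#' @param nBins Number of bins per query region (default 100).
#' @param params [OverlapParams] deciding which subject elements count
#'   (default: any overlap of at least one base, strand ignored) -- the
#'   same overlap semantics as [findRegionOverlaps()].
#' @param orient Reverse bin order for minus-strand queries (default
#'   TRUE).
#' @return A [CoverageMatrix].
#' @examples
#' ws <- makeToyWorkspace()
#' cm <- coverageMatrix(querySet(ws), subjectSet(ws, "TFBS"), nBins = 10)
#' coverageProfile(cm)
#' @export
coverageMatrix <- function(query, subject, nBins = 100,
                           params = OverlapParams(), orient = TRUE) {
  stopifnot(is(query, "RegionSet"), is(subject, "RegionSet"))
  nBins <- as.integer(nBins)
  if (nBins < 1L) stop("'nBins' must be >= 1")
  w <- width(query@ranges)
  kept <- which(w >= nBins)
  nDropped <- length(w) - length(kept)
  if (nDropped > 0)
    warning(nDropped, " query region(s) shorter than ", nBins,
            " bp dropped from the coverage matrix")
  qk <- query[kept]
  ht <- findRegionOverlaps(qk, subject, params)
  h <- ht@hits
  qgr <- qk@ranges
  mat <- matrix(0L, nrow = length(kept), ncol = nBins)
  for (r in seq_along(kept)) {
    hr <- h[h$queryIndex == r, , drop = FALSE]
    if (!nrow(hr)) next
    W <- as.numeric(width(qgr)[r])
    binStarts <- start(qgr)[r] + floor((seq_len(nBins) - 1) * W / nBins)
    first <- findInterval(hr$ovStart, binStarts)
    last <- findInterval(hr$ovEnd, binStarts)
    row <- tabulate(sequence(last - first + 1L, from = first), nbins = nBins)
    if (orient && as.character(strand(qgr))[r] == "-") row <- rev(row)
    mat[r, ] <- row
  }
  cm <- new("CoverageMatrix", queryName = query@name,
            subjectName = subject@name, nBins = nBins, matrix = mat,
            keptQueryIndices = as.integer(kept),
            profile = as.numeric(colSums(mat)),
            nDroppedShort = as.integer(nDropped))
  validObject(cm)
  cm
}

#' Accumulated per-bin profile as a table
#'
#' @param cm A [CoverageMatrix].
#' @return A `data.frame` with columns `bin` (1..nBins, 5' to 3') and
#'   `count` (column sums of the coverage matrix).
#' @export
profileTable <- function(cm) {
  stopifnot(is(cm, "CoverageMatrix"))
  data.frame(bin = seq_len(cm@nBins), count = cm@profile)
}

#' Write coverage results as CSV
#'
#' `writeCoverageMatrix` writes one row per kept query region
#' (`queryIndex` column followed by `bin_1..bin_n`); `writeProfileTable`
#' writes the accumulated per-bin profile. Both are deterministic.
#'
#' @param cm A [CoverageMatrix].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeCoverageMatrix <- function(cm, path) {
  stopifnot(is(cm, "CoverageMatrix"))
  df <- as.data.frame(cm@matrix)
  names(df) <- paste0("bin_", seq_len(cm@nBins))
  df <- cbind(queryIndex = cm@keptQueryIndices, df)
  .writeCsv(df, path)
}

#' @rdname writeCoverageMatrix
#' @export
writeProfileTable <- function(cm, path) {
  .writeCsv(profileTable(cm), path)
}
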