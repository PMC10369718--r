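#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames strand start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

.validStrands <- c("+", "-", "*")

#' RegionSet: a named collection of genomic regions
#'
#' A `RegionSet` wraps a [GenomicRanges::GRanges] object together with
#' provenance metadata: a dataset name, an optional genome label (e.g.
#' `"hg38"`), a record of where the regions came from, and the chromosome
#' naming style in use. All coordinates are 1-based, closed intervals
#' (GFF-style), so a region covering a single base has `start == end` and
#' width 1. Converters from 0-based half-open formats (BED) normalize on
#' read and convert back on write.
#'
#' Input order is preserved and the 1-based position of a region within the
#' set is its stable index, used by hit tables and coverage matrices.
#'
#' @slot ranges A `GRanges` holding the regions; optional `name` and
#'   `score` metadata columns are recognized throughout the package.
#' @slot name Dataset name (single string).
#' @slot genomeLabel Genome assembly label, or `NA`.
#' @slot source List describing provenance (path, format, parse options).
#' @slot chromStyle One of `"ucsc"`, `"ensembl"`, `"mixed"`.
#'
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200), "+")
#' rs <- RegionSet(gr, name = "genes", genomeLabel = "hg38")
#' nRegions(rs)
#' regionWidths(rs)
#' @export
setClass("RegionSet",
  representation(
    ranges = "GRanges",
    name = "character",
    genomeLabel = "character",
    source = "list",
    chromStyle = "character"
  ),
  prototype(
    name = "regions",
    genomeLabel = NA_character_,
    source = list(),
    chromStyle = "mixed"
  )
)

setValidity("RegionSet", function(object) {
  msg <- character(0)
  gr <- object@ranges
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(gr) > 0) {
    if (any(start(gr) < 1L))
      msg <- c(msg, "all region starts must be >= 1 (coordinates are 1-based)")
    if (any(width(gr) < 1L))
      msg <- c(msg, "all regions must have width >= 1 (end >= start)")
  }
  if (!object@chromStyle %in% c("ucsc", "ensembl", "mixed"))
    msg <- c(msg, "'chromStyle' must be \"ucsc\", \"ensembl\" or \"mixed\"")
  if (length(msg)) msg else TRUE
})

#' @rdname RegionSet-class
#' @param ranges A `GRanges` of regions (1-based closed coordinates).
#' @param name Dataset name.
#' @param genomeLabel Optional genome assembly label.
#' @param source Optional provenance list.
#' @param chromStyle Chromosome naming style; detected from the seqnames
#'   when not given.
#' @return A `RegionSet`.
#' @export
RegionSet <- function(ranges, name = "regions", genomeLabel = NA_character_,
                      source = list(), chromStyle = NULL) {
  if (is.null(chromStyle))
    chromStyle <- .detectChromStyle(as.character(seqnames(ranges)))
  new("RegionSet", ranges = ranges, name = name,
      genomeLabel = as.character(genomeLabel), source = source,
      chromStyle = chromStyle)
}

#' OverlapWorkspace: region sets with query/subject roles
#'
#' Holds a named list of [RegionSet] objects, designates one as the
#' *query* (the user's regions of interest, e.g. genes or DEGs) and one or
#' more as *subjects* (annotation sets, e.g. TFBS, CpG islands, promoters),
#' and accumulates a processing log.
#'
#' @slot datasets Named list of `RegionSet` objects.
#' @slot queryName Name of the query dataset.
#' @slot subjectNames Names of the subject datasets.
#' @slot log Character vector of processing messages.
#' @export
setClass("OverlapWorkspace",
  representation(
    datasets = "list",
    queryName = "character",
    subjectNames = "character",
    log = "character"
  ),
  prototype(log = character(0))
)

setValidity("OverlapWorkspace", function(object) {
  msg <- character(0)
  nm <- names(object@datasets)
  if (length(object@datasets) &&
      (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)))
    msg <- c(msg, "'datasets' must be a uniquely named list")
  if (!all(vapply(object@datasets, is, logical(1), "RegionSet")))
    msg <- c(msg, "all datasets must be RegionSet objects")
  if (length(object@queryName) != 1L || !object@queryName %in% nm)
    msg <- c(msg, sprintf("query dataset '%s' not found among datasets",
                          paste(object@queryName, collapse = ",")))
  missing <- setdiff(object@subjectNames, nm)
  if (length(missing))
    msg <- c(msg, sprintf("subject dataset(s) not found: %s",
                          paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname OverlapWorkspace-class
#' @param datasets Named list of [RegionSet] objects.
#' @param queryName Name of the query dataset (default: first).
#' @param subjectNames Names of subject datasets (default: all others).
#' @return An `OverlapWorkspace`.
#' @export
OverlapWorkspace <- function(datasets, queryName = names(datasets)[1],
                             subjectNames = setdiff(names(datasets), queryName)) {
  new("OverlapWorkspace", datasets = datasets, queryName = queryName,
      subjectNames = subjectNames, log = character(0))
}

#' Overlap parameters
#'
#' The three tunable parameters of the overlap engine: the minimum number
#' of overlapping bases required for a hit, the type of overlap, and
#' whether strand is ignored.
#'
#' Types: `"any"` accepts any intersection (partial overlap), `"within"`
#' requires the query interval to lie entirely inside the subject interval
#' (the "full" overlap of a query by an annotation; swap roles for the
#' reverse containment), and `"equal"` requires identical start and end.
#' `minOverlap` applies to all types. When `ignoreStrand = FALSE`, strands
#' must be equal, or either region must be unstranded (`"*"`), which is
#' compatible with both orientations.
#'
#' @slot minOverlap Minimum overlap in bp (>= 1).
#' @slot type One of `"any"`, `"within"`, `"equal"`.
#' @slot ignoreStrand Logical.
#' @export
setClass("OverlapParams",
  representation(minOverlap = "integer", type = "character",
                 ignoreStrand = "logical"),
  prototype(minOverlap = 1L, type = "any", ignoreStrand = TRUE)
)

setValidity("OverlapParams", function(object) {
  msg <- character(0)
  if (length(object@minOverlap) != 1L || is.na(object@minOverlap) ||
      object@minOverlap < 1L)
    msg <- c(msg, "'minOverlap' must be a single integer >= 1")
  if (length(object@type) != 1L || !object@type %in% c("any", "within", "equal"))
    msg <- c(msg, "'type' must be \"any\", \"within\" or \"equal\"")
  if (length(object@ignoreStrand) != 1L || is.na(object@ignoreStrand))
    msg <- c(msg, "'ignoreStrand' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' @rdname OverlapParams-class
#' @param minOverlap Minimum overlap in bp (default 1: a hit is an overlap
#'   of at least one nucleotide base).
#' @param type Overlap type (default `"any"`).
#' @param ignoreStrand Ignore strand when pairing regions (default `TRUE`).
#' @return An `OverlapParams` object.
#' @examples
#' OverlapParams(minOverlap = 10, type = "within", ignoreStrand = FALSE)
#' @export
OverlapParams <- function(minOverlap = 1L, type = c("any", "within", "equal"),
                          ignoreStrand = TRUE) {
  type <- match.arg(type)
  new("OverlapParams", minOverlap = as.integer(minOverlap), type = type,
      ignoreStrand = ignoreStrand)
}

#' HitTable: the result of one query-vs-subject overlap run
#'
#' One row per overlapping (query, subject) region pair. Each hit records
#' the 1-based closed intersection interval, its width, and the overlapped
#' fraction of both the query and the subject region. Rows are sorted by
#' `(queryIndex, subjectIndex)` and pairs are unique, so outputs are
#' byte-stable for identical inputs.
#'
#' @slot params The [OverlapParams] used.
#' @slot queryName,subjectName Dataset names.
#' @slot hits A `data.frame` with columns `queryIndex`, `subjectIndex`,
#'   `chrom`, `ovStart`, `ovEnd`, `ovWidth`, `fracQuery`, `fracSubject`.
#' @export
setClass("HitTable",
  representation(params = "OverlapParams", queryName = "character",
                 subjectName = "character", hits = "data.frame")
)

.hitCols <- c("queryIndex", "subjectIndex", "chrom", "ovStart", "ovEnd",
              "ovWidth", "fracQuery", "fracSubject")

setValidity("HitTable", function(object) {
  msg <- character(0)
  h <- object@hits
  if (!all(.hitCols %in% names(h)))
    msg <- c(msg, paste("hit table must have columns:",
                        paste(.hitCols, collapse = ", ")))
  else if (nrow(h)) {
    if (is.unsorted(order(h$queryIndex, h$subjectIndex)) ||
        any(diff(order(h$queryIndex, h$subjectIndex)) != 1L))
      msg <- c(msg, "hits must be sorted by (queryIndex, subjectIndex)")
    if (anyDuplicated(h[, c("queryIndex", "subjectIndex")]))
      msg <- c(msg, "duplicate (queryIndex, subjectIndex) pairs")
    if (any(h$ovWidth != h$ovEnd - h$ovStart + 1L))
      msg <- c(msg, "ovWidth must equal ovEnd - ovStart + 1")
    if (any(h$ovWidth < object@params@minOverlap))
      msg <- c(msg, "all overlap widths must be >= minOverlap")
    if (any(h$fracQuery <= 0 | h$fracQuery > 1) ||
        any(h$fracSubject <= 0 | h$fracSubject > 1))
      msg <- c(msg, "fractions must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' CoverageMatrix: binned subject coverage across query bodies
#'
#' Each kept query region is split into `nBins` equally sized bins,
#' oriented 5' to 3' (bin 1 starts at the TSS), and each subject element
#' overlapping the query adds one count to every bin it intersects by at
#' least one base. The accumulated per-bin profile is the column sum.
#' Queries shorter than `nBins` bases cannot be tiled into `nBins`
#' non-empty bins and are dropped (counted in `nDroppedShort`).
#'
#' @slot queryName,subjectName Dataset names.
#' @slot nBins Number of bins.
#' @slot matrix Integer matrix, kept queries x bins.
#' @slot keptQueryIndices Indices (into the query set) of kept rows.
#' @slot profile Integer vector of per-bin column sums.
#' @slot nDroppedShort Number of queries dropped as too short.
#' @export
setClass("CoverageMatrix",
  representation(queryName = "character", subjectName = "character",
                 nBins = "integer", matrix = "matrix",
                 keptQueryIndices = "integer", profile = "numeric",
                 nDroppedShort = "integer")
)

setValidity("CoverageMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@matrix) != object@nBins)
    msg <- c(msg, "matrix must have nBins columns")
  if (nrow(object@matrix) != length(object@keptQueryIndices))
    msg <- c(msg, "one matrix row per kept query")
  if (length(object@profile) != object@nBins)
    msg <- c(msg, "profile must have nBins entries")
  if (length(object@matrix) && any(object@matrix < 0))
    msg <- c(msg, "matrix entries must be non-negative")
  if (length(object@matrix) &&
      !isTRUE(all.equal(unname(colSums(object@matrix)), unname(object@profile))))
    msg <- c(msg, "profile must equal the column sums of the matrix")
  if (length(msg)) msg else TRUE
})

#' Track style for region track plots
#'
#' @param color Fill color (name or hex).
#' @param labelMode `"name"` to print region names, `"none"` to suppress.
#' @param shape `"box"` for plain rectangles, `"arrow"` to indicate strand
#'   with an arrowhead where strand is known.
#' @param height Relative track height.
#' @return A list with class `"TrackStyle"`.
#' @examples
#' trackStyle(color = "firebrick", shape = "arrow")
#' @export
trackStyle <- function(color = "steelblue", labelMode = c("name", "none"),
                       shape = c("box", "arrow"), height = 1) {
  labelMode <- match.arg(labelMode)
  shape <- match.arg(shape)
  ok <- tryCatch({ grDevices::col2rgb(color); TRUE }, error = function(e) FALSE)
  if (!ok) stop("'", color, "' is not a valid color")
  structure(list(color = color, labelMode = labelMode, shape = shape,
                 height = height), class = "TrackStyle")
}
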