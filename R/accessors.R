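#' @include AllGenerics.R
NULL

#' Accessors for RegionSet
#'
#' @param x A [RegionSet].
#' @return `regions()` the underlying `GRanges`; `datasetName()`,
#'   `genomeLabel()`, `chromStyle()` the corresponding metadata;
#'   `nRegions()` the number of regions; `regionWidths()` integer widths in
#'   bp (`end - start + 1`, coordinates being 1-based closed);
#'   `regionNames()` region names, with generated `"<set>_<i>"` fallbacks
#'   for unnamed regions.
#' @examples
#' rs <- makeToyWorkspace() |> querySet()
#' regionWidths(rs)[1:3]
#' @rdname RegionSet-accessors
#' @aliases regions datasetName genomeLabel chromStyle nRegions regionWidths
#'   regionNames
#' @export
setMethod("regions", "RegionSet", function(x) x@ranges)

#' @rdname RegionSet-accessors
setMethod("datasetName", "RegionSet", function(x) x@name)

#' @rdname RegionSet-accessors
setMethod("genomeLabel", "RegionSet", function(x) x@genomeLabel)

#' @rdname RegionSet-accessors
setMethod("chromStyle", "RegionSet", function(x) x@chromStyle)

#' @rdname RegionSet-accessors
setMethod("nRegions", "RegionSet", function(x) length(x@ranges))

#' @rdname RegionSet-accessors
setMethod("regionWidths", "RegionSet", function(x) width(x@ranges))

#' @rdname RegionSet-accessors
setMethod("regionWidths", "GRanges", function(x) width(x))

#' @rdname RegionSet-accessors
setMethod("regionNames", "RegionSet", function(x) {
  nm <- mcols(x@ranges)$name
  fallback <- paste0(x@name, "_", seq_along(x@ranges))
  if (is.null(nm)) return(fallback)
  nm <- as.character(nm)
  ifelse(is.na(nm) | !nzchar(nm), fallback, nm)
})

setMethod("length", "RegionSet", function(x) length(x@ranges))

#' Subset a RegionSet by region index
#'
#' @param x A [RegionSet].
#' @param i Integer or logical index.
#' @param j,...,drop Ignored.
#' @return A `RegionSet` with the selected regions, metadata preserved.
#' @export
setMethod("[", "RegionSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, ranges = x@ranges[i])
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet \"%s\": %d region(s), style=%s, genome=%s\n",
              object@name, length(object@ranges), object@chromStyle,
              object@genomeLabel))
  if (length(object@ranges)) show(utils::head(object@ranges, 3))
})

#' Accessors for OverlapWorkspace
#'
#' @param x An [OverlapWorkspace].
#' @param name Subject dataset name (`subjectSet`); default: first subject.
#' @param value Replacement dataset name(s).
#' @return `datasets()` the named list of [RegionSet]s; `queryName()` /
#'   `subjectNames()` the role designations; `querySet()` / `subjectSet()`
#'   the designated sets; `workspaceLog()` the processing log.
#' @rdname OverlapWorkspace-accessors
#' @aliases datasets queryName subjectNames querySet subjectSet workspaceLog
#'   queryName<- subjectNames<-
#' @export
setMethod("datasets", "OverlapWorkspace", function(x) x@datasets)

#' @rdname OverlapWorkspace-accessors
setMethod("queryName", "OverlapWorkspace", function(x) x@queryName)

#' @rdname OverlapWorkspace-accessors
setMethod("subjectNames", "OverlapWorkspace", function(x) x@subjectNames)

#' @rdname OverlapWorkspace-accessors
setReplaceMethod("queryName", "OverlapWorkspace", function(x, value) {
  x@queryName <- value
  validObject(x)
  x
})

#' @rdname OverlapWorkspace-accessors
setReplaceMethod("subjectNames", "OverlapWorkspace", function(x, value) {
  x@subjectNames <- value
  validObject(x)
  x
})

#' @rdname OverlapWorkspace-accessors
setMethod("querySet", "OverlapWorkspace", function(x) x@datasets[[x@queryName]])

#' @rdname OverlapWorkspace-accessors
setMethod("subjectSet", "OverlapWorkspace", function(x, name) {
  if (missing(name)) name <- x@subjectNames[1]
  if (!name %in% names(x@datasets))
    stop("no dataset named '", name, "' in workspace")
  x@datasets[[name]]
})

#' @rdname OverlapWorkspace-accessors
setMethod("workspaceLog", "OverlapWorkspace", function(x) x@log)

setMethod("show", "OverlapWorkspace", function(object) {
  cat(sprintf("OverlapWorkspace: %d dataset(s)\n", length(object@datasets)))
  for (nm in names(object@datasets)) {
    role <- if (nm == object@queryName) "query"
            else if (nm %in% object@subjectNames) "subject" else "unassigned"
    cat(sprintf("  %-12s %-9s %d region(s)\n", nm, role,
                length(object@datasets[[nm]]@ranges)))
  }
})

#' Accessors for HitTable
#'
#' @param x A [HitTable].
#' @return `hits()` the hit `data.frame`; `overlapParams()` the
#'   [OverlapParams] used; `nHits()` the number of hits.
#' @rdname HitTable-accessors
#' @aliases hits overlapParams nHits
#' @export
setMethod("hits", "HitTable", function(x) x@hits)

#' @rdname HitTable-accessors
setMethod("overlapParams", "HitTable", function(x) x@params)

#' @rdname HitTable-accessors
setMethod("nHits", "HitTable", function(x) nrow(x@hits))

setMethod("show", "HitTable", function(object) {
  p <- object@params
  cat(sprintf(
    "HitTable %s ~ %s: %d hit(s) [minOverlap=%d, type=%s, ignoreStrand=%s]\n",
    object@queryName, object@subjectName, nrow(object@hits),
    p@minOverlap, p@type, p@ignoreStrand))
  if (nrow(object@hits)) print(utils::head(object@hits, 5))
})

setMethod("show", "OverlapParams", function(object) {
  cat(sprintf("OverlapParams: minOverlap=%d, type=%s, ignoreStrand=%s\n",
              object@minOverlap, object@type, object@ignoreStrand))
})

#' Accessors for CoverageMatrix
#'
#' @param x A [CoverageMatrix].
#' @return `coverageValues()` the kept-queries x bins integer matrix;
#'   `coverageProfile()` the accumulated per-bin vector (column sums);
#'   `keptQueryIndices()` the query indices retained after dropping
#'   too-short regions.
#' @rdname CoverageMatrix-accessors
#' @aliases coverageValues coverageProfile keptQueryIndices
#' @export
setMethod("coverageValues", "CoverageMatrix", function(x) x@matrix)

#' @rdname CoverageMatrix-accessors
setMethod("coverageProfile", "CoverageMatrix", function(x) x@profile)

#' @rdname CoverageMatrix-accessors
setMethod("keptQueryIndices", "CoverageMatrix", function(x) x@keptQueryIndices)

setMethod("show", "CoverageMatrix", function(object) {
  cat(sprintf(
    "CoverageMatrix %s ~ %s: %d query x %d bins (%d dropped as < %d bp)\n",
    object@queryName, object@subjectName, nrow(object@matrix),
    object@nBins, object@nDroppedShort, object@nBins))
})
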