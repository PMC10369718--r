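#' Per-query overlap counts
#'
#' @param ht A [HitTable].
#' @param nQuery Number of regions in the query set.
#' @return Integer vector of length `nQuery`; position q holds the number
#'   of hits with `queryIndex == q` (0 for hit-less queries). The vector
#'   sums to the total number of hits.
#' @export
countOverlapsPerQuery <- function(ht, nQuery) {
  stopifnot(is(ht, "HitTable"))
  nQuery <- as.integer(nQuery)
  h <- ht@hits
  if (nrow(h) && max(h$queryIndex) > nQuery)
    stop("hit table contains query indices beyond nQuery")
  tabulate(h$queryIndex, nbins = nQuery)
}

#' Summary statistics of per-query overlap counts
#'
#' Reports the number of query regions, the number with at least one hit,
#' the total number of hits, and the minimum, lower quartile, mean,
#' median, upper quartile and maximum of the per-query counts. Quartiles
#' use linear interpolation between order statistics: at probability p,
#' with sorted values x and n = length(x), h = (n - 1)p + 1 and the
#' quartile is x[floor(h)] + (h - floor(h)) (x[floor(h) + 1] - x[floor(h)])
#' (the default definition of [stats::quantile()], type 7).
#'
#' @param counts Non-empty numeric vector of per-query overlap counts
#'   (from [countOverlapsPerQuery()]).
#' @return One-row `data.frame` with columns `nQuery`, `nQueryWithHit`,
#'   `totalHits`, `min`, `lowerQuartile`, `mean`, `median`,
#'   `upperQuartile`, `max`.
#' @examples
#' summaryStats(c(0, 1, 4, 30))
#' @export
summaryStats <- function(counts) {
  if (!length(counts)) stop("'counts' must be non-empty")
  q <- unname(stats::quantile(counts, c(0.25, 0.75), type = 7))
  data.frame(
    nQuery = length(counts),
    nQueryWithHit = sum(counts > 0),
    totalHits = sum(counts),
    min = min(counts),
    lowerQuartile = q[1],
    mean = mean(counts),
    median = stats::median(counts),
    upperQuartile = q[2],
    max = max(counts))
}

#' Workspace-level overlap summary
#'
#' One row of [summaryStats()] per subject dataset, plus an `"overall"`
#' row reporting the number of query regions with at least one hit in
#' *any* subject dataset and the mean total number of annotation elements
#' per query.
#'
#' @param ws An [OverlapWorkspace].
#' @param hitTables Named list of [HitTable]s, one per subject dataset
#'   (as returned by [overlapWorkspace()]).
#' @return A `data.frame` with a leading `dataset` column.
#' @export
summarizeWorkspace <- function(ws, hitTables) {
  stopifnot(is(ws, "OverlapWorkspace"))
  if (!length(hitTables)) stop("no subject hit tables supplied")
  if (is.null(names(hitTables)) || any(!nzchar(names(hitTables))))
    stop("'hitTables' must be named by subject dataset")
  nq <- length(regions(querySet(ws)))
  perSubject <- lapply(names(hitTables), function(sn) {
    counts <- countOverlapsPerQuery(hitTables[[sn]], nq)
    cbind(dataset = sn, summaryStats(counts))
  })
  allCounts <- Reduce(`+`, lapply(hitTables, countOverlapsPerQuery, nQuery = nq))
  overall <- cbind(dataset = "overall", summaryStats(allCounts))
  out <- do.call(rbind, c(perSubject, list(overall)))
  rownames(out) <- NULL
  out
}

#' Subject regions overlapping one query region
#'
#' Drill-down for a single query: all subject regions it overlaps, in
#' subject-index order, with the intersection coordinates attached.
#'
#' @param ht A [HitTable].
#' @param queryIndex Index of the query region (1-based).
#' @param subject The subject [RegionSet] the table was computed against.
#' @return A `data.frame` with one row per overlapping subject region
#'   (zero rows for a hit-less query).
#' @export
subjectsForQuery <- function(ht, queryIndex, subject) {
  stopifnot(is(ht, "HitTable"), is(subject, "RegionSet"))
  h <- ht@hits[ht@hits$queryIndex == queryIndex, , drop = FALSE]
  sgr <- subject@ranges
  if (nrow(h) && max(h$subjectIndex) > length(sgr))
    stop("hit table indices exceed subject set size")
  sn <- regionNames(subject)
  out <- data.frame(
    subjectIndex = h$subjectIndex,
    subjectName = sn[h$subjectIndex],
    chrom = as.character(seqnames(sgr))[h$subjectIndex],
    start = start(sgr)[h$subjectIndex],
    end = end(sgr)[h$subjectIndex],
    strand = as.character(strand(sgr))[h$subjectIndex],
    ovStart = h$ovStart, ovEnd = h$ovEnd, ovWidth = h$ovWidth,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$subjectIndex), , drop = FALSE]
}

#' Histogram binning of per-query overlap counts
#'
#' Groups per-query overlap counts into bins for distribution plots. By
#' default one bin per integer 0..max when max <= 50, otherwise 30
#' equal-width bins spanning [0, max]. Custom `edges` define bins
#' `[e_i, e_{i+1})`, with the last bin closed on the right; edges must be
#' strictly increasing and cover all counts. Frequencies always sum to the
#' number of queries; the median of the counts is returned alongside for
#' the dashed median marker of [plotHistogram()].
#'
#' @param counts Non-empty numeric vector of per-query overlap counts.
#' @param edges Optional numeric vector of bin edges.
#' @return A list: `table` (`data.frame` with `bin`, `lower`, `upper`,
#'   `label`, `frequency`) and `median`.
#' @examples
#' histogramBins(c(0, 0, 1, 3, 3))
#' @export
histogramBins <- function(counts, edges = NULL) {
  if (!length(counts)) stop("'counts' must be non-empty")
  if (is.null(edges)) {
    mx <- max(counts)
    if (mx <= 50) {
      vals <- 0:max(mx, 0)
      freq <- tabulate(counts + 1L, nbins = length(vals))
      tab <- data.frame(bin = seq_along(vals), lower = vals, upper = vals,
                        label = as.character(vals), frequency = freq)
      return(list(table = tab, median = stats::median(counts)))
    }
    edges <- seq(0, mx, length.out = 31)
  }
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("'edges' must be strictly increasing with at least two values")
  idx <- findInterval(counts, edges, rightmost.closed = TRUE)
  if (any(idx == 0L | idx >= length(edges)))
    stop("'edges' do not cover all counts (range ",
         min(counts), "..", max(counts), ")")
  nb <- length(edges) - 1L
  freq <- tabulate(idx, nbins = nb)
  tab <- data.frame(
    bin = seq_len(nb),
    lower = edges[-length(edges)],
    upper = edges[-1],
    label = sprintf("[%g,%g%s", edges[-length(edges)], edges[-1],
                    c(rep(")", nb - 1L), "]")),
    frequency = freq)
  list(table = tab, median = stats::median(counts))
}
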