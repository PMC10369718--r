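#' Find all overlapping query-subject region pairs
#'
#' The core engine. A pair (q, s) is a hit iff the regions are on the
#' same chromosome, their strands are compatible (always, when
#' `ignoreStrand`; otherwise equal, or either unstranded), the
#' intersection is at least `minOverlap` bases wide, and the type
#' constraint holds (`"any"`: any intersection; `"within"`: q entirely
#' inside s; `"equal"`: identical interval). Each hit carries the
#' intersection coordinates, its width, and the overlapped fraction of
#' both regions (`ovWidth / width`), following the convention that a hit
#' is an overlap of at least one nucleotide base.
#'
#' The engine sorts subjects per chromosome and prunes candidate pairs by
#' binary search on the start coordinates (bounded by the widest subject),
#' so it runs in roughly O((n + m) log m + hits) rather than evaluating
#' all n x m pairs; results are identical to [bruteForceOverlaps()],
#' which serves as the reference semantics.
#'
#' @param query,subject [RegionSet] objects.
#' @param params An [OverlapParams].
#' @return A [HitTable], sorted by `(queryIndex, subjectIndex)`.
#' @examples
#' ws <- makeToyWorkspace()
#' ht <- findRegionOverlaps(querySet(ws), subjectSet(ws, "TFBS"))
#' hits(ht)
#' @seealso [annotateHits()], [countOverlapsPerQuery()]
#' @export
findRegionOverlaps <- function(query, subject, params = OverlapParams()) {
  .checkOverlapArgs(query, subject, params)
  qgr <- query@ranges; sgr <- subject@ranges
  qchr <- as.character(seqnames(qgr)); schr <- as.character(seqnames(sgr))
  qs <- start(qgr); qe <- end(qgr); qstr <- as.character(strand(qgr))
  ss <- start(sgr); se <- end(sgr); sstr <- as.character(strand(sgr))
  m <- params@minOverlap

  resQ <- integer(0); resS <- integer(0)
  for (chr in intersect(unique(qchr), unique(schr))) {
    qi <- which(qchr == chr); si <- which(schr == chr)
    o <- order(ss[si])
    si <- si[o]
    s1 <- ss[si]; e1 <- se[si]
    maxw <- max(e1 - s1 + 1L)

    # Candidate subjects for query [a, b]: need start <= b - m + 1 and
    # end >= a + m - 1; since end < start + maxw, the latter implies
    # start > a + m - 1 - maxw. Both bounds are binary searches on the
    # sorted starts.
    hi <- findInterval(qe[qi] - m + 1L, s1)
    lo <- findInterval(qs[qi] + m - 1L - maxw, s1) + 1L
    ncand <- pmax(hi - lo + 1L, 0L)
    if (!sum(ncand)) next
    qrep <- rep(qi, ncand)
    srep <- si[sequence(ncand, from = pmax(lo, 1L))]

    ovs <- pmax(qs[qrep], ss[srep])
    ove <- pmin(qe[qrep], se[srep])
    keep <- ove - ovs + 1L >= m
    if (params@type == "within")
      keep <- keep & qs[qrep] >= ss[srep] & qe[qrep] <= se[srep]
    else if (params@type == "equal")
      keep <- keep & qs[qrep] == ss[srep] & qe[qrep] == se[srep]
    if (!params@ignoreStrand)
      keep <- keep & (qstr[qrep] == sstr[srep] |
                      qstr[qrep] == "*" | sstr[srep] == "*")
    resQ <- c(resQ, qrep[keep]); resS <- c(resS, srep[keep])
  }
  .makeHitTable(resQ, resS, query, subject, params)
}

#' Reference brute-force overlap engine
#'
#' Evaluates the hit rule directly on every (query, subject) pair.
#' Intended for small inputs and as the test oracle for
#' [findRegionOverlaps()]; both must produce identical hit tables.
#'
#' @inheritParams findRegionOverlaps
#' @return A [HitTable].
#' @export
bruteForceOverlaps <- function(query, subject, params = OverlapParams()) {
  .checkOverlapArgs(query, subject, params)
  qgr <- query@ranges; sgr <- subject@ranges
  nq <- length(qgr); ns <- length(sgr)
  if (nq == 0L || ns == 0L)
    return(.makeHitTable(integer(0), integer(0), query, subject, params))
  qi <- rep(seq_len(nq), each = ns)
  si <- rep(seq_len(ns), times = nq)
  qs <- start(qgr)[qi]; qe <- end(qgr)[qi]
  ss <- start(sgr)[si]; se <- end(sgr)[si]
  ok <- as.character(seqnames(qgr))[qi] == as.character(seqnames(sgr))[si]
  ok <- ok & pmin(qe, se) - pmax(qs, ss) + 1L >= params@minOverlap
  if (params@type == "within") ok <- ok & qs >= ss & qe <= se
  if (params@type == "equal") ok <- ok & qs == ss & qe == se
  if (!params@ignoreStrand) {
    qstr <- as.character(strand(qgr))[qi]
    sstr <- as.character(strand(sgr))[si]
    ok <- ok & (qstr == sstr | qstr == "*" | sstr == "*")
  }
  .makeHitTable(qi[ok], si[ok], query, subject, params)
}

.checkOverlapArgs <- function(query, subject, params) {
  if (!is(query, "RegionSet") || !is(subject, "RegionSet"))
    stop("'query' and 'subject' must be RegionSet objects")
  if (!is(params, "OverlapParams")) stop("'params' must be OverlapParams()")
  validObject(params)
}

.makeHitTable <- function(qidx, sidx, query, subject, params) {
  qgr <- query@ranges; sgr <- subject@ranges
  ord <- order(qidx, sidx)
  qidx <- qidx[ord]; sidx <- sidx[ord]
  ovStart <- pmax(start(qgr)[qidx], start(sgr)[sidx])
  ovEnd <- pmin(end(qgr)[qidx], end(sgr)[sidx])
  ovWidth <- ovEnd - ovStart + 1L
  h <- data.frame(
    queryIndex = as.integer(qidx),
    subjectIndex = as.integer(sidx),
    chrom = as.character(seqnames(qgr))[qidx],
    ovStart = as.integer(ovStart),
    ovEnd = as.integer(ovEnd),
    ovWidth = as.integer(ovWidth),
    fracQuery = ovWidth / width(qgr)[qidx],
    fracSubject = ovWidth / width(sgr)[sidx],
    stringsAsFactors = FALSE)
  rownames(h) <- NULL
  ht <- new("HitTable", params = params, queryName = query@name,
            subjectName = subject@name, hits = h)
  validObject(ht)
  ht
}

#' Annotate hits into the long-table schema
#'
#' Joins region names and the full coordinates of both partners onto each
#' hit, producing the one-row-per-hit "long" table: dataset names, region
#' names (with generated `"<set>_<i>"` identifiers for unnamed regions),
#' query and subject coordinates and strands, the intersection interval,
#' its width, and both overlapped fractions.
#'
#' @param ht A [HitTable] produced from these two sets.
#' @param query,subject The [RegionSet] objects used to compute `ht`.
#' @return A `data.frame`, one row per hit, in hit-table order.
#' @seealso [writeLongTable()]
#' @export
annotateHits <- function(ht, query, subject) {
  stopifnot(is(ht, "HitTable"), is(query, "RegionSet"),
            is(subject, "RegionSet"))
  h <- ht@hits
  if (nrow(h) &&
      (max(h$queryIndex) > length(query@ranges) ||
       max(h$subjectIndex) > length(subject@ranges)))
    stop("hit table indices exceed region set sizes; table does not ",
         "belong to these sets")
  qgr <- query@ranges; sgr <- subject@ranges
  qn <- regionNames(query); sn <- regionNames(subject)
  data.frame(
    queryDataset = rep(ht@queryName, nrow(h)),
    subjectDataset = rep(ht@subjectName, nrow(h)),
    queryIndex = h$queryIndex,
    queryName = qn[h$queryIndex],
    queryChrom = as.character(seqnames(qgr))[h$queryIndex],
    queryStart = start(qgr)[h$queryIndex],
    queryEnd = end(qgr)[h$queryIndex],
    queryStrand = as.character(strand(qgr))[h$queryIndex],
    subjectIndex = h$subjectIndex,
    subjectName = sn[h$subjectIndex],
    subjectChrom = as.character(seqnames(sgr))[h$subjectIndex],
    subjectStart = start(sgr)[h$subjectIndex],
    subjectEnd = end(sgr)[h$subjectIndex],
    subjectStrand = as.character(strand(sgr))[h$subjectIndex],
    ovStart = h$ovStart,
    ovEnd = h$ovEnd,
    ovWidth = h$ovWidth,
    fracQuery = h$fracQuery,
    fracSubject = h$fracSubject,
    stringsAsFactors = FALSE)
}

#' Run the overlap engine for every subject dataset of a workspace
#'
#' @param ws An [OverlapWorkspace].
#' @param params An [OverlapParams] applied to every subject.
#' @return Named list of [HitTable] objects, one per subject dataset.
#' @export
overlapWorkspace <- function(ws, params = OverlapParams()) {
  stopifnot(is(ws, "OverlapWorkspace"))
  q <- querySet(ws)
  out <- lapply(ws@subjectNames, function(sn)
    findRegionOverlaps(q, subjectSet(ws, sn), params))
  names(out) <- ws@subjectNames
  out
}
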