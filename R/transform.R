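#' Strand-aware resizing of regions around the TSS, TES or gene body
#'
#' Builds windows relative to a gene's transcription start site (TSS),
#' transcription termination site (TES), or around the whole body, taking
#' strand into account: for a `"+"` (or unstranded) region the TSS is its
#' `start`, for a `"-"` region its `end`, and "upstream" always means 5'
#' of the anchor in the region's reading orientation. The classic promoter
#' window 1200 bp upstream of the TSS is
#' `resizeRegions(rs, anchor = "tss", upstream = 1200, downstream = 0)`.
#'
#' The anchor base counts as position 0 and is included by default, so
#' `upstream = U, downstream = D` gives width `U + D + 1`. With
#' `includeAnchorBase = FALSE` a one-sided window excludes the anchor base
#' itself (width `U` or `D`); excluding it from a two-sided window is not
#' meaningful and raises an error. With `anchor = "body"` both original
#' ends are extended outward (5' end by `upstream`, 3' end by
#' `downstream`) and `includeAnchorBase` is ignored.
#'
#' Results are clipped to `[1, chromSize]` when chromosome sizes are
#' given, and to `[1, Inf)` otherwise; clipping is reported via
#' `message()`. A region that becomes empty after clipping is dropped
#' with a warning. Unstranded (`"*"`) regions are anchored like `"+"`,
#' with a one-time warning per call.
#'
#' @param rs A [RegionSet].
#' @param anchor `"tss"`, `"tes"` or `"body"`.
#' @param upstream,downstream Non-negative extents in bp.
#' @param chromSizes Optional named vector of chromosome lengths (see
#'   [readChromSizes()]).
#' @param includeAnchorBase Include the anchor base itself (default TRUE).
#' @return A resized [RegionSet] (metadata preserved; dropped regions
#'   removed).
#' @examples
#' ws <- makeToyWorkspace()
#' prom <- resizeRegions(querySet(ws), "tss", upstream = 1200, downstream = 0)
#' head(regions(prom))
#' @export
resizeRegions <- function(rs, anchor = c("tss", "tes", "body"),
                          upstream = 0, downstream = 0, chromSizes = NULL,
                          includeAnchorBase = TRUE) {
  anchor <- match.arg(anchor)
  stopifnot(is(rs, "RegionSet"), upstream >= 0, downstream >= 0)
  if (anchor == "body" && upstream == 0 && downstream == 0) return(rs)
  if (!includeAnchorBase && anchor != "body") {
    if (upstream > 0 && downstream > 0)
      stop("the anchor base can only be excluded from a one-sided window")
    if (upstream + downstream == 0)
      stop("excluding the anchor base from an empty window leaves nothing")
  }
  gr <- rs@ranges
  str <- as.character(strand(gr))
  if (anchor != "body" && any(str == "*"))
    warning("unstranded ('*') regions in '", rs@name,
            "' are anchored like '+' strand")
  plus <- str != "-"
  s <- start(gr); e <- end(gr)

  if (anchor == "body") {
    ns <- ifelse(plus, s - upstream, s - downstream)
    ne <- ifelse(plus, e + downstream, e + upstream)
  } else {
    a <- if (anchor == "tss") ifelse(plus, s, e) else ifelse(plus, e, s)
    if (includeAnchorBase) {
      ns <- ifelse(plus, a - upstream, a - downstream)
      ne <- ifelse(plus, a + downstream, a + upstream)
    } else if (downstream == 0) {       # strictly upstream window
      ns <- ifelse(plus, a - upstream, a + 1)
      ne <- ifelse(plus, a - 1, a + upstream)
    } else {                            # strictly downstream window
      ns <- ifelse(plus, a + 1, a - downstream)
      ne <- ifelse(plus, a + downstream, a - 1)
    }
  }

  clippedLow <- ns < 1
  ns[clippedLow] <- 1
  clippedHigh <- rep(FALSE, length(gr))
  if (!is.null(chromSizes)) {
    sz <- chromSizes[as.character(seqnames(gr))]
    known <- !is.na(sz)
    clippedHigh <- known & ne > sz
    ne[clippedHigh] <- sz[clippedHigh]
  }
  nClip <- sum(clippedLow | clippedHigh)
  if (nClip > 0)
    .logMsg(sprintf("clipped %d region(s) of '%s' at chromosome bounds",
                    nClip, rs@name))
  keep <- ns <= ne & ne >= 1
  if (any(!keep))
    warning(sum(!keep), " region(s) of '", rs@name,
            "' became empty after clipping and were dropped")
  out <- GRanges(seqnames(gr)[keep], IRanges(ns[keep], ne[keep]),
                 strand = str[keep])
  mcols(out) <- mcols(gr)[keep, , drop = FALSE]
  rs@ranges <- out
  rs
}

#' Subset a RegionSet by simple predicates
#'
#' Order-preserving filter over region fields: a regular-expression match
#' on the name, a chromosome allow-list, a strand allow-list, a minimum
#' score, and equality tests on arbitrary metadata columns. Predicates
#' combine with AND; regions with a missing value for a tested field are
#' removed by that predicate.
#'
#' @param rs A [RegionSet].
#' @param namePattern Regular expression matched against region names
#'   (use e.g. `"^EGR4$"` to keep one transcription factor's sites).
#' @param chroms Character vector of chromosomes to keep.
#' @param strands Character vector of strands to keep.
#' @param minScore Keep regions with `score >= minScore`.
#' @param attrs Named list of metadata-column equality filters; naming a
#'   column the set does not carry is an error.
#' @return The filtered [RegionSet].
#' @export
subsetRegions <- function(rs, namePattern = NULL, chroms = NULL,
                          strands = NULL, minScore = NULL, attrs = NULL) {
  stopifnot(is(rs, "RegionSet"))
  gr <- rs@ranges
  keep <- rep(TRUE, length(gr))
  if (!is.null(namePattern)) {
    nm <- regionNames(rs)
    keep <- keep & grepl(namePattern, nm)
  }
  if (!is.null(chroms))
    keep <- keep & as.character(seqnames(gr)) %in% chroms
  if (!is.null(strands))
    keep <- keep & as.character(strand(gr)) %in% strands
  if (!is.null(minScore)) {
    sc <- mcols(gr)$score
    if (is.null(sc)) stop("'", rs@name, "' has no score column")
    keep <- keep & !is.na(sc) & sc >= minScore
  }
  if (!is.null(attrs)) {
    for (k in names(attrs)) {
      if (!k %in% names(mcols(gr)))
        stop("unknown attribute '", k, "' in '", rs@name, "'; available: ",
             paste(names(mcols(gr)), collapse = ", "))
      v <- mcols(gr)[[k]]
      keep <- keep & !is.na(v) & v == attrs[[k]]
    }
  }
  nRemoved <- sum(!keep)
  if (nRemoved > 0)
    .logMsg(sprintf("subset '%s': removed %d of %d region(s)", rs@name,
                    nRemoved, length(gr)))
  rs[keep]
}
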