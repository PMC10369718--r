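# Synthetic region-set generators. These stand in for public annotation
# releases (gene annotations, TFBS dumps, CpG island tracks) at desk
# scale: every generator is a pure function of its arguments and seed, so
# tests and examples are reproducible offline.

#' Generate a random RegionSet
#'
#' Regions are placed uniformly: each region's chromosome is drawn with
#' probability proportional to chromosome length, its length uniformly
#' from `lengthRange`, and its start uniformly among the positions that
#' keep it inside the chromosome. Strand is drawn from
#' `strandProbs = (p_plus, p_minus, p_star)`. Regions are named
#' `"r1".."rN"`.
#'
#' @param n Number of regions.
#' @param chromSizes Named vector of chromosome lengths (default: one
#'   1 Mb toy chromosome `chr1`).
#' @param lengthRange Length-2 vector (min, max) of region lengths, or a
#'   single fixed length.
#' @param strandProbs Probabilities for `+`, `-`, `*` (must sum to 1).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param name Dataset name.
#' @return A [RegionSet].
#' @examples
#' generateRegionSet(5, seed = 42)
#' @export
generateRegionSet <- function(n, chromSizes = c(chr1 = 1e6),
                              lengthRange = c(50, 500),
                              strandProbs = c(0.5, 0.5, 0), seed = 1,
                              name = "synthetic") {
  stopifnot(n >= 0, all(chromSizes >= 1), length(strandProbs) == 3)
  if (abs(sum(strandProbs) - 1) > 1e-8)
    stop("'strandProbs' must sum to 1")
  if (length(lengthRange) == 1L) lengthRange <- rep(lengthRange, 2)
  if (lengthRange[1] < 1) stop("region lengths must be >= 1")
  if (lengthRange[2] > max(chromSizes))
    stop("maximum region length exceeds every chromosome size")
  if (n == 0)
    return(RegionSet(GRanges(), name = name,
                     source = list(generator = "uniform", seed = seed)))
  withr::with_seed(seed, {
    chrom <- sample(names(chromSizes), n, replace = TRUE,
                    prob = chromSizes / sum(chromSizes))
    len <- sample(seq(lengthRange[1], lengthRange[2]), n, replace = TRUE)
    maxLen <- chromSizes[chrom]
    if (any(len > maxLen))
      stop("drawn region length exceeds its chromosome size; shrink ",
           "'lengthRange' or enlarge 'chromSizes'")
    start <- pmin(floor(stats::runif(n, min = 1, max = maxLen - len + 2)),
                  maxLen - len + 1)
    str <- sample(c("+", "-", "*"), n, replace = TRUE, prob = strandProbs)
  })
  gr <- GRanges(chrom, IRanges(as.integer(start),
                               as.integer(start + len - 1)), strand = str)
  mcols(gr)$name <- paste0("r", seq_len(n))
  RegionSet(gr, name = name,
            source = list(generator = "uniform", seed = seed))
}

#' Deterministic evenly spaced RegionSet
#'
#' Lays `n` regions of fixed width end to end with a fixed gap on one
#' chromosome -- a non-overlapping "gene body" scaffold for parameter
#' recovery and coverage fixtures.
#'
#' @param n Number of regions.
#' @param width Region width in bp.
#' @param gap Gap between consecutive regions in bp.
#' @param chrom Chromosome name.
#' @param strand Strand for all regions (recycled).
#' @param name Dataset name.
#' @return A [RegionSet].
#' @export
tileRegionSet <- function(n, width = 1000, gap = 100, chrom = "chr1",
                          strand = "+", name = "tiles") {
  stopifnot(n >= 0, width >= 1, gap >= 0)
  if (n == 0) return(RegionSet(GRanges(), name = name))
  s <- 1 + (seq_len(n) - 1) * (width + gap)
  gr <- GRanges(chrom, IRanges(s, s + width - 1),
                strand = rep_len(strand, n))
  mcols(gr)$name <- paste0("r", seq_len(n))
  RegionSet(gr, name = name, source = list(generator = "tiled"))
}

#' Generate subject elements inside query regions at a known rate
#'
#' For each query region, draws `k ~ Poisson(rate)` subject elements and
#' places them fully inside the region body. With `bias = "uniform"` the
#' element start offset is uniform over the admissible positions; with
#' `bias = "five_prime"` the offset (measured from the 5' end, strand
#' aware) has linearly decaying density f(x) = 2(1 - x) over the region
#' body, enriching the TSS-proximal bins. The true per-query element
#' counts are returned for parameter-recovery tests.
#'
#' @param query A [RegionSet] of host regions.
#' @param rate Poisson mean number of elements per query region.
#' @param bias `"uniform"` or `"five_prime"`.
#' @param lengthRange Length-2 vector (min, max) of element lengths;
#'   elements are truncated to the host width when necessary.
#' @param seed Integer seed.
#' @param name Dataset name.
#' @return A list: `subjects` (a [RegionSet], elements unstranded, named
#'   `"<query name>_e<j>"`) and `trueCounts` (integer vector parallel to
#'   the query set).
#' @examples
#' q <- tileRegionSet(5, width = 1000)
#' generateSubjectsFor(q, rate = 2, seed = 7)$trueCounts
#' @export
generateSubjectsFor <- function(query, rate, bias = c("uniform", "five_prime"),
                                lengthRange = c(5, 20), seed = 1,
                                name = "elements") {
  bias <- match.arg(bias)
  stopifnot(is(query, "RegionSet"), rate >= 0)
  if (length(lengthRange) == 1L) lengthRange <- rep(lengthRange, 2)
  qgr <- query@ranges
  nq <- length(qgr)
  withr::with_seed(seed, {
    k <- if (nq) stats::rpois(nq, rate) else integer(0)
    tot <- sum(k)
    host <- rep(seq_len(nq), k)
    len <- if (tot) sample(seq(lengthRange[1], lengthRange[2]), tot,
                           replace = TRUE) else integer(0)
    W <- width(qgr)[host]
    len <- pmin(len, W)
    room <- W - len            # admissible 0-based offsets: 0..room
    u <- stats::runif(tot)
    off <- if (bias == "uniform") floor(u * (room + 1))
           else floor((1 - sqrt(1 - u)) * (room + 1))
    off <- pmin(off, room)
  })
  if (tot == 0)
    return(list(subjects = RegionSet(GRanges(), name = name,
                                     source = list(generator = bias,
                                                   rate = rate, seed = seed)),
                trueCounts = if (nq) k else integer(0)))
  minus <- as.character(strand(qgr))[host] == "-"
  s <- ifelse(minus, end(qgr)[host] - off - len + 1L,
              start(qgr)[host] + off)
  gr <- GRanges(seqnames(qgr)[host], IRanges(as.integer(s),
                                             as.integer(s + len - 1L)))
  hostNames <- regionNames(query)[host]
  mcols(gr)$name <- paste0(hostNames, "_e",
                           stats::ave(host, host, FUN = seq_along))
  list(subjects = RegionSet(gr, name = name,
                            source = list(generator = bias, rate = rate,
                                          seed = seed)),
       trueCounts = k)
}

#' Fixed toy workspace with hand-enumerated overlaps
#'
#' A small, fully deterministic workspace: 10 "gene" query regions on two
#' chromosomes (two on the minus strand) and 25 unstranded subject
#' regions across three annotation sets ("TFBS", "CGI", "promoter").
#' Every overlap, fraction, and summary statistic of this workspace can
#' be enumerated by hand, which makes it the golden fixture for the
#' engine, the tables, and the summaries. With default parameters it
#' yields 17 hits: 8 gene-TFBS, 6 gene-CGI, and 3 gene-promoter.
#'
#' @return An [OverlapWorkspace] with query `"genes"` and subjects
#'   `"TFBS"`, `"CGI"`, `"promoter"`.
#' @examples
#' ws <- makeToyWorkspace()
#' nHits(findRegionOverlaps(querySet(ws), subjectSet(ws, "TFBS")))
#' @export
makeToyWorkspace <- function() {
  genes <- GRanges(
    c("chr1", "chr1", "chr1", "chr1", "chr1",
      "chr2", "chr2", "chr2", "chr2", "chr2"),
    IRanges(c(1000, 3000, 5000, 8000, 9000, 1000, 2500, 5000, 7000, 8000),
            c(2000, 4000, 7000, 8500, 9100, 2000, 2600, 6000, 7050, 9000)),
    strand = c("+", "+", "-", "+", "+", "+", "-", "+", "+", "-"))
  mcols(genes)$name <- paste0("g", 1:10)

  tfbs <- GRanges(
    c("chr1", "chr1", "chr1", "chr1", "chr1",
      "chr1", "chr2", "chr2", "chr2", "chr2"),
    IRanges(c(1100, 1500, 1990, 2100, 5500, 6500, 1000, 5990, 8400, 9500),
            c(1110, 1520, 2010, 2200, 5510, 6600, 1000, 6100, 8600, 9600)))
  mcols(tfbs)$name <- paste0("t", 1:10)

  cgi <- GRanges(
    c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2", "chr2"),
    IRanges(c(900, 2900, 6900, 12000, 950, 2450, 4000, 8900),
            c(1100, 3100, 7100, 12200, 1050, 2550, 4100, 9100)))
  mcols(cgi)$name <- paste0("c", 1:8)

  promoter <- GRanges(
    c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    IRanges(c(800, 2800, 7001, 8000, 900, 4900, 7000),
            c(999, 2999, 7200, 8099, 999, 5050, 7100)))
  mcols(promoter)$name <- paste0("p", 1:7)

  OverlapWorkspace(list(
    genes = RegionSet(genes, name = "genes", genomeLabel = "toy1",
                      source = list(generator = "toy")),
    TFBS = RegionSet(tfbs, name = "TFBS", genomeLabel = "toy1",
                     source = list(generator = "toy")),
    CGI = RegionSet(cgi, name = "CGI", genomeLabel = "toy1",
                    source = list(generator = "toy")),
    promoter = RegionSet(promoter, name = "promoter", genomeLabel = "toy1",
                         source = list(generator = "toy"))),
    queryName = "genes")
}
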