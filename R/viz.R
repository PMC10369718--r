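# Static plots via base graphics; PNG by default, PDF when the output
# path ends in .pdf. Figure dimensions are fixed so identical inputs give
# identical files.

.openDevice <- function(path, width = 8, height = 5) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdf") grDevices::pdf(path, width = width, height = height)
  else grDevices::png(path, width = width * 100, height = height * 100,
                      res = 100)
}

.datasetPalette <- function(n) {
  base <- c("#1B9E77", "#D95F02", "#7570B3", "#E7298A", "#66A61E",
            "#E6AB02", "#A6761D", "#666666")
  rep_len(base, n)
}

#' Bar chart of the workspace overlap summary
#'
#' One bar group per subject dataset showing the number of query regions,
#' the number with at least one hit, the total number of hits, and the
#' mean hits per query.
#'
#' @param summary `data.frame` from [summarizeWorkspace()].
#' @param path Output image path (`.png` or `.pdf`).
#' @return The path, invisibly.
#' @export
plotSummaryBars <- function(summary, path) {
  stopifnot(is.data.frame(summary))
  s <- summary[summary$dataset != "overall", , drop = FALSE]
  if (!nrow(s)) stop("summary table has no subject datasets")
  m <- t(as.matrix(s[, c("nQuery", "nQueryWithHit", "totalHits", "mean")]))
  colnames(m) <- s$dataset
  .openDevice(path)
  on.exit(grDevices::dev.off())
  graphics::barplot(m, beside = TRUE,
                    col = c("grey70", "#1B9E77", "#D95F02", "#7570B3"),
                    legend.text = c("queries", "queries with hit",
                                    "total hits", "mean hits/query"),
                    args.legend = list(x = "topright", bty = "n", cex = 0.8),
                    ylab = "count", main = "Overlap summary")
  invisible(path)
}

#' Histogram of per-query overlap counts with median marker
#'
#' Bar chart of the binned count distribution with a dashed vertical
#' black line at the median.
#'
#' @param hist Result of [histogramBins()], or its `table` component.
#' @param medianValue Median to mark; taken from `hist$median` when the
#'   full [histogramBins()] result is passed.
#' @param path Output image path.
#' @return The path, invisibly.
#' @export
plotHistogram <- function(hist, medianValue = NULL, path) {
  if (is.list(hist) && !is.data.frame(hist) && "table" %in% names(hist)) {
    if (is.null(medianValue)) medianValue <- hist$median
    hist <- hist$table
  }
  stopifnot(is.data.frame(hist), nrow(hist) > 0)
  .openDevice(path)
  on.exit(grDevices::dev.off())
  mids <- graphics::barplot(hist$frequency, names.arg = hist$label,
                            col = "grey60", border = "grey30",
                            xlab = "overlaps per region",
                            ylab = "frequency",
                            main = "Overlap count distribution")
  if (!is.null(medianValue)) {
    centers <- (hist$lower + hist$upper) / 2
    x <- if (nrow(hist) == 1L) mids[1]
         else stats::approx(centers, as.vector(mids), xout = medianValue,
                            rule = 2)$y
    graphics::abline(v = x, lty = 2, lwd = 2, col = "black")
  }
  invisible(path)
}

#' Local genomic track plot around one query region
#'
#' Draws a genomic-coordinate axis and one track per dataset restricted
#' to a window around the chosen query region (default: the query
#' interval extended by 10% flanks on both sides). Regions with known
#' strand are drawn with an arrowhead when the track style asks for
#' arrows; datasets that were not part of the overlap run can be layered
#' in via `extraDatasets`.
#'
#' @param ws An [OverlapWorkspace].
#' @param queryIndex Index of the query region to center on.
#' @param window Optional length-1 `GRanges` window; must be on the query
#'   region's chromosome.
#' @param styles Optional named list of [trackStyle()] per dataset.
#' @param extraDatasets Names of additional workspace datasets to layer
#'   below the subjects.
#' @param path Output image path.
#' @return The path, invisibly.
#' @export
plotRegionTracks <- function(ws, queryIndex, window = NULL, styles = NULL,
                             extraDatasets = NULL, path) {
  stopifnot(is(ws, "OverlapWorkspace"))
  q <- querySet(ws)
  if (queryIndex < 1 || queryIndex > length(q@ranges))
    stop("'queryIndex' out of range (1..", length(q@ranges), ")")
  qr <- q@ranges[queryIndex]
  chrom <- as.character(seqnames(qr))
  if (is.null(window)) {
    flank <- ceiling(width(qr) * 0.10)
    ws_ <- max(1, start(qr) - flank)
    we_ <- end(qr) + flank
  } else {
    stopifnot(is(window, "GRanges"), length(window) == 1L)
    if (as.character(seqnames(window)) != chrom)
      stop("window chromosome (", as.character(seqnames(window)),
           ") differs from the query region's (", chrom, ")")
    ws_ <- start(window); we_ <- end(window)
  }
  trackNames <- unique(c(ws@queryName, ws@subjectNames, extraDatasets))
  unknown <- setdiff(trackNames, names(ws@datasets))
  if (length(unknown))
    stop("unknown dataset(s): ", paste(unknown, collapse = ", "))
  pal <- .datasetPalette(length(trackNames))
  .openDevice(path, width = 9, height = 1 + 0.8 * length(trackNames))
  on.exit(grDevices::dev.off())
  n <- length(trackNames)
  graphics::par(mar = c(3.5, 8, 2.5, 1))
  graphics::plot(NA, xlim = c(ws_, we_), ylim = c(0, n), xlab = "", ylab = "",
                 yaxt = "n", main = sprintf("%s:%d-%d", chrom, ws_, we_),
                 xaxs = "i")
  graphics::mtext(sprintf("position on %s (bp)", chrom), side = 1, line = 2.2)
  graphics::axis(2, at = seq_len(n) - 0.5, labels = rev(trackNames),
                 las = 2, tick = FALSE)
  for (k in seq_len(n)) {
    nm <- trackNames[k]
    y0 <- n - k + 0.15
    sty <- if (!is.null(styles) && nm %in% names(styles)) styles[[nm]]
           else trackStyle(color = pal[k])
    y1 <- y0 + 0.55 * sty$height
    rs <- ws@datasets[[nm]]
    gr <- rs@ranges
    inWin <- as.character(seqnames(gr)) == chrom &
      start(gr) <= we_ & end(gr) >= ws_
    gr <- gr[inWin]
    labs <- regionNames(rs)[inWin]
    if (length(gr)) {
      xs <- pmax(start(gr), ws_); xe <- pmin(end(gr), we_)
      str <- as.character(strand(gr))
      for (j in seq_along(gr)) {
        if (sty$shape == "arrow" && str[j] %in% c("+", "-")) {
          head_ <- min((we_ - ws_) * 0.01, (xe[j] - xs[j]) * 0.5)
          ym <- (y0 + y1) / 2
          if (str[j] == "+")
            graphics::polygon(
              c(xs[j], xe[j] - head_, xe[j], xe[j] - head_, xs[j]),
              c(y0, y0, ym, y1, y1), col = sty$color, border = NA)
          else
            graphics::polygon(
              c(xe[j], xs[j] + head_, xs[j], xs[j] + head_, xe[j]),
              c(y0, y0, ym, y1, y1), col = sty$color, border = NA)
        } else {
          graphics::rect(xs[j], y0, xe[j], y1, col = sty$color, border = NA)
        }
        if (sty$labelMode == "name" && !is.na(labs[j]))
          graphics::text((xs[j] + xe[j]) / 2, y1 + 0.12, labs[j], cex = 0.6)
      }
    }
  }
  invisible(path)
}

#' Line plot of an accumulated coverage profile
#'
#' @param cm A [CoverageMatrix].
#' @param path Output image path.
#' @return The path, invisibly.
#' @export
plotCoverageProfile <- function(cm, path) {
  stopifnot(is(cm, "CoverageMatrix"))
  .openDevice(path)
  on.exit(grDevices::dev.off())
  graphics::plot(seq_len(cm@nBins), cm@profile, type = "l", lwd = 2,
                 col = "#1B9E77", xlab = "bin (5' → 3')",
                 ylab = "accumulated overlap count",
                 main = sprintf("Coverage profile: %s ~ %s",
                                cm@queryName, cm@subjectName))
  invisible(path)
}

#' UCSC genome browser URL for a region
#'
#' Builds an `hgTracks` link for one region, normalizing the chromosome
#' name to the UCSC dialect the browser expects.
#'
#' @param r A length-1 `GRanges` (or single-region [RegionSet]).
#' @param genome UCSC assembly label, e.g. `"hg38"`.
#' @return The URL string.
#' @examples
#' ucscUrl(GenomicRanges::GRanges("2", IRanges::IRanges(240000, 241000)),
#'         "hg38")
#' @export
ucscUrl <- function(r, genome) {
  if (is(r, "RegionSet")) r <- regions(r)
  stopifnot(is(r, "GRanges"), length(r) == 1L)
  .stopifnotScalarString(genome, "genome")
  chrom <- .toUcscName(as.character(seqnames(r)))
  sprintf("https://genome.ucsc.edu/cgi-bin/hgTracks?db=%s&position=%s%%3A%d-%d",
          genome, chrom, start(r), end(r))
}
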