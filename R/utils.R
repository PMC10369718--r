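# Internal helpers shared across modules.

# A chromosome name is "canonical" if it is an autosome number, X, Y or the
# mitochondrial contig in either naming dialect; only canonical names are
# translated between styles, everything else is kept verbatim.
.isUcscName <- function(x) grepl("^chr([0-9]+|X|Y|M)$", x)
.isEnsemblName <- function(x) grepl("^([0-9]+|X|Y|MT)$", x)

.detectChromStyle <- function(chroms) {
  chroms <- unique(chroms)
  if (!length(chroms)) return("mixed")
  ucsc <- grepl("^chr", chroms)
  if (all(ucsc)) "ucsc" else if (!any(ucsc)) "ensembl" else "mixed"
}

.toUcscName <- function(x) {
  out <- x
  out[x == "MT"] <- "chrM"
  plain <- .isEnsemblName(x) & x != "MT"
  out[plain] <- paste0("chr", x[plain])
  out
}

.toEnsemblName <- function(x) {
  out <- x
  out[x == "chrM"] <- "MT"
  pref <- .isUcscName(x) & x != "chrM"
  out[pref] <- sub("^chr", "", x[pref])
  out
}

# Deterministic CSV writer: fixed column order, RFC-4180 quoting of
# character fields, no row names, "." decimal, LF line endings.
.writeCsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = which(
    vapply(df, function(x) is.character(x) || is.factor(x), logical(1))),
    eol = "\n", na = "")
  invisible(path)
}

.stopifnotScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop("'", what, "' must be a single non-empty string")
}

# message() with a uniform prefix; all progress reporting funnels through
# here so it can be silenced with suppressMessages().
.logMsg <- function(...) message("[GenomicOverlaps] ", ...)
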