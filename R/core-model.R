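#' Validate a workspace before analysis
#'
#' Scans the datasets of an [OverlapWorkspace] for problems that commonly
#' arise when mixing annotation sources: inconsistent chromosome naming
#' styles across datasets, differing genome assembly labels, and empty
#' datasets. The workspace is never modified; each finding is returned as
#' a human-readable warning string. A missing query or subject designation
#' is a hard error (raised by the workspace's own validity check).
#'
#' @param ws An [OverlapWorkspace].
#' @return Character vector of issues (length 0 when nothing was found).
#' @examples
#' ws <- makeToyWorkspace()
#' validateWorkspace(ws)
#' @export
validateWorkspace <- function(ws) {
  stopifnot(is(ws, "OverlapWorkspace"))
  validObject(ws)
  issues <- character(0)
  ds <- ws@datasets

  styles <- vapply(ds, chromStyle, character(1))
  if (length(unique(styles)) > 1L)
    issues <- c(issues, sprintf(
      "mixed chromosome naming styles across datasets: %s",
      paste(sprintf("%s=%s", names(styles), styles), collapse = ", ")))
  if (any(styles == "mixed"))
    issues <- c(issues, sprintf(
      "dataset(s) with internally mixed chromosome styles: %s",
      paste(names(styles)[styles == "mixed"], collapse = ", ")))

  labels <- vapply(ds, genomeLabel, character(1))
  known <- labels[!is.na(labels)]
  if (length(unique(known)) > 1L)
    issues <- c(issues, sprintf(
      "differing genome labels across datasets: %s",
      paste(sprintf("%s=%s", names(labels), labels), collapse = ", ")))

  empty <- names(ds)[vapply(ds, function(x) length(x@ranges) == 0L, logical(1))]
  if (length(empty))
    issues <- c(issues, sprintf("empty dataset(s): %s",
                                paste(empty, collapse = ", ")))
  issues
}
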