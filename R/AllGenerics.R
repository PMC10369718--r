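#' @include AllClasses.R
NULL

#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))
#' @export
setGeneric("genomeLabel", function(x) standardGeneric("genomeLabel"))
#' @export
setGeneric("chromStyle", function(x) standardGeneric("chromStyle"))
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @export
setGeneric("regionWidths", function(x) standardGeneric("regionWidths"))
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @export
setGeneric("datasets", function(x) standardGeneric("datasets"))
#' @export
setGeneric("queryName", function(x) standardGeneric("queryName"))
#' @export
setGeneric("queryName<-", function(x, value) standardGeneric("queryName<-"))
#' @export
setGeneric("subjectNames", function(x) standardGeneric("subjectNames"))
#' @export
setGeneric("subjectNames<-", function(x, value) standardGeneric("subjectNames<-"))
#' @export
setGeneric("querySet", function(x) standardGeneric("querySet"))
#' @export
setGeneric("subjectSet", function(x, name) standardGeneric("subjectSet"))
#' @export
setGeneric("workspaceLog", function(x) standardGeneric("workspaceLog"))
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))
#' @export
setGeneric("overlapParams", function(x) standardGeneric("overlapParams"))
#' @export
setGeneric("nHits", function(x) standardGeneric("nHits"))
#' @export
setGeneric("coverageValues", function(x) standardGeneric("coverageValues"))
#' @export
setGeneric("coverageProfile", function(x) standardGeneric("coverageProfile"))
#' @export
setGeneric("keptQueryIndices", function(x) standardGeneric("keptQueryIndices"))
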