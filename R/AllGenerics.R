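#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @export
setGeneric("animal", function(x) standardGeneric("animal"))

#' @export
setGeneric("chemistry", function(x) standardGeneric("chemistry"))

#' @export
setGeneric("snpCalls", function(x) standardGeneric("snpCalls"))

#' @export
setGeneric("readSpace", function(x) standardGeneric("readSpace"))

#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @export
setGeneric("duplications", function(x) standardGeneric("duplications"))

#' @export
setGeneric("divergentSites", function(x) standardGeneric("divergentSites"))

#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' @export
setGeneric("validatedKeys", function(x, ...) standardGeneric("validatedKeys"))
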