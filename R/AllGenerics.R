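#' Gene symbols contained in an object
#'
#' @param x an object holding gene symbols
#' @return character vector of symbols
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' Number of nodes / edges of a network-like object
#'
#' @param x a network-like object
#' @return integer count
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname numNodes
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Seed terminals retained in a subnetwork
#'
#' @param x a [Subnetwork-class]
#' @return character vector
#' @export
setGeneric("terminals", function(x) standardGeneric("terminals"))

#' Recruited non-seed linkers of a subnetwork
#'
#' @param x a [Subnetwork-class]
#' @return character vector
#' @export
setGeneric("linkers", function(x) standardGeneric("linkers"))

#' Seeds excluded from a subnetwork, with reasons
#'
#' @param x a [Subnetwork-class]
#' @return data.frame with columns gene, reason
#' @export
setGeneric("droppedSeeds", function(x) standardGeneric("droppedSeeds"))

#' Result table of a DE or enrichment analysis
#'
#' @param x a [DEResult-class] or [EnrichmentResult-class]
#' @return a \code{DataFrame}
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' Functional groups of a crosstalk graph
#'
#' @param x a [CrosstalkGraph-class]
#' @return list of character vectors of pathway names
#' @export
setGeneric("functionalGroups", function(x) standardGeneric("functionalGroups"))
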