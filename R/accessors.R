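#' @describeIn Interactome gene symbols of all network nodes
#' @param x an object
#' @export
setMethod("geneSymbols", "Interactome", function(x) {
    if (gorder(x@graph)) V(x@graph)$name else character()
})

#' @describeIn GeneSet member gene symbols
#' @export
setMethod("geneSymbols", "GeneSet", function(x) x@genes)

#' @describeIn Subnetwork all node symbols (terminals and linkers)
#' @export
setMethod("geneSymbols", "Subnetwork", function(x) {
    if (gorder(x@graph)) V(x@graph)$name else character()
})

#' @describeIn Interactome node count
#' @export
setMethod("numNodes", "Interactome", function(x) gorder(x@graph))

#' @describeIn Interactome edge count
#' @export
setMethod("numEdges", "Interactome", function(x) gsize(x@graph))

#' @describeIn Subnetwork node count
#' @export
setMethod("numNodes", "Subnetwork", function(x) gorder(x@graph))

#' @describeIn Subnetwork edge count
#' @export
setMethod("numEdges", "Subnetwork", function(x) gsize(x@graph))

#' @describeIn Subnetwork retained seed terminals
#' @export
setMethod("terminals", "Subnetwork", function(x) x@terminals)

#' @describeIn Subnetwork recruited linkers
#' @export
setMethod("linkers", "Subnetwork", function(x) x@linkers)

#' @describeIn Subnetwork excluded seeds with reasons
#' @export
setMethod("droppedSeeds", "Subnetwork", function(x) x@dropped)

#' @describeIn DEResult per-gene result table
#' @export
setMethod("resultTable", "DEResult", function(x) x@table)

#' @describeIn EnrichmentResult per-pathway result table
#' @export
setMethod("resultTable", "EnrichmentResult", function(x) x@table)

#' @describeIn CrosstalkGraph functional groups (components with >= 2 nodes)
#' @export
setMethod("functionalGroups", "CrosstalkGraph", function(x) x@groups)

#' @describeIn PathwayCollection number of pathways
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@pathways))

#' @describeIn PathwayCollection pathway names
#' @export
setMethod("names", "PathwayCollection", function(x) names(x@pathways))

#' Extract one pathway
#' @param x a [PathwayCollection-class]
#' @param i pathway index or name
#' @return a [GeneSet-class]
#' @export
setMethod("[[", "PathwayCollection", function(x, i) x@pathways[[i]])

setMethod("show", "Interactome", function(object) {
    cat(sprintf("Interactome '%s': %d nodes, %d edges\n",
                object@name, numNodes(object), numEdges(object)))
})

setMethod("show", "GeneSet", function(object) {
    g <- object@genes
    preview <- paste(head(g, 6L), collapse = ", ")
    if (length(g) > 6L) preview <- paste0(preview, ", ...")
    cat(sprintf("GeneSet '%s': %d genes [%s]\n",
                object@name, length(g), preview))
})

setMethod("show", "PathwayCollection", function(object) {
    cat(sprintf("PathwayCollection (%s): %d pathways\n",
                object@source, length(object)))
})

setMethod("show", "Subnetwork", function(object) {
    cat(sprintf(
        "Subnetwork for '%s': %d nodes (%d terminals + %d linkers), %d edges; %d seeds dropped\n",
        object@seedName, numNodes(object), length(object@terminals),
        length(object@linkers), numEdges(object), nrow(object@dropped)))
})

setMethod("show", "DEResult", function(object) {
    cat(sprintf("DEResult (%s t-test): %d genes, %d cases vs %d controls\n",
                object@testVariant, nrow(object@table),
                object@nCase, object@nControl))
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf(
        "EnrichmentResult for '%s': %d pathways tested, %d significant (P<%g & hits>=%d), background %d\n",
        object@query, nrow(object@table), sum(object@table$significant),
        object@pCutoff, object@minHits, object@backgroundSize))
})

setMethod("show", "CrosstalkGraph", function(object) {
    cat(sprintf(
        "CrosstalkGraph: %d pathways, %d crosstalk edges, %d functional groups (%d isolated)\n",
        gorder(object@graph), gsize(object@graph),
        length(object@groups), length(object@isolated)))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth (seed %d): %d bridges, %d overlap genes, %d DE genes, %d clustered pathways\n",
        object@seed, length(object@plantedBridges),
        length(object@plantedOverlap), length(object@plantedDE),
        length(object@plantedPathwayClusters)))
})
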