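#' @import methods
#' @importFrom igraph V E gorder gsize is_simple is_directed vcount ecount
#' @importFrom igraph V<- E<-
NULL

setOldClass("igraph")

#' Interactome: an undirected simple protein-protein interaction network
#'
#' Thin S4 wrapper around an undirected simple \pkg{igraph} graph whose
#' vertices are uppercase gene symbols. Invariants (no self loops, no
#' multi-edges, named non-empty symbols) are enforced by the validity method,
#' so every function in the package can rely on them.
#'
#' @slot graph an undirected simple \code{igraph} with a \code{name} vertex
#'   attribute holding gene symbols
#' @slot name a label for the network (e.g. the source database)
#'
#' @seealso [readInteractome()], [genInteractome()]
#' @export
setClass("Interactome", representation(graph = "igraph", name = "character"))

setValidity("Interactome", function(object) {
    g <- object@graph
    msg <- character()
    if (is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (!is_simple(g)) msg <- c(msg, "graph must be simple (no loops/multi-edges)")
    nm <- V(g)$name
    if (is.null(nm) && gorder(g) > 0L) {
        msg <- c(msg, "vertices must carry gene symbols in the 'name' attribute")
    } else if (gorder(g) > 0L) {
        if (anyNA(nm) || any(nm == "") || any(grepl("\\s", nm)))
            msg <- c(msg, "gene symbols must be non-empty and whitespace-free")
        if (anyDuplicated(nm)) msg <- c(msg, "duplicate gene symbols")
    }
    if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct an Interactome from an edge table
#'
#' Builds the network from two character vectors of interactor symbols.
#' Symbols are uppercased and trimmed; self-loops and duplicate (unordered)
#' pairs are dropped.
#'
#' @param from,to character vectors of equal length, one interaction per entry
#' @param name label for the network
#' @param isolated optional character vector of additional node symbols
#' @return an [Interactome-class] object
#' @export
Interactome <- function(from = character(), to = character(),
                        name = "interactome", isolated = character()) {
    stopifnot(length(from) == length(to))
    from <- normalizeSymbols(from)
    to <- normalizeSymbols(to)
    keep <- from != to
    a <- pmin(from[keep], to[keep])
    b <- pmax(from[keep], to[keep])
    dup <- duplicated(paste(a, b, sep = "\t"))
    verts <- sort(unique(c(a, b, normalizeSymbols(isolated))))
    g <- igraph::graph_from_data_frame(
        data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE),
        directed = FALSE, vertices = verts)
    new("Interactome", graph = g, name = name)
}

#' GeneSet: a named set of gene symbols
#'
#' @slot name set label (non-empty)
#' @slot genes character vector of unique, uppercase gene symbols
#' @export
setClass("GeneSet", representation(name = "character", genes = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    g <- object@genes
    if (anyDuplicated(g)) msg <- c(msg, "genes must be unique")
    if (length(g) && (anyNA(g) || any(g == "") || any(g != toupper(g))))
        msg <- c(msg, "genes must be non-empty uppercase symbols")
    if (length(msg)) msg else TRUE
})

#' @param name set label
#' @param genes character vector of symbols (normalized and deduplicated)
#' @return a [GeneSet-class]
#' @rdname GeneSet-class
#' @export
GeneSet <- function(name, genes) {
    new("GeneSet", name = name, genes = sort(unique(normalizeSymbols(genes))))
}

#' PathwayCollection: an ordered list of pathways
#'
#' @slot pathways list of [GeneSet-class] objects with unique names
#' @slot source provenance label (e.g. the GMT file)
#' @export
setClass("PathwayCollection",
         representation(pathways = "list", source = "character"))

setValidity("PathwayCollection", function(object) {
    msg <- character()
    ok <- vapply(object@pathways, is, logical(1), class2 = "GeneSet")
    if (!all(ok)) msg <- c(msg, "all pathways must be GeneSet objects")
    else {
        nms <- vapply(object@pathways, slot, character(1), name = "name")
        if (anyDuplicated(nms)) msg <- c(msg, "pathway names must be unique")
        sz <- vapply(object@pathways, function(p) length(p@genes), integer(1))
        if (any(sz == 0L)) msg <- c(msg, "pathways must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' @param pathways list of [GeneSet-class]
#' @param source provenance label
#' @rdname PathwayCollection-class
#' @export
PathwayCollection <- function(pathways, source = "user") {
    pl <- as.list(pathways)
    names(pl) <- vapply(pl, function(p) p@name, character(1))
    new("PathwayCollection", pathways = pl, source = source)
}

#' Subnetwork: the connected output of Steiner subnetwork construction
#'
#' Nodes are partitioned into seed terminals that made it into the subnetwork
#' and non-seed linkers recruited to connect them. Seeds that could not be
#' included are listed in \code{dropped} with a reason: \code{not-in-network}
#' (absent from the interactome), \code{unreachable} (no path to the winning
#' component), or \code{too-costly} (connecting them would have recruited more
#' linkers per terminal than the cost cap allows).
#'
#' @slot graph induced \code{igraph} subgraph on the selected nodes
#' @slot terminals seed symbols included in the subnetwork
#' @slot linkers recruited non-seed symbols
#' @slot dropped data.frame with columns \code{gene}, \code{reason}
#' @slot seedName label of the seed set that produced this subnetwork
#' @export
setClass("Subnetwork",
         representation(graph = "igraph", terminals = "character",
                        linkers = "character", dropped = "data.frame",
                        seedName = "character"))

setValidity("Subnetwork", function(object) {
    msg <- character()
    g <- object@graph
    nodes <- if (gorder(g)) V(g)$name else character()
    if (length(intersect(object@terminals, object@linkers)))
        msg <- c(msg, "terminals and linkers must be disjoint")
    if (!setequal(nodes, c(object@terminals, object@linkers)))
        msg <- c(msg, "graph nodes must equal terminals + linkers")
    if (gorder(g) > 0L && igraph::count_components(g) != 1L)
        msg <- c(msg, "non-empty subnetwork must be connected")
    if (!identical(sort(colnames(object@dropped)), c("gene", "reason")) &&
        nrow(object@dropped) > 0L)
        msg <- c(msg, "dropped must have columns gene, reason")
    bad <- setdiff(object@dropped$reason,
                   c("not-in-network", "unreachable", "too-costly"))
    if (length(bad)) msg <- c(msg, paste("unknown drop reason:", bad[1]))
    if (length(msg)) msg else TRUE
})

#' SteinerParams: tuning knobs for the Steiner subnetwork heuristic
#'
#' @slot maxMergeCost non-negative cost cap: the maximum number of newly
#'   recruited linkers per merged seed component a single merge may pay
#'   (default 2); merges above the cap are refused and the affected seeds
#'   reported as too costly
#' @export
setClass("SteinerParams", representation(maxMergeCost = "numeric"))

setValidity("SteinerParams", function(object) {
    if (length(object@maxMergeCost) != 1L || is.na(object@maxMergeCost) ||
        object@maxMergeCost < 0)
        "maxMergeCost must be a single non-negative number" else TRUE
})

#' @param maxMergeCost cost cap, linkers per merged seed component
#' @rdname SteinerParams-class
#' @export
SteinerParams <- function(maxMergeCost = 2) {
    new("SteinerParams", maxMergeCost = as.numeric(maxMergeCost))
}

#' ExpressionData: a two-group expression matrix with probe-to-gene mapping
#'
#' Extends \linkS4class{SummarizedExperiment}; the single assay
#' \code{"intensity"} holds already-normalized intensities, \code{colData}
#' carries a \code{group} factor with levels \code{case}/\code{control}, and
#' \code{rowData} may carry a \code{gene} column mapping probes to symbols.
#' No normalization is ever performed by this package.
#'
#' @export
setClass("ExpressionData", contains = "SummarizedExperiment")

setValidity("ExpressionData", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        grp <- as.character(cd$group)
        if (!all(grp %in% c("case", "control")))
            msg <- c(msg, "group labels must be 'case' or 'control'")
    }
    if (length(msg)) msg else TRUE
})

#' @param intensities numeric matrix (probes x samples) of normalized values
#' @param groups character/factor of "case"/"control", one per sample
#' @param probeToGene optional named character vector probe -> gene symbol
#' @return an [ExpressionData-class]
#' @rdname ExpressionData-class
#' @export
ExpressionData <- function(intensities, groups, probeToGene = NULL) {
    if (is.null(colnames(intensities)))
        stop("intensity matrix must have sample column names")
    if (is.null(rownames(intensities)))
        stop("intensity matrix must have probe/gene row names")
    groups <- as.character(groups)
    if (length(groups) != ncol(intensities))
        stop("one group label per sample is required")
    rd <- S4Vectors::DataFrame(row.names = rownames(intensities))
    if (!is.null(probeToGene)) {
        rd$gene <- normalizeSymbols(
            unname(probeToGene[rownames(intensities)]))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = as.matrix(intensities)),
        colData = S4Vectors::DataFrame(
            group = factor(groups, levels = c("case", "control")),
            row.names = colnames(intensities)),
        rowData = rd)
    new("ExpressionData", se)
}

#' DEResult: per-gene two-sample differential expression results
#'
#' @slot table \code{DataFrame} with one row per gene: \code{gene},
#'   \code{meanCase}, \code{meanControl}, \code{t}, \code{p},
#'   \code{degenerate} (TRUE when both groups had zero variance)
#' @slot nCase,nControl group sizes
#' @slot testVariant \code{"welch"} or \code{"pooled"}
#' @export
setClass("DEResult",
         representation(table = "DataFrame", nCase = "integer",
                        nControl = "integer", testVariant = "character"))

setValidity("DEResult", function(object) {
    msg <- character()
    need <- c("gene", "meanCase", "meanControl", "t", "p", "degenerate")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, paste("table must have columns:",
                            paste(need, collapse = ", ")))
    else {
        p <- object@table$p
        if (length(p) && (any(p < 0 | p > 1, na.rm = TRUE)))
            msg <- c(msg, "p-values must lie in [0,1]")
        if (anyDuplicated(object@table$gene))
            msg <- c(msg, "one row per gene required")
    }
    if (!object@testVariant %in% c("welch", "pooled"))
        msg <- c(msg, "testVariant must be 'welch' or 'pooled'")
    if (length(msg)) msg else TRUE
})

#' EnrichmentResult: pathway over-representation results
#'
#' @slot table \code{DataFrame}: \code{pathway}, \code{pathwaySize}
#'   (restricted to the background), \code{nHits}, \code{p},
#'   \code{significant}, and a list column \code{hitGenes}
#' @slot query name of the query gene set
#' @slot minHits,pCutoff the significance thresholds used
#' @slot backgroundSize size of the background universe
#' @export
setClass("EnrichmentResult",
         representation(table = "DataFrame", query = "character",
                        minHits = "integer", pCutoff = "numeric",
                        backgroundSize = "integer"))

setValidity("EnrichmentResult", function(object) {
    need <- c("pathway", "pathwaySize", "nHits", "p", "significant", "hitGenes")
    if (!all(need %in% colnames(object@table)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    tb <- object@table
    nh <- vapply(tb$hitGenes, length, integer(1))
    if (!all(nh == tb$nHits)) return("nHits must equal |hitGenes|")
    exp_sig <- tb$p < object@pCutoff & tb$nHits >= object@minHits
    if (!identical(as.logical(tb$significant), as.logical(exp_sig)))
        return("significant flag inconsistent with thresholds")
    TRUE
})

#' CrosstalkGraph: significant pathways linked by gene-set overlap
#'
#' Nodes are significant pathways (attributes: \code{membership} in
#' \{setA, setB, both\}, \code{nInteresting}); edges carry \code{nShared},
#' \code{jc}, \code{oc} and \code{score} = (jc+oc)/2. \code{groups} lists the
#' connected components with at least two nodes ("functional groups"),
#' ordered by decreasing size.
#'
#' @slot graph undirected \code{igraph}
#' @slot groups list of character vectors of pathway names
#' @slot isolated pathway names with no retained crosstalk edge
#' @export
setClass("CrosstalkGraph",
         representation(graph = "igraph", groups = "list",
                        isolated = "character"))

setValidity("CrosstalkGraph", function(object) {
    g <- object@graph
    if (gsize(g)) {
        jc <- E(g)$jc; oc <- E(g)$oc; sc <- E(g)$score
        if (any(jc < 0 | jc > 1) || any(oc < 0 | oc > 1))
            return("jc and oc must lie in [0,1]")
        if (any(jc > oc + 1e-12))
            return("jc must not exceed oc")
        if (any(abs(sc - (jc + oc) / 2) > 1e-12))
            return("score must equal (jc+oc)/2")
    }
    TRUE
})

#' SyntheticTruth: ground truth planted by the synthetic-data generators
#'
#' @slot plantedBridges non-seed symbols placed so that both Steiner runs
#'   should recruit them as linkers
#' @slot plantedOverlap symbols present in both seed lists
#' @slot plantedDE named numeric vector of per-gene effect sizes (in SD units)
#' @slot plantedPathwayClusters named character: pathway -> cluster label
#' @slot seed RNG seed the artifact was generated with
#' @export
setClass("SyntheticTruth",
         representation(plantedBridges = "character",
                        plantedOverlap = "character",
                        plantedDE = "numeric",
                        plantedPathwayClusters = "character",
                        seed = "integer"))

SyntheticTruth <- function(plantedBridges = character(),
                           plantedOverlap = character(),
                           plantedDE = numeric(),
                           plantedPathwayClusters = character(),
                           seed = NA_integer_) {
    new("SyntheticTruth", plantedBridges = plantedBridges,
        plantedOverlap = plantedOverlap, plantedDE = plantedDE,
        plantedPathwayClusters = plantedPathwayClusters,
        seed = as.integer(seed))
}
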