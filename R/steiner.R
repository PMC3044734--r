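#' Steiner subnetwork construction for a seed gene set
#'
#' Builds a connected subnetwork spanning as many seed genes as possible
#' while recruiting as few non-seed linker proteins as possible — the
#' node-weighted Steiner-tree problem with weight 0 on seeds and 1 on
#' non-seeds. The solver is a deterministic Klein–Ravi style spider-merging
#' heuristic (guaranteed within \code{2*ln(k)} of the optimal linker count
#' for \code{k} seeds): every seed starts as its own component, and the
#' cheapest center-plus-paths "spider" joining two or more components
#' (fewest newly recruited non-seeds per merged component) is merged until
#' one component remains or the cheapest merge exceeds the cost cap.
#' Shortest paths are unweighted breadth-first paths; all ties are broken
#' lexicographically by gene symbol, so the output is fully deterministic.
#'
#' Seeds absent from the network are dropped with reason
#' \code{not-in-network}; seeds whose component never became affordable are
#' \code{too-costly}, or \code{unreachable} when no path to the winning
#' component exists at all. The component containing the most seeds wins
#' (tie: the one containing the lexicographically smallest seed).
#'
#' @param net an [Interactome-class]
#' @param seeds a [GeneSet-class] of seed genes (terminals)
#' @param params a [SteinerParams-class]; \code{maxMergeCost} is the largest
#'   tolerated number of newly recruited linkers per merged seed component
#'   (use \code{Inf} to always connect everything reachable)
#' @param union if \code{TRUE}, return a list of [Subnetwork-class] objects,
#'   one per final component, ordered by decreasing seed count, instead of
#'   only the winning component
#' @return a [Subnetwork-class] (or a list of them when \code{union=TRUE})
#' @examples
#' net <- Interactome(c("A", "B"), c("B", "C"))
#' sn <- steinerSubnetwork(net, GeneSet("s", c("A", "C")))
#' terminals(sn)  # A, C
#' linkers(sn)    # B
#' @export
steinerSubnetwork <- function(net, seeds, params = SteinerParams(),
                              union = FALSE) {
    stopifnot(is(net, "Interactome"), is(seeds, "GeneSet"),
              is(params, "SteinerParams"))
    if (!length(seeds@genes)) stop("empty seed set")
    if (!numNodes(net)) stop("empty interactome")

    nodes <- sort(geneSymbols(net), method = "radix")
    present <- intersect(seeds@genes, nodes)
    notInNet <- setdiff(seeds@genes, nodes)
    emptyDropped <- function(genes, reason) {
        data.frame(gene = genes,
                   reason = rep_len(reason, length(genes)),
                   stringsAsFactors = FALSE)
    }
    if (!length(present)) {
        empty <- new("Subnetwork",
                     graph = igraph::make_empty_graph(0, directed = FALSE),
                     terminals = character(), linkers = character(),
                     dropped = emptyDropped(sort(notInNet), "not-in-network"),
                     seedName = seeds@name)
        return(if (union) list(empty) else empty)
    }

    csr <- buildCSR(net, nodes)
    isSeed <- nodes %in% present
    comp <- .kr_steiner(length(nodes), csr$start, csr$adj, isSeed,
                        params@maxMergeCost)

    inStruct <- comp >= 0L
    compIds <- comp[inStruct]
    seedCount <- table(factor(compIds[isSeed[inStruct]],
                              levels = sort(unique(compIds))))
    winnerId <- as.integer(names(seedCount)[which.max(seedCount)])

    fullComp <- igraph::components(net@graph)$membership[nodes]
    makeSub <- function(id) {
        members <- nodes[inStruct & comp == id]
        terms <- members[members %in% present]
        links <- setdiff(members, terms)
        lost <- setdiff(present, terms)
        reach <- fullComp[lost] %in% fullComp[members]
        drop <- rbind(
            emptyDropped(sort(notInNet), "not-in-network"),
            emptyDropped(sort(lost[reach]), "too-costly"),
            emptyDropped(sort(lost[!reach]), "unreachable"))
        new("Subnetwork", graph = inducedGraph(net, members),
            terminals = sort(terms), linkers = sort(links),
            dropped = drop, seedName = seeds@name)
    }
    if (!union) return(makeSub(winnerId))
    ids <- as.integer(names(sort(seedCount, decreasing = TRUE)))
    lapply(ids, makeSub)
}

# compressed sparse row adjacency in the given (lexicographic) node order
buildCSR <- function(net, nodes) {
    idx <- stats::setNames(seq_along(nodes) - 1L, nodes)
    el <- igraph::as_edgelist(net@graph)
    if (nrow(el)) {
        a <- idx[el[, 1]]; b <- idx[el[, 2]]
        from <- c(a, b); to <- c(b, a)
        o <- order(from, to)
        from <- from[o]; to <- to[o]
    } else {
        from <- integer(); to <- integer()
    }
    start <- c(0L, cumsum(tabulate(from + 1L, nbins = length(nodes))))
    list(start = as.integer(start), adj = as.integer(to))
}

#' Exhaustive Steiner oracle for tiny networks
#'
#' Finds the provably smallest set of non-seed nodes whose union with the
#' seeds induces a connected subgraph containing every seed, by enumerating
#' linker subsets in order of size (ties: lexicographically smallest node
#' set). Intended as an independent reference for validating the heuristic;
#' refuses networks above 15 nodes.
#'
#' @param net an [Interactome-class] with at most 15 nodes
#' @param seeds a [GeneSet-class]; all seeds must lie in one connected
#'   component of \code{net}
#' @return a [Subnetwork-class]
#' @export
exactSteinerOracle <- function(net, seeds) {
    stopifnot(is(net, "Interactome"), is(seeds, "GeneSet"))
    if (numNodes(net) > 15L)
        stop("oracle is exhaustive; at most 15 nodes supported")
    nodes <- sort(geneSymbols(net), method = "radix")
    terms <- intersect(seeds@genes, nodes)
    if (!setequal(terms, seeds@genes))
        stop("unreachable terminals: seeds missing from the network")
    memb <- igraph::components(net@graph)$membership[terms]
    if (length(unique(memb)) != 1L)
        stop("unreachable terminals: seeds span multiple components")
    nonSeeds <- setdiff(nodes, terms)
    found <- NULL
    for (k in 0:length(nonSeeds)) {
        subsets <- if (k == 0L) list(character()) else
            utils::combn(nonSeeds, k, simplify = FALSE)
        for (s in subsets) {
            g <- inducedGraph(net, c(terms, s))
            if (igraph::count_components(g) == 1L) { found <- s; break }
        }
        if (!is.null(found)) break
    }
    new("Subnetwork", graph = inducedGraph(net, c(terms, found)),
        terminals = sort(terms), linkers = sort(found),
        dropped = data.frame(gene = character(), reason = character(),
                             stringsAsFactors = FALSE),
        seedName = seeds@name)
}

#' Node-role table and summary counts for a subnetwork
#'
#' @param subnet a [Subnetwork-class]
#' @return a list with \code{roles} (\code{DataFrame}: gene, role) and
#'   \code{summary} (named counts: nTerminals, nLinkers, and dropped seeds
#'   by reason)
#' @export
classifyNodes <- function(subnet) {
    stopifnot(is(subnet, "Subnetwork"))
    genes <- sort(geneSymbols(subnet), method = "radix")
    roles <- S4Vectors::DataFrame(
        gene = genes,
        role = ifelse(genes %in% subnet@terminals, "terminal", "linker"))
    dropTab <- table(factor(subnet@dropped$reason,
                            levels = c("not-in-network", "unreachable",
                                       "too-costly")))
    summary <- c(nTerminals = length(subnet@terminals),
                 nLinkers = length(subnet@linkers),
                 stats::setNames(as.integer(dropTab),
                                 paste0("nDropped.", names(dropTab))))
    list(roles = roles, summary = summary)
}
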