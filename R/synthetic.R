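#' Generate a synthetic interactome
#'
#' Produces a connected simple undirected network of artificial gene
#' symbols (\code{G0001}, \code{G0002}, ...). The scale-free model
#' (preferential attachment, the default) emulates the heavy-tailed degree
#' distribution of curated PPI databases; the Erdos-Renyi model is a
#' homogeneous control. Only the largest connected component is kept, so
#' slightly fewer than \code{nNodes} nodes may be returned (for extremely
#' sparse Erdos-Renyi settings this may legitimately be a single node).
#'
#' @param nNodes number of nodes before component pruning (>= 10)
#' @param model \code{"scale-free"} or \code{"erdos-renyi"}
#' @param meanDegree target mean degree (edges/node ratio is meanDegree/2);
#'   the default 10 mirrors the roughly 5 interactions per protein of large
#'   curated interactomes
#' @param seed RNG seed
#' @return an [Interactome-class]
#' @export
genInteractome <- function(nNodes = 1000L,
                           model = c("scale-free", "erdos-renyi"),
                           meanDegree = 10, seed = 1L) {
    model <- match.arg(model)
    if (nNodes < 10L) stop("nNodes must be at least 10")
    if (meanDegree < 0 || meanDegree >= nNodes)
        stop("infeasible meanDegree")
    set.seed(seed)
    g <- if (model == "scale-free") {
        m <- max(1L, round(meanDegree / 2))
        igraph::sample_pa(nNodes, m = m, directed = FALSE)
    } else {
        igraph::sample_gnp(nNodes, p = meanDegree / (nNodes - 1))
    }
    V(g)$name <- sprintf(paste0("G%0", nchar(nNodes), "d"),
                         seq_len(igraph::gorder(g)))
    comps <- igraph::components(g)
    keep <- which(comps$membership == which.max(comps$csize))
    g <- igraph::induced_subgraph(g, keep)
    g <- igraph::simplify(g)
    new("Interactome", graph = g, name = sprintf("synthetic-%s", model))
}

#' Plant two seed modules joined by bridge linkers
#'
#' Selects two seed gene sets from an existing interactome so that the
#' Steiner construction of each module must recruit a known set of
#' non-seed "bridge" nodes, and so that \code{nOverlap} genes belong to
#' both seed lists. The graph itself is never modified: each bridge is an
#' existing node chosen together with three of its neighbors per module
#' such that the bridge is the unique common neighbor of every pair of the
#' triple (so connecting the triple cheaply requires the bridge), and each
#' overlap gene is a further neighbor of a bridge (so it attaches to both
#' subnetworks at no extra cost once the bridge is recruited). Later seed
#' picks are constrained so that no non-bridge neighbor of a triple seed
#' becomes adjacent to three or more seeds of the same list: such a hub
#' would connect a triple seed more cheaply than its bridge does.
#' Remaining seeds are otherwise sampled from the local neighborhood of
#' each module to mimic the clustering of disease genes.
#'
#' With \code{nBridges = 0} no recruitment structure is planted; overlap
#' genes are then sampled at random and their recovery by the pipeline is
#' not guaranteed.
#'
#' @param net an [Interactome-class]
#' @param nSeedsA,nSeedsB seed list sizes (must each be at least
#'   \code{3*nBridges + nOverlap})
#' @param nBridges number of planted bridge linkers
#' @param nOverlap number of genes present in both seed lists
#' @param seed RNG seed
#' @return list with \code{seedsA}, \code{seedsB} ([GeneSet-class]) and
#'   \code{truth} ([SyntheticTruth-class])
#' @export
genSeedSets <- function(net, nSeedsA = 40L, nSeedsB = 20L, nBridges = 4L,
                        nOverlap = 5L, seed = 1L) {
    stopifnot(is(net, "Interactome"))
    if (nSeedsA < 3L * nBridges + nOverlap ||
        nSeedsB < 3L * nBridges + nOverlap)
        stop("seed lists too small for the requested bridges and overlap")
    set.seed(seed)
    g <- net@graph
    nodes <- sort(geneSymbols(net), method = "radix")
    if (length(nodes) < nSeedsA + nSeedsB + nBridges + 10L)
        stop("interactome too small for the requested seed sets")
    deg <- igraph::degree(g)[nodes]
    adj <- lapply(igraph::adjacent_vertices(g, nodes), function(v) v$name)
    names(adj) <- nodes

    used <- character()
    bridges <- character()
    seedsA <- character(); seedsB <- character()

    # unique-common-neighbor check for a triple around a bridge
    tripleOK <- function(b, triple) {
        for (i in 1:2) for (j in (i + 1):3) {
            u <- triple[i]; v <- triple[j]
            if (u %in% adj[[v]]) return(FALSE)
            if (!identical(sort(intersect(adj[[u]], adj[[v]])), b))
                return(FALSE)
        }
        TRUE
    }
    # Per-module guard: seedAdj counts, per node, how many already-chosen
    # seeds of that list it touches; tripleNbrs is the set of non-bridge
    # neighbors of planted triple seeds. A candidate seed is admissible if
    # it does not raise any tripleNbrs node to >= 3 seed adjacencies,
    # which would let that node out-compete a bridge's merge ratio.
    seedAdjA <- stats::setNames(integer(length(nodes)), nodes)
    seedAdjB <- stats::setNames(integer(length(nodes)), nodes)
    tripleNbrsA <- character(); tripleNbrsB <- character()
    admissible <- function(f, seedAdj, tripleNbrs) {
        if (f %in% tripleNbrs) return(FALSE)  # adjacency would bypass the bridge
        xs <- setdiff(intersect(adj[[f]], tripleNbrs), bridges)
        !length(xs) || all(seedAdj[xs] + 1L <= 2L)
    }
    countSeed <- function(f, seedAdj) {
        seedAdj[adj[[f]]] <- seedAdj[adj[[f]]] + 1L
        seedAdj
    }
    pickTriple <- function(b, pool, seedAdj, tripleNbrs) {
        if (length(pool) < 3L) return(NULL)
        for (i in seq_len(25L)) {
            tr <- sample(pool, 3L)
            if (tripleOK(b, tr) &&
                all(vapply(tr, admissible, logical(1), seedAdj, tripleNbrs)))
                return(tr)
        }
        NULL
    }

    overlapPerBridge <- if (nBridges > 0L)
        tabulate(rep(seq_len(nBridges), length.out = nOverlap),
                 nbins = nBridges) else integer()
    overlap <- character()
    attempts <- 0L
    while (length(bridges) < nBridges) {
        attempts <- attempts + 1L
        if (attempts > 100L)
            stop("infeasible placement: could not plant bridges after 100 attempts")
        need <- 6L + overlapPerBridge[length(bridges) + 1L]
        cand <- setdiff(nodes[deg >= need + 1L], c(used, bridges))
        if (!length(cand)) stop("infeasible placement: no bridge candidates")
        b <- sample(cand, 1L)
        nb <- setdiff(adj[[b]], c(used, bridges))
        if (length(nb) < need) next
        trA <- pickTriple(b, nb, seedAdjA, tripleNbrsA)
        if (is.null(trA)) next
        trB <- pickTriple(b, setdiff(nb, trA), seedAdjB, tripleNbrsB)
        if (is.null(trB)) next
        ovPool <- Filter(function(f) admissible(f, seedAdjA, tripleNbrsA) &&
                                      admissible(f, seedAdjB, tripleNbrsB),
                         setdiff(nb, c(trA, trB)))
        nOv <- overlapPerBridge[length(bridges) + 1L]
        if (length(ovPool) < nOv) next
        ov <- if (nOv > 0L) sample(ovPool, nOv) else character()
        bridges <- c(bridges, b)
        seedsA <- c(seedsA, trA); seedsB <- c(seedsB, trB)
        overlap <- c(overlap, ov)
        used <- c(used, trA, trB, ov)
        for (f in c(trA, ov)) seedAdjA <- countSeed(f, seedAdjA)
        for (f in c(trB, ov)) seedAdjB <- countSeed(f, seedAdjB)
        tripleNbrsA <- union(tripleNbrsA, unlist(adj[trA]))
        tripleNbrsB <- union(tripleNbrsB, unlist(adj[trB]))
    }
    if (nBridges == 0L && nOverlap > 0L) {
        overlap <- sample(setdiff(nodes[deg >= 3L], used), nOverlap)
        used <- c(used, overlap)
    }

    # fill each module from the neighborhood of its current seeds,
    # respecting the bridge-protection rule
    fillModule <- function(core, nNeeded, seedAdj, tripleNbrs) {
        extra <- character()
        anchor <- if (length(core)) core else sample(nodes, 1L)
        d <- igraph::distances(g, v = anchor, to = nodes)
        d <- apply(d, 2L, min)
        radius <- 2L
        while (length(extra) < nNeeded) {
            pool <- setdiff(nodes[d <= radius],
                            c(used, bridges, core, extra))
            pool <- if (length(pool) > 1L) sample(pool) else pool
            for (f in pool) {
                if (!admissible(f, seedAdj, tripleNbrs)) next
                extra <- c(extra, f)
                seedAdj <- countSeed(f, seedAdj)
                if (length(extra) == nNeeded) break
            }
            radius <- radius + 1L
            if (radius > length(nodes))
                stop("infeasible placement: module fill")
        }
        extra
    }
    nFreeA <- nSeedsA - length(seedsA) - nOverlap
    seedsA <- c(seedsA, fillModule(seedsA, nFreeA, seedAdjA, tripleNbrsA))
    used <- c(used, seedsA)
    nFreeB <- nSeedsB - length(seedsB) - nOverlap
    seedsB <- c(seedsB, fillModule(seedsB, nFreeB, seedAdjB, tripleNbrsB))
    used <- c(used, seedsB)

    list(seedsA = GeneSet("seedsA", c(seedsA, overlap)),
         seedsB = GeneSet("seedsB", c(seedsB, overlap)),
         truth = SyntheticTruth(plantedBridges = sort(bridges),
                                plantedOverlap = sort(overlap),
                                seed = seed))
}

#' Generate a normalized two-group expression matrix with planted DE genes
#'
#' Intensities are drawn per probe and sample from Normal(8, 1), a
#' log-scale-like baseline typical of normalized bead arrays. A fraction
#' \code{deFraction} of genes is shifted upward by \code{effectSd} standard
#' deviations in the case group. Ten percent of genes carry a second probe
#' whose baseline is two units lower, to exercise max-mean probe collapse.
#'
#' @param genes character vector of gene symbols to measure
#' @param nCase,nControl group sizes (defaults 7 and 8, a typical small
#'   case-control deletion-carrier design)
#' @param deFraction fraction of genes differentially expressed
#' @param effectSd case-group shift in SD units for planted genes
#' @param seed RNG seed
#' @return list with \code{expr} ([ExpressionData-class], probe-level) and
#'   \code{truth} ([SyntheticTruth-class] with \code{plantedDE})
#' @export
genExpression <- function(genes, nCase = 7L, nControl = 8L,
                          deFraction = 0.05, effectSd = 2, seed = 1L) {
    if (deFraction < 0 || deFraction > 1)
        stop("deFraction must lie in [0, 1]")
    genes <- normalizeSymbols(genes)
    set.seed(seed)
    nG <- length(genes)
    nS <- nCase + nControl
    samples <- sprintf("S%02d", seq_len(nS))
    groups <- rep(c("case", "control"), c(nCase, nControl))
    nDE <- round(deFraction * nG)
    de <- if (nDE > 0L) sort(sample(genes, nDE)) else character()

    mainProbes <- paste0(genes, "_p1")
    mat <- matrix(stats::rnorm(nG * nS, mean = 8, sd = 1), nrow = nG,
                  dimnames = list(mainProbes, samples))
    shift <- ifelse(genes %in% de, effectSd, 0)
    mat[, groups == "case"] <- mat[, groups == "case"] + shift
    map <- stats::setNames(genes, mainProbes)

    nDup <- round(0.1 * nG)
    if (nDup > 0L) {
        dupGenes <- sort(sample(genes, nDup))
        dupProbes <- paste0(dupGenes, "_p2")
        dup <- matrix(stats::rnorm(nDup * nS, mean = 6, sd = 1), nrow = nDup,
                      dimnames = list(dupProbes, samples))
        dshift <- ifelse(dupGenes %in% de, effectSd, 0)
        dup[, groups == "case"] <- dup[, groups == "case"] + dshift
        mat <- rbind(mat, dup)
        map <- c(map, stats::setNames(dupGenes, dupProbes))
    }
    expr <- ExpressionData(mat, groups, map)
    list(expr = expr,
         truth = SyntheticTruth(
             plantedDE = stats::setNames(rep(effectSd, length(de)), de),
             seed = seed))
}

#' Generate a pathway collection with planted crosstalk clusters
#'
#' Each cluster of \code{clusterSpec} is a list/vector
#' \code{c(clusterSize, sharedCoreSize)}: its pathways share a random core
#' of \code{sharedCoreSize} genes, while all non-core members are unique to
#' a single pathway across the whole collection, so pathways from different
#' clusters share no genes at all. Pathways beyond the clustered ones are
#' singletons with entirely unique genes.
#'
#' @param genes universe to draw members from
#' @param nPathways total number of pathways
#' @param clusterSpec list of \code{c(clusterSize, sharedCoreSize)} pairs
#' @param pathwaySize genes per pathway (identical for all)
#' @param seed RNG seed
#' @return list with \code{collection} ([PathwayCollection-class]) and
#'   \code{truth} (cluster labels in \code{plantedPathwayClusters};
#'   unclustered pathways are labelled \code{"noise"})
#' @export
genPathways <- function(genes, nPathways = 40L,
                        clusterSpec = list(c(6L, 4L), c(5L, 4L),
                                           c(4L, 4L), c(4L, 4L)),
                        pathwaySize = 20L, seed = 1L) {
    genes <- normalizeSymbols(genes)
    sizes <- vapply(clusterSpec, `[`, numeric(1), 1L)
    cores <- vapply(clusterSpec, `[`, numeric(1), 2L)
    if (any(cores >= pathwaySize)) stop("infeasible spec: core >= pathwaySize")
    nClustered <- sum(sizes)
    if (nClustered > nPathways) stop("infeasible spec: too many clustered pathways")
    needed <- sum(cores + sizes * (pathwaySize - cores)) +
        (nPathways - nClustered) * pathwaySize
    if (needed > length(genes))
        stop(sprintf("infeasible spec: need %d unique genes, have %d",
                     needed, length(genes)))
    set.seed(seed)
    pool <- sample(genes)
    takeGenes <- function(n) {
        out <- pool[seq_len(n)]
        pool <<- pool[-seq_len(n)]
        out
    }
    pathways <- list()
    labels <- character()
    pwName <- function(i) sprintf("PW%02d", i)
    idx <- 0L
    for (ci in seq_along(clusterSpec)) {
        core <- takeGenes(cores[ci])
        for (j in seq_len(sizes[ci])) {
            idx <- idx + 1L
            members <- c(core, takeGenes(pathwaySize - cores[ci]))
            pathways[[pwName(idx)]] <- GeneSet(pwName(idx), members)
            labels[pwName(idx)] <- paste0("cluster", ci)
        }
    }
    while (idx < nPathways) {
        idx <- idx + 1L
        pathways[[pwName(idx)]] <- GeneSet(pwName(idx), takeGenes(pathwaySize))
        labels[pwName(idx)] <- "noise"
    }
    list(collection = PathwayCollection(pathways, source = "synthetic"),
         truth = SyntheticTruth(plantedPathwayClusters = labels,
                                seed = seed))
}

#' Simulate a complete convergent-analysis study
#'
#' The \code{"paperlike"} preset generates, at desk scale, inputs with the
#' structure of a CNV-gene / curated-gene convergence study: a 1000-node
#' scale-free interactome with mean degree 10 (the ~5 interactions per
#' protein of large curated PPI sets), two seed lists of 40 and 20 genes
#' (preserving the roughly 2:1 size ratio of typical CNV versus curated
#' lists) sharing 5 genes and joined through 4 planted bridge linkers, a
#' 7-case / 8-control expression matrix over all interactome genes with 5%
#' of genes shifted by 2 SD, and 40 equal-size pathways containing four
#' planted crosstalk clusters.
#'
#' @param preset currently only \code{"paperlike"}
#' @param seed RNG seed controlling every generator
#' @param outDir if non-NULL, write \code{ppi.tsv}, \code{seeds_a.txt},
#'   \code{seeds_b.txt}, \code{expr.tsv}, \code{groups.tsv},
#'   \code{probe_map.tsv}, \code{pathways.gmt} and \code{truth.json} there
#' @return list with \code{net}, \code{seedsA}, \code{seedsB}, \code{expr},
#'   \code{collection}, \code{truth} ([SyntheticTruth-class] merging all
#'   planted structure)
#' @export
simulateStudy <- function(preset = "paperlike", seed = 1L, outDir = NULL) {
    preset <- match.arg(preset, "paperlike")
    set.seed(seed)
    subSeeds <- sample.int(.Machine$integer.max, 4L)
    net <- genInteractome(1000L, "scale-free", 10, seed = subSeeds[1])
    ss <- genSeedSets(net, nSeedsA = 40L, nSeedsB = 20L, nBridges = 4L,
                      nOverlap = 5L, seed = subSeeds[2])
    ex <- genExpression(geneSymbols(net), nCase = 7L, nControl = 8L,
                        deFraction = 0.05, effectSd = 2,
                        seed = subSeeds[3])
    pw <- genPathways(geneSymbols(net), nPathways = 40L,
                      pathwaySize = 20L, seed = subSeeds[4])
    truth <- SyntheticTruth(
        plantedBridges = ss$truth@plantedBridges,
        plantedOverlap = ss$truth@plantedOverlap,
        plantedDE = ex$truth@plantedDE,
        plantedPathwayClusters = pw$truth@plantedPathwayClusters,
        seed = as.integer(seed))
    validateTruth(truth, net, ss$seedsA, ss$seedsB, ex$expr, pw$collection)

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        fp <- function(f) file.path(outDir, f)
        writeInteractome(net, fp("ppi.tsv"))
        writeGeneSet(ss$seedsA, fp("seeds_a.txt"))
        writeGeneSet(ss$seedsB, fp("seeds_b.txt"))
        mat <- SummarizedExperiment::assay(ex$expr, "intensity")
        utils::write.table(
            data.frame(probe = rownames(mat), mat, check.names = FALSE),
            fp("expr.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        cd <- SummarizedExperiment::colData(ex$expr)
        writeLines(paste(rownames(cd), cd$group, sep = "\t"),
                   fp("groups.tsv"))
        rd <- SummarizedExperiment::rowData(ex$expr)
        writeLines(paste(rownames(mat), rd$gene, sep = "\t"),
                   fp("probe_map.tsv"))
        writeGMT(pw$collection, fp("pathways.gmt"))
        jsonlite::write_json(
            list(planted_bridges = truth@plantedBridges,
                 planted_overlap = truth@plantedOverlap,
                 planted_de = as.list(truth@plantedDE),
                 planted_pathway_clusters =
                     as.list(truth@plantedPathwayClusters),
                 rng_seed = truth@seed),
            fp("truth.json"), auto_unbox = TRUE, digits = NA)
    }
    list(net = net, seedsA = ss$seedsA, seedsB = ss$seedsB,
         expr = ex$expr, collection = pw$collection, truth = truth)
}

#' Check that every planted symbol exists in its generated artifact
#'
#' @param truth a [SyntheticTruth-class]
#' @param net,seedsA,seedsB,expr,collection the generated artifacts
#'   (any may be NULL to skip its check)
#' @return TRUE invisibly; stops on an inconsistency
#' @export
validateTruth <- function(truth, net = NULL, seedsA = NULL, seedsB = NULL,
                          expr = NULL, collection = NULL) {
    stopifnot(is(truth, "SyntheticTruth"))
    if (!is.null(net)) {
        nodes <- geneSymbols(net)
        if (!all(truth@plantedBridges %in% nodes))
            stop("planted bridges missing from interactome")
        if (!all(truth@plantedOverlap %in% nodes))
            stop("planted overlap genes missing from interactome")
    }
    if (!is.null(seedsA) && !all(truth@plantedOverlap %in% seedsA@genes))
        stop("planted overlap genes missing from seedsA")
    if (!is.null(seedsB) && !all(truth@plantedOverlap %in% seedsB@genes))
        stop("planted overlap genes missing from seedsB")
    if (!is.null(expr)) {
        g <- SummarizedExperiment::rowData(expr)$gene
        if (!all(names(truth@plantedDE) %in% g))
            stop("planted DE genes missing from expression matrix")
    }
    if (!is.null(collection) && length(truth@plantedPathwayClusters)) {
        if (!all(names(truth@plantedPathwayClusters) %in% names(collection)))
            stop("planted pathway clusters missing from collection")
    }
    invisible(TRUE)
}
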