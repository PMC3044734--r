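#' Pathway over-representation analysis
#'
#' One-sided hypergeometric (Fisher's exact) test of a query gene set
#' against every pathway of a collection, given a background universe:
#' with \code{k} query genes in the pathway, \code{K} pathway genes in the
#' background, \code{n} query genes and a background of \code{N}, the
#' p-value is the upper tail \code{P(X >= k)}. A pathway is called
#' significant when \code{p < pCutoff} and it contains at least
#' \code{minHits} genes of interest (both thresholds are recorded in the
#' result).
#'
#' Query genes outside the background are dropped with a warning; pathway
#' gene sets are intersected with the background before testing.
#'
#' @param query a [GeneSet-class] of genes of interest (e.g. subnetwork
#'   genes)
#' @param collection a [PathwayCollection-class]
#' @param background a [GeneSet-class] universe (e.g. all interactome genes)
#' @param minHits minimum number of query genes in a significant pathway
#' @param pCutoff p-value threshold for significance
#' @return an [EnrichmentResult-class]
#' @export
fisherEnrich <- function(query, collection, background,
                         minHits = 5L, pCutoff = 0.01) {
    stopifnot(is(query, "GeneSet"), is(collection, "PathwayCollection"),
              is(background, "GeneSet"))
    if (!length(collection)) stop("empty pathway collection")
    bg <- background@genes
    q <- query@genes
    outside <- setdiff(q, bg)
    if (length(outside) == length(q) && length(q))
        stop("background smaller than query: no query gene in background")
    if (length(outside)) {
        warning(sprintf("%d query genes outside the background were dropped",
                        length(outside)))
        q <- intersect(q, bg)
    }
    N <- length(bg); n <- length(q)
    rows <- lapply(collection@pathways, function(pw) {
        pwBg <- intersect(pw@genes, bg)
        hits <- intersect(q, pwBg)
        k <- length(hits); K <- length(pwBg)
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        list(pathway = pw@name, pathwaySize = K, nHits = k, p = p,
             hits = sort(hits, method = "radix"))
    })
    tab <- S4Vectors::DataFrame(
        pathway = unname(vapply(rows, `[[`, character(1), "pathway")),
        pathwaySize = unname(vapply(rows, `[[`, integer(1), "pathwaySize")),
        nHits = unname(vapply(rows, `[[`, integer(1), "nHits")),
        p = unname(vapply(rows, `[[`, numeric(1), "p")))
    tab$significant <- tab$p < pCutoff & tab$nHits >= minHits
    tab$hitGenes <- S4Vectors::SimpleList(unname(lapply(rows, `[[`, "hits")))
    tab <- tab[order(tab$p, tab$pathway, method = "radix"), ]
    rownames(tab) <- NULL
    new("EnrichmentResult", table = tab, query = query@name,
        minHits = as.integer(minHits), pCutoff = pCutoff,
        backgroundSize = as.integer(N))
}

#' Crosstalk score between two gene sets
#'
#' Jaccard coefficient \code{JC = |A∩B| / |A∪B|}, overlap coefficient
#' \code{OC = |A∩B| / min(|A|, |B|)}, and the crosstalk score, their mean.
#' \code{JC <= OC} always holds.
#'
#' @param a,b [GeneSet-class] objects or plain character vectors (non-empty)
#' @return named numeric vector \code{c(jc, oc, score)}
#' @examples
#' crosstalkScore(c("a", "b", "c"), c("b", "c", "d"))  # 0.5, 2/3, 7/12
#' @export
crosstalkScore <- function(a, b) {
    ga <- if (is(a, "GeneSet")) a@genes else normalizeSymbols(a)
    gb <- if (is(b, "GeneSet")) b@genes else normalizeSymbols(b)
    if (!length(ga) || !length(gb)) stop("empty gene set")
    i <- length(intersect(ga, gb))
    jc <- i / length(union(ga, gb))
    oc <- i / min(length(unique(ga)), length(unique(gb)))
    c(jc = jc, oc = oc, score = (jc + oc) / 2)
}

#' Build the pathway crosstalk graph
#'
#' Within each enrichment result, every pair of significant pathways sharing
#' at least \code{minShared} genes gets a candidate edge scored by
#' [crosstalkScore()]. Only the top-scoring edges are retained: those with
#' score at or above the \code{1 - topFraction} quantile of that result's
#' candidate edge scores (ties at the threshold kept). The two filtered
#' graphs are united; when the same pathway pair survives in both, the
#' higher-scoring version supplies the edge attributes. Nodes are all
#' significant pathways with a \code{membership} attribute (\code{setA},
#' \code{setB}, or \code{both} when significant in both results) and
#' \code{nInteresting}, the number of distinct genes of interest the pathway
#' contains across both queries. Functional groups are the connected
#' components with at least two pathways, ordered by decreasing size.
#'
#' By default overlaps are computed on each pathway's genes of interest
#' (its enrichment hits); \code{fullSets = TRUE} uses the complete pathway
#' gene sets from \code{collection} instead.
#'
#' @param enrichA,enrichB [EnrichmentResult-class] objects for the two
#'   queries
#' @param minShared minimum number of shared genes for a candidate edge
#' @param topFractionA,topFractionB fraction of top-scoring candidate edges
#'   retained per result, in (0, 1]
#' @param fullSets use full pathway gene sets instead of enrichment hits
#' @param collection the [PathwayCollection-class]; required when
#'   \code{fullSets = TRUE}
#' @return a [CrosstalkGraph-class]
#' @export
buildCrosstalkGraph <- function(enrichA, enrichB, minShared = 3L,
                                topFractionA = 0.01, topFractionB = 0.05,
                                fullSets = FALSE, collection = NULL) {
    stopifnot(is(enrichA, "EnrichmentResult"), is(enrichB, "EnrichmentResult"))
    for (tf in c(topFractionA, topFractionB))
        if (!is.numeric(tf) || tf <= 0 || tf > 1)
            stop("top fractions must lie in (0, 1]")
    if (fullSets && is.null(collection))
        stop("collection is required when fullSets = TRUE")

    edgeSet <- function(enrich, topFraction) {
        tb <- enrich@table[enrich@table$significant, , drop = FALSE]
        if (nrow(tb) < 2L) {
            return(data.frame(a = character(), b = character(),
                              nShared = integer(), jc = numeric(),
                              oc = numeric(), score = numeric(),
                              stringsAsFactors = FALSE))
        }
        sets <- lapply(seq_len(nrow(tb)), function(i) {
            if (fullSets) collection[[tb$pathway[i]]]@genes
            else tb$hitGenes[[i]]
        })
        names(sets) <- tb$pathway
        pairs <- utils::combn(sort(tb$pathway, method = "radix"), 2L)
        rows <- lapply(seq_len(ncol(pairs)), function(j) {
            pa <- pairs[1, j]; pb <- pairs[2, j]
            shared <- length(intersect(sets[[pa]], sets[[pb]]))
            if (shared < minShared) return(NULL)
            sc <- crosstalkScore(sets[[pa]], sets[[pb]])
            data.frame(a = pa, b = pb, nShared = shared,
                       jc = sc[["jc"]], oc = sc[["oc"]],
                       score = sc[["score"]], stringsAsFactors = FALSE)
        })
        ed <- do.call(rbind, rows)
        if (is.null(ed) || !nrow(ed)) {
            return(data.frame(a = character(), b = character(),
                              nShared = integer(), jc = numeric(),
                              oc = numeric(), score = numeric(),
                              stringsAsFactors = FALSE))
        }
        thr <- stats::quantile(ed$score, probs = 1 - topFraction,
                               names = FALSE, type = 7)
        ed[ed$score >= thr, , drop = FALSE]
    }

    edA <- edgeSet(enrichA, topFractionA)
    edB <- edgeSet(enrichB, topFractionB)
    both <- rbind(edA, edB)
    if (nrow(both)) {
        key <- paste(both$a, both$b, sep = "\t")
        # same pair retained in both results: keep the higher-scoring edge
        both <- both[order(key, -both$score, method = "radix"), , drop = FALSE]
        both <- both[!duplicated(paste(both$a, both$b, sep = "\t")), ,
                     drop = FALSE]
    }

    sigA <- enrichA@table$pathway[enrichA@table$significant]
    sigB <- enrichB@table$pathway[enrichB@table$significant]
    nodes <- sort(union(sigA, sigB), method = "radix")
    membership <- ifelse(nodes %in% sigA & nodes %in% sigB, "both",
                  ifelse(nodes %in% sigA, "setA", "setB"))
    hitsOf <- function(enrich, pw) {
        i <- match(pw, enrich@table$pathway)
        if (is.na(i)) character() else enrich@table$hitGenes[[i]]
    }
    nInteresting <- vapply(nodes, function(pw) {
        length(union(if (pw %in% sigA) hitsOf(enrichA, pw) else character(),
                     if (pw %in% sigB) hitsOf(enrichB, pw) else character()))
    }, integer(1))

    g <- igraph::graph_from_data_frame(
        both[, c("a", "b", "nShared", "jc", "oc", "score"), drop = FALSE],
        directed = FALSE,
        vertices = data.frame(name = nodes, membership = membership,
                              nInteresting = nInteresting,
                              stringsAsFactors = FALSE))
    comps <- igraph::components(g)
    groups <- split(nodes, comps$membership[nodes])
    groups <- lapply(groups, function(x) sort(x, method = "radix"))
    groups <- groups[lengths(groups) >= 2L]
    ord <- order(-lengths(groups),
                 vapply(groups, `[`, character(1), 1L), method = "radix")
    groups <- unname(groups[ord])
    isolated <- nodes[igraph::degree(g) == 0L]
    new("CrosstalkGraph", graph = g, groups = groups, isolated = isolated)
}

#' Functional-group table of a crosstalk graph
#'
#' One row per pathway in a functional group (connected component with at
#' least two pathways); isolated pathways are listed with group \code{NA}.
#'
#' @param graph a [CrosstalkGraph-class]
#' @return a \code{DataFrame} with columns \code{group}, \code{pathway},
#'   \code{membership}, \code{nInteresting}
#' @export
functionalGroupTable <- function(graph) {
    stopifnot(is(graph, "CrosstalkGraph"))
    g <- graph@graph
    rows <- do.call(rbind, c(
        lapply(seq_along(graph@groups), function(i) {
            data.frame(group = i, pathway = graph@groups[[i]],
                       stringsAsFactors = FALSE)
        }),
        list(if (length(graph@isolated))
            data.frame(group = NA_integer_, pathway = graph@isolated,
                       stringsAsFactors = FALSE))))
    if (is.null(rows))
        return(S4Vectors::DataFrame(group = integer(), pathway = character(),
                                    membership = character(),
                                    nInteresting = integer()))
    idx <- match(rows$pathway, V(g)$name)
    S4Vectors::DataFrame(group = rows$group, pathway = rows$pathway,
                         membership = V(g)$membership[idx],
                         nInteresting = V(g)$nInteresting[idx])
}

#' Write an enrichment result as TSV
#'
#' @param enrich an [EnrichmentResult-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeEnrichment <- function(enrich, path) {
    tb <- enrich@table
    df <- data.frame(pathway = tb$pathway, pathwaySize = tb$pathwaySize,
                     nHits = tb$nHits, p = tb$p,
                     significant = ifelse(tb$significant, "Y", "N"),
                     hitGenes = vapply(tb$hitGenes, paste,
                                       character(1), collapse = ","),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a crosstalk graph as GraphML, plus a groups TSV
#'
#' @param graph a [CrosstalkGraph-class]
#' @param path GraphML output file
#' @param groupsPath optional TSV for the functional-group table
#' @return \code{path}, invisibly
#' @export
writeCrosstalkGraph <- function(graph, path, groupsPath = NULL) {
    igraph::write_graph(graph@graph, path, format = "graphml")
    if (!is.null(groupsPath)) {
        utils::write.table(as.data.frame(functionalGroupTable(graph)),
                           groupsPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}
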