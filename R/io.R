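#' Read a protein-protein interaction network
#'
#' Two dialects are supported. \code{"edge-list"} expects two tab-separated
#' gene-symbol columns per line; lines starting with \code{#} are comments.
#' \code{"mitab-lite"} consumes only the first two interactor columns of a
#' PSI-MI TAB style export, stripping database prefixes of the form
#' \code{prefix:VALUE}; an optional \code{symbolMap} (named character vector,
#' accession -> gene symbol) translates the stripped values. Records whose
#' accession has no map entry are dropped with a logged count.
#'
#' Self-loops and duplicate undirected edges are removed; the number of
#' dropped records is reported via \code{message()}.
#'
#' @param path input file
#' @param dialect \code{"edge-list"} or \code{"mitab-lite"}
#' @param symbolMap optional named character vector used by the mitab-lite
#'   dialect to map interactor accessions to gene symbols
#' @param name network label (defaults to the file name)
#' @return an [Interactome-class]
#' @export
readInteractome <- function(path, dialect = c("edge-list", "mitab-lite"),
                            symbolMap = NULL, name = basename(path)) {
    dialect <- match.arg(dialect)
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) stop("empty interaction file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 2L)
    if (length(short))
        stop(sprintf("malformed interaction record at line %d of %s: fewer than 2 columns",
                     lineNo[short[1]], path))
    a <- vapply(parts, `[[`, character(1), 1L)
    b <- vapply(parts, `[[`, character(1), 2L)
    if (dialect == "mitab-lite") {
        a <- sub("^[^:\t]*:", "", a)
        b <- sub("^[^:\t]*:", "", b)
        if (!is.null(symbolMap)) {
            ma <- symbolMap[a]; mb <- symbolMap[b]
            unmapped <- is.na(ma) | is.na(mb)
            if (any(unmapped))
                cnMessage("dropped %d mitab records with unmapped interactors",
                          sum(unmapped))
            a <- unname(ma[!unmapped]); b <- unname(mb[!unmapped])
        }
    }
    net <- Interactome(a, b, name = name)
    nDropped <- length(a) - numEdges(net)
    if (nDropped > 0L)
        cnMessage("dropped %d records (self-loops/duplicates) reading %s",
                  nDropped, path)
    cnMessage("interactome '%s': %d nodes, %d edges", name,
              numNodes(net), numEdges(net))
    net
}

#' Write an interactome as an edge list
#'
#' @param net an [Interactome-class]
#' @param path output file
#' @param dialect \code{"edge-list"} (plain two-column TSV) or
#'   \code{"mitab-lite"} (the two symbols prefixed with \code{symbol:})
#' @return \code{path}, invisibly
#' @export
writeInteractome <- function(net, path,
                             dialect = c("edge-list", "mitab-lite")) {
    dialect <- match.arg(dialect)
    el <- igraph::as_edgelist(net@graph)
    if (dialect == "mitab-lite" && nrow(el))
        el[] <- paste0("symbol:", el)
    writeLines(if (nrow(el)) paste(el[, 1], el[, 2], sep = "\t") else character(),
               path)
    invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and \code{#} comments are ignored;
#' symbols are uppercased and deduplicated.
#'
#' @param path input file
#' @param name label for the resulting set
#' @return a [GeneSet-class]
#' @export
readGeneSet <- function(path, name = basename(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("empty gene set: ", path)
    GeneSet(name, lines)
}

#' Write a gene list, one symbol per line
#'
#' @param geneSet a [GeneSet-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeGeneSet <- function(geneSet, path) {
    writeLines(geneSet@genes, path)
    invisible(path)
}

#' Read a pathway collection in GMT format
#'
#' Standard GMT: per line, pathway name, description, then member genes, all
#' tab-separated. The description column is discarded (logged). Lines without
#' any member gene are skipped with a warning; duplicate pathway names are an
#' error.
#'
#' @param path input GMT file
#' @return a [PathwayCollection-class]
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty GMT file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    pathways <- list()
    for (i in seq_along(parts)) {
        p <- parts[[i]]
        if (length(p) < 3L) {
            warning(sprintf("GMT line %d has no member genes; skipped", i))
            next
        }
        nm <- trimws(p[1])
        if (nm %in% names(pathways))
            stop("duplicate pathway name in GMT: ", nm)
        pathways[[nm]] <- GeneSet(nm, p[-(1:2)])
    }
    if (!length(pathways)) stop("no usable pathways in GMT file: ", path)
    cnMessage("read %d pathways from %s (descriptions discarded)",
              length(pathways), path)
    PathwayCollection(pathways, source = basename(path))
}

#' Write a pathway collection in GMT format
#'
#' @param collection a [PathwayCollection-class]
#' @param path output file
#' @param description description field written for every pathway
#' @return \code{path}, invisibly
#' @export
writeGMT <- function(collection, path, description = "na") {
    lines <- vapply(collection@pathways, function(p) {
        paste(c(p@name, description, p@genes), collapse = "\t")
    }, character(1))
    writeLines(unname(lines), path)
    invisible(path)
}

#' Read a normalized expression matrix with sample groups
#'
#' The matrix file is tab-delimited with probe/gene identifiers in the first
#' column and sample identifiers in the header. The groups file has two
#' tab-separated columns, sample identifier and group label
#' (\code{case}/\code{control}); every sample of the matrix must be labelled
#' and every labelled sample must be present. The optional probe map has two
#' columns, probe identifier and gene symbol. Values are taken as already
#' normalized; nothing is rescaled.
#'
#' @param matrixPath expression matrix TSV
#' @param groupsPath sample-to-group TSV
#' @param probeMapPath optional probe-to-gene TSV
#' @return an [ExpressionData-class]
#' @export
readExpression <- function(matrixPath, groupsPath, probeMapPath = NULL) {
    tab <- utils::read.delim(matrixPath, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    if (ncol(tab) < 2L) stop("expression matrix needs >= 1 sample column")
    probes <- tab[[1]]
    if (anyDuplicated(probes)) stop("duplicate row identifiers in matrix")
    vals <- as.matrix(tab[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
    if (anyNA(num)) {
        bad <- which(is.na(num), arr.ind = TRUE)[1, ]
        stop(sprintf("non-numeric expression value at row '%s', sample '%s'",
                     probes[bad[1]], colnames(vals)[bad[2]]))
    }
    dimnames(num) <- list(probes, colnames(vals))

    gr <- utils::read.delim(groupsPath, header = FALSE, sep = "\t",
                            col.names = c("sample", "group"),
                            colClasses = "character")
    gr$group <- tolower(trimws(gr$group))
    if (!all(gr$group %in% c("case", "control")))
        stop("group labels must be 'case' or 'control'")
    missingFromMatrix <- setdiff(gr$sample, colnames(num))
    if (length(missingFromMatrix))
        stop("samples in groups file absent from matrix: ",
             paste(missingFromMatrix, collapse = ", "))
    unlabelled <- setdiff(colnames(num), gr$sample)
    if (length(unlabelled))
        stop("samples without a group label: ",
             paste(unlabelled, collapse = ", "))
    groups <- gr$group[match(colnames(num), gr$sample)]

    probeToGene <- NULL
    if (!is.null(probeMapPath)) {
        pm <- utils::read.delim(probeMapPath, header = FALSE, sep = "\t",
                                col.names = c("probe", "gene"),
                                colClasses = "character")
        probeToGene <- stats::setNames(pm$gene, pm$probe)
    }
    ExpressionData(num, groups, probeToGene)
}

#' Export a subnetwork for downstream viewers
#'
#' \describe{
#'   \item{sif}{Cytoscape simple interaction format; interaction type
#'     \code{pp}, isolated nodes as bare names.}
#'   \item{graphml}{GraphML with a \code{role} node attribute
#'     (\code{terminal}/\code{linker}).}
#'   \item{tsv}{edge list written to \code{path} plus a node-annotation
#'     table (\code{gene}, \code{role}) at \code{path} with a
#'     \code{.nodes.tsv} suffix.}
#' }
#'
#' @param subnet a [Subnetwork-class]
#' @param path output file
#' @param format \code{"sif"}, \code{"graphml"} or \code{"tsv"}
#' @return \code{path}, invisibly
#' @export
writeSubnetwork <- function(subnet, path, format = c("sif", "graphml", "tsv")) {
    format <- match.arg(format)
    g <- subnet@graph
    nodes <- geneSymbols(subnet)
    roles <- ifelse(nodes %in% subnet@terminals, "terminal", "linker")
    if (format == "sif") {
        el <- igraph::as_edgelist(g)
        lines <- if (nrow(el)) paste(el[, 1], "pp", el[, 2], sep = "\t")
                 else character()
        isolated <- nodes[igraph::degree(g) == 0L]
        writeLines(c(lines, isolated), path)
    } else if (format == "graphml") {
        gg <- g
        if (gorder(gg)) V(gg)$role <- roles
        igraph::write_graph(gg, path, format = "graphml")
    } else {
        el <- igraph::as_edgelist(g)
        writeLines(c("from\tto",
                     if (nrow(el)) paste(el[, 1], el[, 2], sep = "\t")),
                   path)
        nodePath <- paste0(sub("\\.tsv$", "", path), ".nodes.tsv")
        writeLines(c("gene\trole",
                     if (length(nodes)) paste(nodes, roles, sep = "\t")),
                   nodePath)
    }
    invisible(path)
}

#' Re-import a subnetwork written as GraphML
#'
#' Restores node roles from the \code{role} attribute. Dropped-seed
#' information is not serialized and comes back empty.
#'
#' @param path GraphML file produced by [writeSubnetwork()]
#' @param seedName label for the seed set
#' @return a [Subnetwork-class]
#' @export
readSubnetworkGraphML <- function(path, seedName = basename(path)) {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- if (gorder(g)) V(g)$name else character()
    roles <- if (gorder(g)) V(g)$role else character()
    new("Subnetwork", graph = g,
        terminals = nodes[roles == "terminal"],
        linkers = nodes[roles == "linker"],
        dropped = data.frame(gene = character(), reason = character(),
                             stringsAsFactors = FALSE),
        seedName = seedName)
}
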