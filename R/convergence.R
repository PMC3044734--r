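#' Genes shared by two subnetworks
#'
#' The convergent (high-priority) candidates are the genes present in both
#' subnetworks, counting terminals and recruited linkers alike: a gene can
#' earn convergent status purely by being structurally required by both
#' networks. Symmetric in its arguments.
#'
#' @param subnetA,subnetB [Subnetwork-class] objects (may be empty)
#' @return sorted character vector of shared gene symbols
#' @export
convergeSubnetworks <- function(subnetA, subnetB) {
    stopifnot(is(subnetA, "Subnetwork"), is(subnetB, "Subnetwork"))
    sort(intersect(geneSymbols(subnetA), geneSymbols(subnetB)),
         method = "radix")
}

#' Annotate convergent genes with their evidence of origin
#'
#' For each convergent gene, records whether it belongs to either original
#' seed list and derives an origin class: \code{both-seeds} (in both lists),
#' \code{cnv-only-seed}, \code{huge-only-seed}, or \code{linker-only}
#' (recruited by both constructions without being a seed anywhere). The four
#' classes partition the table. When a differential expression result is
#' supplied, each gene's p-value is attached where available.
#'
#' @param genes character vector from [convergeSubnetworks()]
#' @param cnvSeeds,hugeSeeds the two original seed [GeneSet-class]s
#' @param de optional [DEResult-class]
#' @return a \code{DataFrame} with columns \code{gene}, \code{inCnvSubnet},
#'   \code{inHugeSubnet}, \code{cnvSeed}, \code{hugeSeed}, \code{originClass}
#'   and, if \code{de} is given, \code{deP}
#' @export
annotateOrigin <- function(genes, cnvSeeds, hugeSeeds, de = NULL) {
    stopifnot(is(cnvSeeds, "GeneSet"), is(hugeSeeds, "GeneSet"))
    genes <- sort(normalizeSymbols(genes), method = "radix")
    isCnv <- genes %in% cnvSeeds@genes
    isHuge <- genes %in% hugeSeeds@genes
    cls <- ifelse(isCnv & isHuge, "both-seeds",
           ifelse(isCnv, "cnv-only-seed",
           ifelse(isHuge, "huge-only-seed", "linker-only")))
    tab <- S4Vectors::DataFrame(
        gene = genes,
        inCnvSubnet = rep(TRUE, length(genes)),
        inHugeSubnet = rep(TRUE, length(genes)),
        cnvSeed = isCnv,
        hugeSeed = isHuge,
        originClass = cls)
    if (!is.null(de)) {
        stopifnot(is(de, "DEResult"))
        tab$deP <- de@table$p[match(genes, de@table$gene)]
    }
    tab
}

#' Write a convergent-gene table as TSV
#'
#' Boolean seed flags are written as \code{Y}/\code{N}; a missing p-value as
#' \code{NA}.
#'
#' @param table output of [annotateOrigin()]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeConvergentTable <- function(table, path) {
    df <- as.data.frame(table)
    for (col in c("inCnvSubnet", "inHugeSubnet", "cnvSeed", "hugeSeed"))
        df[[col]] <- ifelse(df[[col]], "Y", "N")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
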