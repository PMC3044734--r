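#' Collapse probes to genes by maximum mean intensity
#'
#' Microarray platforms interrogate many genes with several probes. For each
#' gene, the single probe with the largest mean intensity across all samples
#' is kept to represent it (ties: lexicographically smaller probe
#' identifier). Probes with no gene mapping are dropped with a logged count.
#'
#' @param expr an [ExpressionData-class] whose \code{rowData} has a
#'   \code{gene} column
#' @return a gene-level [ExpressionData-class] (rows keyed by gene symbol,
#'   with the chosen probe recorded in \code{rowData$probe})
#' @export
collapseProbes <- function(expr) {
    stopifnot(is(expr, "ExpressionData"))
    rd <- SummarizedExperiment::rowData(expr)
    if (!"gene" %in% colnames(rd) || all(is.na(rd$gene)))
        stop("probe-to-gene mapping required (rowData 'gene' column)")
    gene <- as.character(rd$gene)
    mapped <- !is.na(gene) & nzchar(gene)
    if (any(!mapped))
        cnMessage("dropped %d probes without a gene mapping", sum(!mapped))
    mat <- SummarizedExperiment::assay(expr, "intensity")[mapped, , drop = FALSE]
    gene <- gene[mapped]
    probe <- rownames(mat)
    means <- rowMeans(mat)
    ord <- order(gene, -means, probe, method = "radix")
    keep <- ord[!duplicated(gene[ord])]
    out <- mat[keep, , drop = FALSE]
    rownames(out) <- gene[keep]
    res <- ExpressionData(out,
                          SummarizedExperiment::colData(expr)$group)
    SummarizedExperiment::rowData(res)$probe <- probe[keep]
    res
}

#' Two-sided two-sample t-test per gene
#'
#' Tests every row for a mean difference between case and control samples.
#' The default is the Welch (unequal variance) statistic; \code{"pooled"}
#' gives the classical equal-variance Student variant. P-values are raw
#' (unadjusted); use [deGenes()] with \code{adjust = "BH"} if a corrected
#' list is wanted. Rows where both groups have zero variance are flagged
#' degenerate: t is 0 and p is 1 when the means agree, otherwise the
#' difference is infinitely well supported and p is 0.
#'
#' @param expr a gene-level [ExpressionData-class] (at least two samples per
#'   group)
#' @param variant \code{"welch"} (default) or \code{"pooled"}
#' @return a [DEResult-class], rows ordered by p-value
#' @export
tTestDE <- function(expr, variant = c("welch", "pooled")) {
    stopifnot(is(expr, "ExpressionData"))
    variant <- match.arg(variant)
    grp <- as.character(SummarizedExperiment::colData(expr)$group)
    mat <- SummarizedExperiment::assay(expr, "intensity")
    caseIdx <- grp == "case"
    n1 <- sum(caseIdx); n2 <- sum(!caseIdx)
    if (n1 < 2L || n2 < 2L)
        stop("at least 2 samples per group are required")
    x <- mat[, caseIdx, drop = FALSE]
    y <- mat[, !caseIdx, drop = FALSE]
    m1 <- rowMeans(x); m2 <- rowMeans(y)
    v1 <- rowSums((x - m1)^2) / (n1 - 1)
    v2 <- rowSums((y - m2)^2) / (n2 - 1)
    if (variant == "welch") {
        se2 <- v1 / n1 + v2 / n2
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se2 <- sp2 * (1 / n1 + 1 / n2)
        df <- rep(n1 + n2 - 2, length(se2))
    }
    tstat <- (m1 - m2) / sqrt(se2)
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    degenerate <- se2 == 0
    tstat[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 0, Inf *
                                sign(m1[degenerate] - m2[degenerate]))
    p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
    tab <- S4Vectors::DataFrame(
        gene = rownames(mat), meanCase = unname(m1),
        meanControl = unname(m2), t = unname(tstat), p = unname(p),
        degenerate = unname(degenerate))
    tab <- tab[order(tab$p, tab$gene, method = "radix"), ]
    rownames(tab) <- NULL
    new("DEResult", table = tab, nCase = as.integer(n1),
        nControl = as.integer(n2), testVariant = variant)
}

#' Significant differentially expressed genes
#'
#' Genes with p strictly below \code{alpha}. Optionally applies a
#' Benjamini-Hochberg correction first.
#'
#' @param result a [DEResult-class]
#' @param alpha significance level in (0, 1)
#' @param adjust \code{"none"} (raw p-values, the default) or \code{"BH"}
#' @return a [GeneSet-class] of significant genes
#' @export
deGenes <- function(result, alpha = 0.05, adjust = c("none", "BH")) {
    stopifnot(is(result, "DEResult"))
    adjust <- match.arg(adjust)
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
        stop("alpha must lie strictly between 0 and 1")
    p <- result@table$p
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    GeneSet(paste0("DE<", alpha, if (adjust == "BH") " (BH)" else ""),
            result@table$gene[p < alpha])
}

#' Write a DE result as TSV
#'
#' @param result a [DEResult-class]
#' @param path output file
#' @param alpha level used for the significant(Y/N) column
#' @return \code{path}, invisibly
#' @export
writeDEResult <- function(result, path, alpha = 0.05) {
    df <- as.data.frame(result@table)
    df$significant <- ifelse(df$p < alpha, "Y", "N")
    df$degenerate <- NULL
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
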