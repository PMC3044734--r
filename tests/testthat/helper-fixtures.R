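options(ConvergeNet.quiet = TRUE)

# interactome from an "A-B" edge string, e.g. "A-B B-C"
edgeNet <- function(spec, name = "test") {
    pairs <- strsplit(strsplit(spec, " ", fixed = TRUE)[[1]], "-", fixed = TRUE)
    Interactome(vapply(pairs, `[`, "", 1L), vapply(pairs, `[`, "", 2L),
                name = name)
}

# random connected graph as an Interactome with shuffled symbol labels
randomConnectedNet <- function(n, p = 0.35) {
    repeat {
        g <- igraph::sample_gnp(n, p = p)
        if (igraph::is_connected(g)) break
    }
    igraph::V(g)$name <- sprintf("N%02d", sample(n))
    new("Interactome", graph = g, name = "random")
}

randomTreeNet <- function(n) {
    g <- igraph::sample_tree(n)
    igraph::V(g)$name <- sprintf("N%02d", sample(n))
    new("Interactome", graph = g, name = "tree")
}

# upper-tail hypergeometric probability by direct summation (independent of
# phyper): P(X >= k) with K special among N, n drawn
hyperTailOracle <- function(k, K, N, n) {
    i <- seq(from = k, to = min(K, n))
    if (!length(i) || k <= 0) return(1)
    sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# tiny expression fixture: matrix of given dims with named groups
exprFixture <- function(values, nCase, nControl, genes = NULL) {
    m <- matrix(values, ncol = nCase + nControl)
    rownames(m) <- if (is.null(genes)) paste0("G", seq_len(nrow(m))) else genes
    colnames(m) <- paste0("S", seq_len(ncol(m)))
    ExpressionData(m, rep(c("case", "control"), c(nCase, nControl)))
}

# adjusted Rand index between two labelings (comparison utility)
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    expected <- si * sj / choose(sum(tab), 2)
    maxidx <- (si + sj) / 2
    if (maxidx == expected) return(1)
    (sij - expected) / (maxidx - expected)
}

table2Path <- function() {
    system.file("extdata", "high_priority_genes.tsv",
                package = "ConvergeNet", mustWork = TRUE)
}
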