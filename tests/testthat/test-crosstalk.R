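test_that("over-representation p-values and significance flags are correct", {
    bg <- GeneSet("bg", paste0("g", 1:20))
    col <- PathwayCollection(list(GeneSet("P1", paste0("g", 1:10))))
    # query = one half, pathway = same half: p = 1/choose(20,10)
    q <- GeneSet("q", paste0("g", 1:10))
    r <- fisherEnrich(q, col, bg, minHits = 5, pCutoff = 0.01)
    expect_equal(resultTable(r)$p, 1 / choose(20, 10), tolerance = 1e-12)
    expect_true(resultTable(r)$significant)

    # no hits: upper tail P(X >= 0) = 1
    q0 <- GeneSet("q0", paste0("g", 11:15))
    col0 <- PathwayCollection(list(GeneSet("P1", paste0("g", 1:5))))
    r0 <- fisherEnrich(q0, col0, bg)
    expect_equal(resultTable(r0)$p, 1)
    expect_false(resultTable(r0)$significant)

    # significance needs BOTH p < cutoff and hits >= minHits
    q3 <- GeneSet("q3", paste0("g", 1:3))
    r3 <- fisherEnrich(q3, PathwayCollection(list(GeneSet("P1", paste0("g", 1:3)))),
                       bg, minHits = 5, pCutoff = 0.01)
    expect_lt(resultTable(r3)$p, 0.01)
    expect_false(resultTable(r3)$significant)

    expect_error(fisherEnrich(q, PathwayCollection(list()), bg), "empty")
    out <- GeneSet("out", c("zz1", "zz2"))
    expect_error(fisherEnrich(out, col, bg), "background")
})

test_that("enrichment matches the direct-summation oracle on random configs", {
    set.seed(77)
    for (i in 1:60) {
        N <- sample(20:200, 1)
        K <- sample(2:(N - 1), 1)
        n <- sample(2:(N - 1), 1)
        bg <- GeneSet("bg", sprintf("g%03d", 1:N))
        col <- PathwayCollection(list(GeneSet("P", sprintf("g%03d", 1:K))))
        q <- GeneSet("q", sample(bg@genes, n))
        r <- fisherEnrich(q, col, bg)
        k <- resultTable(r)$nHits
        expect_equal(resultTable(r)$p, hyperTailOracle(k, K, N, n),
                     tolerance = 1e-12)
    }
})

test_that("crosstalk scores reproduce hand-computed coefficients", {
    expect_equal(unname(crosstalkScore(c("a", "b"), c("a", "b"))),
                 c(1, 1, 1))
    expect_equal(unname(crosstalkScore(c("a", "b"), c("c", "d"))),
                 c(0, 0, 0))
    sc <- crosstalkScore(c("a", "b", "c"), c("b", "c", "d"))
    expect_equal(unname(sc), c(0.5, 2 / 3, 7 / 12))
    expect_error(crosstalkScore(character(), "a"), "empty")

    set.seed(4)
    for (i in 1:50) {
        a <- sample(letters, sample(1:10, 1))
        b <- sample(letters, sample(1:10, 1))
        s1 <- crosstalkScore(a, b); s2 <- crosstalkScore(b, a)
        expect_equal(s1, s2)
        expect_lte(s1[["jc"]], s1[["oc"]] + 1e-12)
        expect_equal(s1[["score"]], (s1[["jc"]] + s1[["oc"]]) / 2)
    }
})

# enrichment result in which exactly the given pathways are significant,
# with their full gene sets as hits
mockEnrich <- function(collection, sig, query = "q") {
    bg <- GeneSet("bg", c(unique(unlist(lapply(collection@pathways,
                                               slot, "genes"))),
                          sprintf("pad%04d", 1:2000)))
    q <- GeneSet(query, unique(unlist(lapply(sig, function(p)
        collection[[p]]@genes))))
    fisherEnrich(q, collection, bg, minHits = 4, pCutoff = 0.01)
}

test_that("crosstalk graph respects thresholds and retains ties", {
    col <- PathwayCollection(list(
        GeneSet("P1", c("a", "b", "c", "d", "e")),
        GeneSet("P2", c("a", "b", "c", "x", "y")),
        GeneSet("P3", c("a", "b", "z", "w", "v"))))
    e <- mockEnrich(col, c("P1", "P2", "P3"))
    g <- buildCrosstalkGraph(e, e, minShared = 3, topFractionA = 1,
                             topFractionB = 1)
    # only P1-P2 share >= 3 genes
    expect_equal(igraph::gsize(g@graph), 1L)
    expect_setequal(functionalGroups(g)[[1]], c("P1", "P2"))
    expect_identical(g@isolated, "P3")
    expect_true(all(igraph::V(g@graph)$membership == "both"))

    # single significant pathway: one node, no edges, no groups
    e1 <- mockEnrich(PathwayCollection(list(GeneSet("P1", letters[1:5]))), "P1")
    g1 <- buildCrosstalkGraph(e1, e1, topFractionA = 1, topFractionB = 1)
    expect_equal(igraph::gorder(g1@graph), 1L)
    expect_equal(igraph::gsize(g1@graph), 0L)
    expect_length(functionalGroups(g1), 0L)

    expect_error(buildCrosstalkGraph(e, e, topFractionA = 0,
                                     topFractionB = 1), "top fractions")
    expect_error(buildCrosstalkGraph(e, e, topFractionA = 1,
                                     topFractionB = 1.5), "top fractions")
})

test_that("topFraction=1 keeps every qualifying pair (all-pairs oracle)", {
    set.seed(12)
    pws <- lapply(1:8, function(i)
        GeneSet(sprintf("PW%d", i), sample(letters, 8)))
    col <- PathwayCollection(pws)
    e <- mockEnrich(col, names(col))
    g <- buildCrosstalkGraph(e, e, minShared = 3, topFractionA = 1,
                             topFractionB = 1)
    brute <- sum(utils::combn(names(col), 2, function(pr)
        length(intersect(col[[pr[1]]]@genes, col[[pr[2]]]@genes)) >= 3))
    expect_equal(igraph::gsize(g@graph), brute)
})

test_that("filtering is anti-monotone in minShared and topFraction", {
    set.seed(13)
    pws <- lapply(1:10, function(i)
        GeneSet(sprintf("PW%02d", i), sample(letters[1:15], 8)))
    col <- PathwayCollection(pws)
    e <- mockEnrich(col, names(col))
    edges <- function(ms, tf)
        igraph::gsize(buildCrosstalkGraph(e, e, minShared = ms,
                                          topFractionA = tf,
                                          topFractionB = tf)@graph)
    expect_true(edges(4, 1) <= edges(3, 1))
    expect_true(edges(5, 1) <= edges(4, 1))
    expect_true(edges(3, 0.25) <= edges(3, 0.5))
    expect_true(edges(3, 0.5) <= edges(3, 1))
})

test_that("membership is 'both' exactly for pathways significant in both results", {
    col <- PathwayCollection(list(
        GeneSet("P1", c("a", "b", "c", "d")),
        GeneSet("P2", c("a", "b", "c", "e")),
        GeneSet("P3", c("f", "g", "h", "i"))))
    eA <- mockEnrich(col, c("P1", "P2"))
    eB <- mockEnrich(col, c("P2", "P3"))
    g <- buildCrosstalkGraph(eA, eB, minShared = 3, topFractionA = 1,
                             topFractionB = 1)
    memb <- stats::setNames(igraph::V(g@graph)$membership,
                            igraph::V(g@graph)$name)
    expect_identical(unname(memb[c("P1", "P2", "P3")]),
                     c("setA", "both", "setB"))
})

test_that("planted pathway clusters are recovered as functional groups", {
    genes <- sprintf("g%04d", 1:600)
    pw <- genPathways(genes, nPathways = 6,
                      clusterSpec = list(c(3, 4), c(3, 4)),
                      pathwaySize = 20, seed = 5)
    e <- mockEnrich(pw$collection, names(pw$collection))
    g <- buildCrosstalkGraph(e, e, minShared = 3, topFractionA = 1,
                             topFractionB = 1)
    expect_length(functionalGroups(g), 2L)
    found <- rep(NA_integer_, 6)
    names(found) <- names(pw$collection)
    for (i in seq_along(functionalGroups(g)))
        found[functionalGroups(g)[[i]]] <- i
    truth <- pw$truth@plantedPathwayClusters[names(found)]
    expect_equal(adjustedRand(found, truth), 1)

    # shared cores below the edge threshold produce no edges
    pw2 <- genPathways(genes, nPathways = 6,
                       clusterSpec = list(c(3, 2), c(3, 2)),
                       pathwaySize = 20, seed = 5)
    e2 <- mockEnrich(pw2$collection, names(pw2$collection))
    g2 <- buildCrosstalkGraph(e2, e2, minShared = 3, topFractionA = 1,
                              topFractionB = 1)
    expect_equal(igraph::gsize(g2@graph), 0L)
})
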