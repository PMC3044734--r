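test_that("edge-list reader deduplicates, drops self-loops, errors usefully", {
    f <- withr::local_tempfile(lines = c("A\tB", "B\tA", "A\tA"))
    net <- readInteractome(f)
    expect_setequal(geneSymbols(net), c("A", "B"))
    expect_equal(numEdges(net), 1L)

    f2 <- withr::local_tempfile(lines = c("# comment", "A\tB", "B\tC", "C\tD"))
    net2 <- readInteractome(f2)
    expect_equal(numNodes(net2), 4L)
    expect_equal(numEdges(net2), 3L)

    bad <- withr::local_tempfile(lines = c("A\tB", "LONERECORD"))
    expect_error(readInteractome(bad), "line 2")
    empty <- withr::local_tempfile(lines = "# only a comment")
    expect_error(readInteractome(empty), "empty")
})

test_that("mitab-lite reader strips prefixes and applies the symbol map", {
    f <- system.file("extdata", "ppi_mitab_lite.txt",
                     package = "ConvergeNet", mustWork = TRUE)
    map <- c(P14867 = "GABRA1", P27824 = "CANX", P28482 = "MAPK1")
    net <- readInteractome(f, dialect = "mitab-lite", symbolMap = map)
    # hand-parsed: 5 records = 1 self-loop + 1 duplicate + 3 distinct edges
    expect_setequal(geneSymbols(net), c("GABRA1", "CANX", "MAPK1"))
    expect_equal(numEdges(net), 3L)
    el <- igraph::as_edgelist(net@graph)
    expect_true(all(apply(el, 1, function(e)
        paste(sort(e), collapse = "-")) %in%
        c("CANX-GABRA1", "GABRA1-MAPK1", "CANX-MAPK1")))
})

test_that("interactome parsing is idempotent under line reordering and round-trips", {
    lines <- c("A\tB", "B\tC", "C\tD", "D\tA", "B\tD")
    f1 <- withr::local_tempfile(lines = lines)
    f2 <- withr::local_tempfile(lines = rev(lines))
    n1 <- readInteractome(f1); n2 <- readInteractome(f2)
    expect_setequal(geneSymbols(n1), geneSymbols(n2))
    expect_equal(numEdges(n1), numEdges(n2))

    set.seed(5)
    for (dialect in c("edge-list", "mitab-lite")) {
        for (i in 1:5) {
            net <- randomConnectedNet(sample(5:50, 1), p = 0.2)
            f <- withr::local_tempfile()
            writeInteractome(net, f, dialect = dialect)
            back <- readInteractome(f, dialect = dialect)
            expect_setequal(geneSymbols(back), geneSymbols(net))
            expect_equal(numEdges(back), numEdges(net))
        }
    }
})

test_that("gene set reader normalizes case, ignores blanks, rejects empties", {
    f <- withr::local_tempfile(lines = c("gabra1", "GABRA1", ""))
    gs <- readGeneSet(f, "x")
    expect_equal(geneSymbols(gs), "GABRA1")

    f5 <- withr::local_tempfile(lines = c("a", "b", "c", "d", "e"))
    expect_length(geneSymbols(readGeneSet(f5, "five")), 5L)

    empty <- withr::local_tempfile(lines = c("", "# nothing"))
    expect_error(readGeneSet(empty, "none"), "empty gene set")

    tab2 <- utils::read.delim(table2Path())
    f20 <- withr::local_tempfile(lines = tab2$gene)
    expect_length(geneSymbols(readGeneSet(f20, "hp")), 20L)
})

test_that("GMT reader/writer round-trip and input validation", {
    f <- withr::local_tempfile(lines = c("P1\tdesc\tA\tB\tC"))
    col <- readGMT(f)
    expect_length(col, 1L)
    expect_setequal(geneSymbols(col[["P1"]]), c("A", "B", "C"))

    f2 <- withr::local_tempfile(lines = c("P1\td\tA\tB\tC", "P2\td\tB\tC\tD"))
    col2 <- readGMT(f2)
    expect_length(intersect(geneSymbols(col2[["P1"]]),
                            geneSymbols(col2[["P2"]])), 2L)

    dupf <- withr::local_tempfile(lines = c("P1\td\tA", "P1\td\tB"))
    expect_error(readGMT(dupf), "duplicate pathway")
    shortf <- withr::local_tempfile(lines = c("P1\tdesc", "P2\td\tA"))
    expect_warning(col3 <- readGMT(shortf), "skipped")
    expect_length(col3, 1L)

    # 10-pathway round trip
    set.seed(1)
    pws <- lapply(1:10, function(i)
        GeneSet(sprintf("PW%02d", i), sample(LETTERS, sample(3:10, 1))))
    orig <- PathwayCollection(pws, source = "fixture")
    rt <- withr::local_tempfile()
    writeGMT(orig, rt)
    back <- readGMT(rt)
    expect_identical(names(back), names(orig))
    for (nm in names(orig))
        expect_identical(geneSymbols(back[[nm]]), geneSymbols(orig[[nm]]))
})

test_that("expression reader enforces the sample/group contract", {
    mat <- withr::local_tempfile(lines = c(
        "probe\tS1\tS2\tS3\tS4",
        "p1\t1.5\t2.5\t3.5\t4.5",
        "p2\t1\t2\t3\t4",
        "p3\t0\t0\t1\t1"))
    grp <- withr::local_tempfile(lines = c("S1\tcase", "S2\tcase",
                                           "S3\tcontrol", "S4\tcontrol"))
    ed <- readExpression(mat, grp)
    expect_s4_class(ed, "ExpressionData")
    expect_equal(dim(ed), c(3L, 4L))
    expect_equal(as.vector(table(SummarizedExperiment::colData(ed)$group)),
                 c(2L, 2L))

    badgrp <- withr::local_tempfile(lines = c("S1\tcase", "S2\tcase",
                                              "S3\tcontrol", "S9\tcontrol"))
    expect_error(readExpression(mat, badgrp), "absent from matrix")
    partial <- withr::local_tempfile(lines = c("S1\tcase", "S2\tcase",
                                               "S3\tcontrol"))
    expect_error(readExpression(mat, partial), "without a group label")

    nonnum <- withr::local_tempfile(lines = c("probe\tS1\tS2\tS3\tS4",
                                              "p1\t1\tx\t3\t4"))
    expect_error(readExpression(nonnum, grp), "non-numeric")

    # 7 cases vs 8 controls accepted
    n <- 15
    mat15 <- withr::local_tempfile(lines = c(
        paste(c("probe", paste0("S", 1:n)), collapse = "\t"),
        paste(c("p1", round(rnorm(n, 8), 3)), collapse = "\t")))
    grp15 <- withr::local_tempfile(lines = paste0(
        "S", 1:n, "\t", rep(c("case", "control"), c(7, 8))))
    ed15 <- readExpression(mat15, grp15)
    expect_equal(sum(SummarizedExperiment::colData(ed15)$group == "case"), 7L)
    expect_equal(sum(SummarizedExperiment::colData(ed15)$group == "control"), 8L)
})

test_that("subnetwork exports: SIF lines, empty files, GraphML role round-trip", {
    net <- edgeNet("A-B")
    sn <- steinerSubnetwork(net, GeneSet("s", c("A", "B")))
    sif <- withr::local_tempfile()
    writeSubnetwork(sn, sif, "sif")
    expect_identical(readLines(sif), "A\tpp\tB")

    emptySn <- steinerSubnetwork(net, GeneSet("s", "ZZZ"))
    for (fmt in c("sif", "graphml", "tsv")) {
        out <- withr::local_tempfile(fileext = ".tsv")
        expect_no_error(writeSubnetwork(emptySn, out, fmt))
        expect_true(file.exists(out))
    }

    big <- edgeNet("A-B B-C C-D B-E")
    sn2 <- steinerSubnetwork(big, GeneSet("s", c("A", "C", "E")))
    gml <- withr::local_tempfile(fileext = ".graphml")
    writeSubnetwork(sn2, gml, "graphml")
    back <- readSubnetworkGraphML(gml)
    expect_setequal(terminals(back), terminals(sn2))
    expect_setequal(linkers(back), linkers(sn2))
    expect_equal(numEdges(back), numEdges(sn2))

    expect_error(writeSubnetwork(sn2, gml, "dot"), "arg")
})
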