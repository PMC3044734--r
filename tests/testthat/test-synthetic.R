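test_that("interactome generator hits the requested size and density", {
    net <- genInteractome(1000, "scale-free", meanDegree = 10, seed = 3)
    expect_gte(numNodes(net), 900)
    expect_lt(abs(numEdges(net) - numNodes(net) * 5) / (numNodes(net) * 5),
              0.1)
    expect_equal(igraph::count_components(net@graph), 1L)

    # determinism
    net2 <- genInteractome(1000, "scale-free", meanDegree = 10, seed = 3)
    expect_identical(igraph::as_edgelist(net@graph),
                     igraph::as_edgelist(net2@graph))

    # heavy tail under preferential attachment vs homogeneous ER
    er <- genInteractome(1000, "erdos-renyi", meanDegree = 10, seed = 3)
    expect_gt(max(igraph::degree(net@graph)), max(igraph::degree(er@graph)))

    expect_error(genInteractome(5), "at least 10")
    expect_error(genInteractome(100, meanDegree = 200), "infeasible")
})

test_that("seed planting produces the requested overlap and bridge structure", {
    net <- genInteractome(800, seed = 21)
    ss <- genSeedSets(net, nSeedsA = 40, nSeedsB = 20, nBridges = 4,
                      nOverlap = 5, seed = 8)
    expect_length(geneSymbols(ss$seedsA), 40L)
    expect_length(geneSymbols(ss$seedsB), 20L)
    expect_setequal(intersect(geneSymbols(ss$seedsA), geneSymbols(ss$seedsB)),
                    ss$truth@plantedOverlap)
    expect_length(ss$truth@plantedOverlap, 5L)
    expect_length(ss$truth@plantedBridges, 4L)
    # bridges are non-seeds present in the network
    expect_length(intersect(ss$truth@plantedBridges,
                            c(geneSymbols(ss$seedsA),
                              geneSymbols(ss$seedsB))), 0L)
    expect_true(all(ss$truth@plantedBridges %in% geneSymbols(net)))

    ss0 <- genSeedSets(net, nSeedsA = 20, nSeedsB = 15, nBridges = 0,
                       nOverlap = 3, seed = 8)
    expect_length(ss0$truth@plantedBridges, 0L)
    expect_length(intersect(geneSymbols(ss0$seedsA),
                            geneSymbols(ss0$seedsB)), 3L)

    expect_error(genSeedSets(net, nSeedsA = 10, nSeedsB = 10, nBridges = 4,
                             nOverlap = 5, seed = 1), "too small")
})

test_that("expression generator plants effects and duplicate probes deterministically", {
    genes <- sprintf("G%03d", 1:200)
    ex <- genExpression(genes, nCase = 7, nControl = 8, deFraction = 0.1,
                        effectSd = 2, seed = 14)
    expect_equal(ncol(ex$expr), 15L)
    expect_equal(sum(SummarizedExperiment::colData(ex$expr)$group == "case"),
                 7L)
    expect_length(ex$truth@plantedDE, 20L)
    # 10% duplicate probes at lower mean
    expect_equal(nrow(ex$expr), 220L)
    rd <- SummarizedExperiment::rowData(ex$expr)
    dupGenes <- names(which(table(rd$gene) == 2))
    expect_length(dupGenes, 20L)
    m <- SummarizedExperiment::assay(ex$expr)
    for (g in dupGenes[1:5]) {
        pr <- rownames(ex$expr)[rd$gene == g]
        expect_gt(mean(m[pr[grepl("_p1$", pr)], ]),
                  mean(m[pr[grepl("_p2$", pr)], ]))
    }
    ex2 <- genExpression(genes, nCase = 7, nControl = 8, deFraction = 0.1,
                         effectSd = 2, seed = 14)
    expect_identical(SummarizedExperiment::assay(ex$expr),
                     SummarizedExperiment::assay(ex2$expr))
    expect_error(genExpression(genes, deFraction = 1.5), "deFraction")
})

test_that("pathway generator controls sizes and cross-cluster sharing", {
    genes <- sprintf("g%04d", 1:900)
    pw <- genPathways(genes, nPathways = 12,
                      clusterSpec = list(c(3, 4), c(3, 4)),
                      pathwaySize = 20, seed = 6)
    col <- pw$collection
    expect_length(col, 12L)
    expect_true(all(vapply(seq_len(12), function(i)
        length(geneSymbols(col[[i]])), integer(1)) == 20L))
    lab <- pw$truth@plantedPathwayClusters
    for (p1 in names(col)) for (p2 in names(col)) {
        if (p1 >= p2) next
        shared <- length(intersect(geneSymbols(col[[p1]]),
                                   geneSymbols(col[[p2]])))
        if (lab[p1] == lab[p2] && lab[p1] != "noise") {
            expect_equal(shared, 4L)
        } else {
            expect_lt(shared, 3L)
        }
    }
    expect_error(genPathways(letters, nPathways = 12,
                             clusterSpec = list(c(3, 4)), pathwaySize = 20),
                 "infeasible")
})

test_that("the paperlike preset is consistent, complete and reproducible", {
    dir1 <- withr::local_tempdir()
    sim <- simulateStudy("paperlike", seed = 99, outDir = dir1)
    expect_true(validateTruth(sim$truth, sim$net, sim$seedsA, sim$seedsB,
                              sim$expr, sim$collection))
    files <- c("ppi.tsv", "seeds_a.txt", "seeds_b.txt", "expr.tsv",
               "groups.tsv", "probe_map.tsv", "pathways.gmt", "truth.json")
    expect_true(all(file.exists(file.path(dir1, files))))

    dir2 <- withr::local_tempdir()
    simulateStudy("paperlike", seed = 99, outDir = dir2)
    for (f in files)
        expect_identical(readLines(file.path(dir1, f)),
                         readLines(file.path(dir2, f)),
                         label = paste("file", f))

    # written artifacts parse back into equivalent objects
    net <- readInteractome(file.path(dir1, "ppi.tsv"))
    expect_equal(numNodes(net), numNodes(sim$net))
    expect_equal(numEdges(net), numEdges(sim$net))
    sa <- readGeneSet(file.path(dir1, "seeds_a.txt"), "seedsA")
    expect_setequal(geneSymbols(sa), geneSymbols(sim$seedsA))
})
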