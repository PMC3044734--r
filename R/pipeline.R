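#' Default pipeline parameters
#'
#' Thresholds follow the conventions of convergent network analyses:
#' Steiner cost cap 2 linkers per merged component, raw t-test alpha 0.05,
#' pathway significance P < 0.01 with at least 5 genes of interest, at
#' least 3 shared genes per crosstalk edge, and top 1% / top 5% retained
#' edges for the two enrichment results.
#'
#' @return named list of defaults
#' @export
pipelineDefaults <- function() {
    list(maxMergeCost = 2, alpha = 0.05, minHits = 5L, pCutoff = 0.01,
         minShared = 3L, topFractionA = 0.01, topFractionB = 0.05,
         testVariant = "welch", background = "interactome")
}

#' Read and validate a pipeline run configuration
#'
#' The YAML file names the inputs (\code{ppi}, \code{seeds_a},
#' \code{seeds_b}; optional \code{expr}, \code{groups}, \code{probe_map};
#' optional \code{gmt}), the output directory (\code{out_dir}) and any of
#' the parameters of [pipelineDefaults()] (snake_case keys). Relative paths
#' are resolved against the YAML file's directory. Referenced files must
#' exist.
#'
#' @param path YAML configuration file
#' @return validated configuration list for [runPipeline()]
#' @export
readRunConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    resolve <- function(p) {
        if (is.null(p)) return(NULL)
        if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
        p
    }
    cfg <- pipelineDefaults()
    keyMap <- c(max_merge_cost = "maxMergeCost", alpha = "alpha",
                min_hits = "minHits", p_cutoff = "pCutoff",
                min_shared = "minShared", top_fraction_a = "topFractionA",
                top_fraction_b = "topFractionB", test_variant = "testVariant",
                background = "background")
    for (k in names(keyMap))
        if (!is.null(raw[[k]])) cfg[[keyMap[[k]]]] <- raw[[k]]
    for (k in c("ppi", "seeds_a", "seeds_b", "expr", "groups", "probe_map",
                "gmt"))
        cfg[[k]] <- resolve(raw[[k]])
    cfg$out_dir <- resolve(raw[[("out_dir")]])
    for (k in c("ppi", "seeds_a", "seeds_b"))
        if (is.null(cfg[[k]]))
            stop("config must name the '", k, "' input")
    for (k in c("ppi", "seeds_a", "seeds_b", "expr", "groups", "probe_map",
                "gmt"))
        if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
            stop("configured file does not exist: ", cfg[[k]])
    if (!is.null(cfg$expr) && is.null(cfg$groups))
        stop("expression input requires a groups file")
    if (is.null(cfg$out_dir)) stop("config must name 'out_dir'")
    if (cfg$maxMergeCost < 0) stop("max_merge_cost must be non-negative")
    if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0,1)")
    cfg
}

#' Run the full convergent analysis
#'
#' Executes, in order: Steiner subnetwork construction for both seed sets,
#' convergence and origin annotation, optional probe collapse + t-test
#' differential expression (attached to the convergent table), optional
#' pathway enrichment of both subnetworks, crosstalk graph and functional
#' groups. All artifacts are written to \code{config$out_dir}:
#' \code{subnet_a.graphml}, \code{subnet_b.graphml},
#' \code{convergent_table.tsv}, and when inputs allow \code{de.tsv},
#' \code{enrich_a.tsv}, \code{enrich_b.tsv}, \code{crosstalk.graphml},
#' \code{groups.tsv}, plus a machine-readable \code{manifest.json} with
#' input checksums, parameters and stage counts. A stage failure aborts
#' with the stage name and leaves a \code{FAILED} marker in the output
#' directory.
#'
#' @param config configuration list from [readRunConfig()], or a list with
#'   the same fields
#' @return (invisibly) list of the in-memory results: \code{subnetA},
#'   \code{subnetB}, \code{table}, and optionally \code{de},
#'   \code{enrichA}, \code{enrichB}, \code{crosstalk}
#' @export
runPipeline <- function(config) {
    cfg <- utils::modifyList(pipelineDefaults(), config)
    outDir <- cfg$out_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                       file.path(outDir, "FAILED"))
            stop("pipeline failed at stage '", name, "': ",
                 conditionMessage(e), call. = FALSE)
        })
    }
    counts <- list()

    net <- stage("read-interactome", readInteractome(cfg$ppi))
    seedsA <- stage("read-seeds-a", readGeneSet(cfg$seeds_a, "seedsA"))
    seedsB <- stage("read-seeds-b", readGeneSet(cfg$seeds_b, "seedsB"))
    params <- SteinerParams(cfg$maxMergeCost)

    subA <- stage("subnet-a", steinerSubnetwork(net, seedsA, params))
    subB <- stage("subnet-b", steinerSubnetwork(net, seedsB, params))
    writeSubnetwork(subA, file.path(outDir, "subnet_a.graphml"), "graphml")
    writeSubnetwork(subB, file.path(outDir, "subnet_b.graphml"), "graphml")
    counts$subnetA <- c(nTerminals = length(terminals(subA)),
                        nLinkers = length(linkers(subA)),
                        nDropped = nrow(droppedSeeds(subA)))
    counts$subnetB <- c(nTerminals = length(terminals(subB)),
                        nLinkers = length(linkers(subB)),
                        nDropped = nrow(droppedSeeds(subB)))

    de <- NULL
    if (!is.null(cfg$expr)) {
        expr <- stage("read-expression",
                      readExpression(cfg$expr, cfg$groups, cfg$probe_map))
        geneExpr <- stage("collapse-probes",
                          if (is.null(cfg$probe_map)) expr
                          else collapseProbes(expr))
        de <- stage("t-test", tTestDE(geneExpr, variant = cfg$testVariant))
        writeDEResult(de, file.path(outDir, "de.tsv"), alpha = cfg$alpha)
        counts$de <- c(nGenes = nrow(resultTable(de)),
                       nSignificant = length(
                           geneSymbols(deGenes(de, cfg$alpha))))
    }

    common <- stage("converge", convergeSubnetworks(subA, subB))
    tab <- stage("annotate", annotateOrigin(common, seedsA, seedsB, de))
    writeConvergentTable(tab, file.path(outDir, "convergent_table.tsv"))
    counts$convergence <- c(nOverlap = length(common),
                            nBothSeeds = sum(tab$originClass == "both-seeds"),
                            nLinkerOnly = sum(tab$originClass == "linker-only"))

    enrichA <- enrichB <- xt <- NULL
    if (!is.null(cfg$gmt)) {
        collection <- stage("read-gmt", readGMT(cfg$gmt))
        background <- if (identical(cfg$background, "interactome"))
            GeneSet("interactome", geneSymbols(net))
        else stage("read-background", readGeneSet(cfg$background, "background"))
        enrichA <- stage("enrich-a", fisherEnrich(
            GeneSet("subnetA", geneSymbols(subA)), collection, background,
            minHits = cfg$minHits, pCutoff = cfg$pCutoff))
        enrichB <- stage("enrich-b", fisherEnrich(
            GeneSet("subnetB", geneSymbols(subB)), collection, background,
            minHits = cfg$minHits, pCutoff = cfg$pCutoff))
        writeEnrichment(enrichA, file.path(outDir, "enrich_a.tsv"))
        writeEnrichment(enrichB, file.path(outDir, "enrich_b.tsv"))
        xt <- stage("crosstalk", buildCrosstalkGraph(
            enrichA, enrichB, minShared = cfg$minShared,
            topFractionA = cfg$topFractionA,
            topFractionB = cfg$topFractionB))
        writeCrosstalkGraph(xt, file.path(outDir, "crosstalk.graphml"),
                            file.path(outDir, "groups.tsv"))
        counts$enrichment <- c(
            nSignificantA = sum(resultTable(enrichA)$significant),
            nSignificantB = sum(resultTable(enrichB)$significant))
        counts$crosstalk <- c(nNodes = gorder(xt@graph),
                              nEdges = gsize(xt@graph),
                              nGroups = length(functionalGroups(xt)))
    }

    inputs <- Filter(Negate(is.null),
                     cfg[c("ppi", "seeds_a", "seeds_b", "expr", "groups",
                           "probe_map", "gmt")])
    manifest <- list(
        package = "ConvergeNet",
        version = as.character(utils::packageVersion("ConvergeNet")),
        parameters = cfg[c("maxMergeCost", "alpha", "minHits", "pCutoff",
                           "minShared", "topFractionA", "topFractionB",
                           "testVariant")],
        inputs = lapply(inputs, function(p)
            list(path = p, md5 = unname(tools::md5sum(p)))),
        counts = counts)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(subnetA = subA, subnetB = subB, table = tab, de = de,
                   enrichA = enrichA, enrichB = enrichB, crosstalk = xt,
                   manifest = manifest))
}
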