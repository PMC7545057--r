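#' Pipeline configuration
#'
#' Collects every stage-level option of the analysis together with either
#' file paths (`counts`, `samples`, `lengths`, `terms`) or a `simulation`
#' block ([simulationConfig()] arguments). Exactly one of the two input
#' modes must be present.
#'
#' @param counts,samples,lengths,terms input file paths (file mode).
#' @param simulation named list of [simulationConfig()] arguments
#'   (simulation mode).
#' @param seed integer seed; forwarded to the simulator.
#' @param tau presence threshold for [stagePresence()].
#' @param pseudocount for log transforms and fold changes.
#' @param pCut,fdrCut DEG thresholds.
#' @param diaFcCut,diaPCut DIA input filter thresholds.
#' @param strictDualTest require the chi-square test too for DEG calls.
#' @param maxProfiles,maxUnitChange model-profile settings (defaults 20, 2).
#' @param clusterCorrThreshold profile-grouping threshold (default 0.7).
#' @param corrThreshold,corrUseAbs,topK,blockSize co-expression settings.
#' @param diaCombination,diaLogBase,topN DIA settings.
#' @param verbose print stage progress.
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(counts = NULL, samples = NULL, lengths = NULL,
                           terms = NULL, simulation = NULL, seed = 1L,
                           tau = 0, pseudocount = 0.125,
                           pCut = 0.05, fdrCut = 0.05,
                           diaFcCut = 2, diaPCut = 0.001,
                           strictDualTest = FALSE,
                           maxProfiles = 20L, maxUnitChange = 2L,
                           clusterCorrThreshold = 0.7,
                           corrThreshold = 0.92, corrUseAbs = TRUE,
                           topK = 20L, blockSize = 512L,
                           diaCombination = "product", diaLogBase = 10,
                           topN = 10L, verbose = FALSE) {
    fileMode <- !is.null(counts)
    simMode <- !is.null(simulation) || !fileMode
    if (fileMode && !is.null(simulation))
        stop("provide either input files or a simulation block, not both")
    if (fileMode && (is.null(samples) || is.null(lengths)))
        stop("file mode needs counts, samples and lengths paths")
    stopifnot(tau >= 0, pseudocount >= 0, pCut > 0, pCut <= 1,
              fdrCut > 0, fdrCut <= 1, diaFcCut >= 1, diaPCut > 0,
              maxProfiles >= 1, maxUnitChange >= 1,
              corrThreshold > 0, corrThreshold <= 1, topK >= 1, topN >= 1)
    structure(list(counts = counts, samples = samples, lengths = lengths,
                   terms = terms, simulation = simulation, seed = as.integer(seed),
                   tau = tau, pseudocount = pseudocount, pCut = pCut,
                   fdrCut = fdrCut, diaFcCut = diaFcCut, diaPCut = diaPCut,
                   strictDualTest = strictDualTest,
                   maxProfiles = as.integer(maxProfiles),
                   maxUnitChange = as.integer(maxUnitChange),
                   clusterCorrThreshold = clusterCorrThreshold,
                   corrThreshold = corrThreshold, corrUseAbs = corrUseAbs,
                   topK = as.integer(topK), blockSize = as.integer(blockSize),
                   diaCombination = diaCombination, diaLogBase = diaLogBase,
                   topN = as.integer(topN), verbose = verbose),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; keys are [pipelineConfig()] arguments.
#' @export
readPipelineConfig <- function(path) {
    raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
           else yaml::read_yaml(path)
    do.call(pipelineConfig, raw)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading or simulation; RPKM normalization,
#' abundance binning and stage-presence analysis; stage-pair DEG testing;
#' model-profile pattern analysis over the DEG union; co-expression network
#' and node-gene ranking over the DEG union; and DIA term scoring per
#' comparison. Every stage product is materialized as a TSV in `outDir`, and
#' a machine-readable `report.json` (sorted keys, 9-significant-digit
#' floats) summarizes the run. Identical inputs, configuration and seed give
#' byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return the report, invisibly (class `PipelineReport`).
#' @export
runPipeline <- function(config, outDir) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    say <- function(...) if (isTRUE(config$verbose)) message(...)
    t0 <- proc.time()[["elapsed"]]
    timings <- list()
    tick <- function(stage) {
        t1 <- proc.time()[["elapsed"]]
        timings[[stage]] <<- round(t1 - t0, 3)
        t0 <<- t1
    }

    ## ingest
    truth <- NULL
    if (!is.null(config$counts)) {
        se <- readStageExperiment(config$counts, config$samples, config$lengths)
        terms <- if (!is.null(config$terms)) readGMT(config$terms) else NULL
    } else {
        simArgs <- config$simulation %||% list()
        simArgs$seed <- simArgs$seed %||% config$seed
        simCfg <- do.call(simulationConfig, simArgs)
        sim <- simulateCounts(simCfg)
        se <- sim$se
        truth <- sim$truth
        terms <- simulateAnnotation(simCfg, truth)
        writeFixture(sim, outDir, annotation = terms, config = simCfg)
    }
    say("loaded ", nrow(se), " genes x ", ncol(se), " samples")
    tick("ingest")

    ## expression core
    se <- computeRPKM(se)
    writeRPKM(rpkm(se), file.path(outDir, "rpkm.tsv"))
    means <- stageMeans(se)
    binTab <- vapply(colnames(means), function(s)
        table(classifyAbundance(means[, s])), integer(3))
    rownames(binTab) <- c("low", "medium", "high")
    pres <- stagePresence(means, tau = config$tau)
    tick("expression")

    ## DEG testing
    deg <- testDEG(se, pseudocount = config$pseudocount, pCut = config$pCut,
                   fdrCut = config$fdrCut, diaFcCut = config$diaFcCut,
                   diaPCut = config$diaPCut,
                   strictDualTest = config$strictDualTest)
    writeTSV(format(as.data.frame(deg), digits = 9, scientific = TRUE,
                    trim = TRUE),
             file.path(outDir, "deg_results.tsv"))
    degUnion <- sort(unique(deg$gene_id[deg$is_deg]))
    say(length(degUnion), " DEGs across comparisons")
    tick("deg")

    ## temporal patterns over the DEG union
    cand <- enumerateProfiles(length(stageLevels(se)), config$maxUnitChange)
    profiles <- selectModelProfiles(cand, config$maxProfiles)
    patMeans <- means[degUnion, , drop = FALSE]
    if (length(degUnion) >= 2L) {
        assign <- assignProfiles(patMeans, profiles, config$pseudocount)
        psig <- profileSignificance(patMeans, profiles, config$pseudocount)
        psig$cluster_id <- clusterProfiles(profiles, psig$significant,
                                           config$clusterCorrThreshold)
    } else {
        assign <- data.frame(gene_id = character(), profile_id = integer(),
                             correlation = numeric())
        psig <- data.frame(profile_id = as.integer(rownames(profiles)),
                           levels = apply(profiles, 1L, paste, collapse = ","),
                           observed = 0L, expected = 0, p = 1,
                           p_bonferroni = 1, significant = FALSE,
                           cluster_id = NA_integer_)
    }
    writeTSV(assign, file.path(outDir, "patterns.tsv"))
    writeTSV(psig, file.path(outDir, "profiles.tsv"))
    tick("patterns")

    ## co-expression network over the DEG union
    logx <- log2(rpkm(se)[degUnion, , drop = FALSE] + config$pseudocount)
    edges <- coexpressionNetwork(logx, threshold = config$corrThreshold,
                                 useAbs = config$corrUseAbs,
                                 blockSize = config$blockSize)
    writeTSV(edges, file.path(outDir, "network_edges.tsv"))
    hubs <- rankNodeGenes(edges, degUnion, topK = config$topK)
    writeTSV(attr(hubs, "full"), file.path(outDir, "network_degrees.tsv"))
    tick("network")

    ## DIA
    impacts <- NULL
    topTerms <- NULL
    if (!is.null(terms)) {
        comps <- unique(deg$comparison)
        impacts <- do.call(rbind, lapply(comps, function(cmp) {
            ti <- termImpact(terms, deg[deg$comparison == cmp, , drop = FALSE],
                             universe = rownames(se),
                             combination = config$diaCombination,
                             logBase = config$diaLogBase)
            ti <- normalizeImpacts(ti)
            cbind(comparison = cmp, ti)
        }))
        writeTSV(impacts, file.path(outDir, "dia_impacts.tsv"))
        topTerms <- topImpacted(impacts, n = config$topN)
    }
    tick("dia")

    ## report
    degCounts <- lapply(split(deg, deg$comparison), function(d)
        list(total = sum(d$is_deg), up = sum(d$direction == "up"),
             down = sum(d$direction == "down"),
             dia_filter = sum(d$passes_dia_filter)))
    report <- list(
        tool = "lactDGE", version = as.character(utils::packageVersion("lactDGE")),
        seed = config$seed,
        config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
        n_genes = nrow(se), n_samples = ncol(se),
        stages = stageLevels(se),
        abundance_bins = lapply(stats::setNames(colnames(binTab),
                                                colnames(binTab)),
            function(s) as.list(stats::setNames(as.integer(binTab[, s]),
                                                rownames(binTab)))),
        per_stage_expressed = as.list(pres$perStageTotals),
        unique_genes = as.list(pres$uniqueCounts),
        venn = as.list(pres$venn),
        deg_counts = degCounts,
        n_deg_union = length(degUnion),
        n_patterns_used = sum(psig$observed > 0),
        significant_profiles = psig$profile_id[psig$significant],
        network = list(n_edges = nrow(edges),
                       top_node_genes = hubs$gene_id,
                       top_degrees = hubs$degree),
        dia_top_terms = if (!is.null(topTerms))
            list(term_id = topTerms$term_id,
                 mean_impact = topTerms$mean_impact,
                 mean_flux = topTerms$mean_flux))
    class(report) <- "PipelineReport"
    writeReport(report, file.path(outDir, "report.json"))
    # timings are run-dependent; they go in the log, not the report
    writeLines(c(sprintf("lactDGE pipeline, seed %d", config$seed),
                 sprintf("%-12s %8.3f s  (records in: %d genes x %d samples)",
                         names(timings), unlist(timings), nrow(se), ncol(se))),
               file.path(outDir, "pipeline_log.txt"))
    attr(report, "timings") <- timings
    if (!is.null(truth)) attr(report, "truth") <- truth
    attr(report, "deg") <- deg
    invisible(report)
}

#' Write a pipeline report as deterministic JSON
#'
#' Keys sorted, floats at 9 significant digits, UTF-8: identical reports
#' give byte-identical files.
#'
#' @param report `PipelineReport` (any nested list works).
#' @param path output path.
#' @export
writeReport <- function(report, path) {
    rounded <- rapply(unclass(report), function(x)
        if (is.double(x)) signif(x, 9) else x, how = "replace")
    sortKeys <- function(x) {
        if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x))))
            x <- lapply(x[order(names(x))], sortKeys)
        else if (is.list(x)) x <- lapply(x, sortKeys)
        x
    }
    json <- jsonlite::toJSON(sortKeys(rounded), auto_unbox = TRUE,
                             digits = NA, null = "null", pretty = TRUE)
    writeLines(json, path, useBytes = TRUE)
    invisible(path)
}
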