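#' Simulation configuration
#'
#' Builds and validates the configuration driving the synthetic-data
#' generator. Defaults emulate a 3-stage (L, D, NP) by 3-replicate bulk
#' transcriptome design with overdispersed negative-binomial counts,
#' lognormal baseline abundances, a fifth of genes carrying planted stage
#' effects of 2 log2 units per unit profile level, and one in ten annotation
#' terms preferentially drawing planted DE genes.
#'
#' @param nGenes number of genes.
#' @param stages ordered stage labels.
#' @param replicates replicates per stage.
#' @param baselineLogMean,baselineLogSd natural-log mean/sd of the lognormal
#'   baseline expected count.
#' @param nbDispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param fracDE fraction of genes with a planted temporal effect.
#' @param effectLog2FC log2 fold change per unit level of the planted
#'   profile template.
#' @param plantedProfiles list of integer level vectors (first level 0, unit
#'   steps bounded as in [enumerateProfiles()]); DE genes are assigned one.
#' @param profileWeights mixing weights over `plantedProfiles` (sum to 1).
#' @param geneLengthRange min/max gene length in bp.
#' @param nTerms,termSizeRange annotation terms and their size range.
#' @param fracEnrichedTerms fraction of terms enriched for planted DE genes.
#' @param enrichmentOdds odds multiplier with which enriched terms sample DE
#'   genes.
#' @param seed integer RNG seed; all outputs are pure functions of the
#'   configuration including this seed.
#' @return validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nGenes = 2000L,
                             stages = c("L", "D", "NP"),
                             replicates = 3L,
                             baselineLogMean = log(60),
                             baselineLogSd = 1.5,
                             nbDispersion = 0.1,
                             fracDE = 0.2,
                             effectLog2FC = 2,
                             plantedProfiles = list(c(0L, 1L, 1L),
                                                    c(0L, -1L, -1L),
                                                    c(0L, 1L, 0L),
                                                    c(0L, -1L, 0L)),
                             profileWeights = NULL,
                             geneLengthRange = c(300L, 5000L),
                             nTerms = 50L,
                             termSizeRange = c(10L, 50L),
                             fracEnrichedTerms = 0.1,
                             enrichmentOdds = 10,
                             seed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes), stages = as.character(stages),
                replicates = as.integer(replicates),
                baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
                nbDispersion = nbDispersion, fracDE = fracDE,
                effectLog2FC = effectLog2FC,
                plantedProfiles = lapply(plantedProfiles, as.integer),
                profileWeights = profileWeights %||%
                    rep(1 / length(plantedProfiles), length(plantedProfiles)),
                geneLengthRange = as.integer(geneLengthRange),
                nTerms = as.integer(nTerms),
                termSizeRange = as.integer(termSizeRange),
                fracEnrichedTerms = fracEnrichedTerms,
                enrichmentOdds = enrichmentOdds, seed = as.integer(seed))
    bad <- character()
    if (cfg$nGenes < 1) bad <- c(bad, "nGenes")
    if (length(cfg$stages) < 2 || anyDuplicated(cfg$stages)) bad <- c(bad, "stages")
    if (cfg$replicates < 1) bad <- c(bad, "replicates")
    if (cfg$baselineLogSd < 0) bad <- c(bad, "baselineLogSd")
    if (cfg$nbDispersion <= 0) bad <- c(bad, "nbDispersion")
    if (cfg$fracDE < 0 || cfg$fracDE > 1) bad <- c(bad, "fracDE")
    if (cfg$effectLog2FC < 0) bad <- c(bad, "effectLog2FC")
    if (!length(cfg$plantedProfiles) ||
        any(vapply(cfg$plantedProfiles, function(p)
            length(p) != length(cfg$stages) || p[1L] != 0L, TRUE)))
        bad <- c(bad, "plantedProfiles")
    if (length(cfg$profileWeights) != length(cfg$plantedProfiles) ||
        abs(sum(cfg$profileWeights) - 1) > 1e-8 || any(cfg$profileWeights < 0))
        bad <- c(bad, "profileWeights")
    if (diff(cfg$geneLengthRange) < 0 || cfg$geneLengthRange[1L] < 1)
        bad <- c(bad, "geneLengthRange")
    if (cfg$nTerms < 1) bad <- c(bad, "nTerms")
    if (cfg$termSizeRange[1L] < 1 || diff(cfg$termSizeRange) < 0)
        bad <- c(bad, "termSizeRange")
    if (cfg$termSizeRange[2L] > cfg$nGenes) bad <- c(bad, "termSizeRange")
    if (cfg$fracEnrichedTerms < 0 || cfg$fracEnrichedTerms > 1)
        bad <- c(bad, "fracEnrichedTerms")
    if (cfg$enrichmentOdds <= 0) bad <- c(bad, "enrichmentOdds")
    if (length(bad))
        stop("invalid configuration field(s): ", paste(bad, collapse = ", "))
    structure(cfg, class = "SimulationConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a stage-structured count dataset with known ground truth
#'
#' Counts are negative-binomial with gene-specific expected value
#' `baseline * 2^(level * effectLog2FC)` per stage, where `baseline` is
#' lognormal across genes and `level` is the gene's planted profile level at
#' that stage (all-zero for non-DE genes). Dispersion is shared across genes.
#' The returned truth table records, per gene, the DE flag, the planted
#' template, and the true log2 fold change for every stage pair in the
#' orientation used by [testDEG()] (later stage over earlier stage).
#'
#' @param config a [simulationConfig()].
#' @return list with `se` (a [StageExperiment-class] with gene lengths and
#'   a `"counts"` assay) and `truth` (data.frame).
#' @examples
#' sim <- simulateCounts(simulationConfig(nGenes = 100, seed = 7))
#' table(sim$truth$is_de)
#' @export
simulateCounts <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    ng <- config$nGenes
    st <- config$stages
    t <- length(st)
    reps <- config$replicates
    genes <- sprintf("gene%05d", seq_len(ng))
    samples <- paste0(rep(st, each = reps), "_rep", rep(seq_len(reps), t))
    stage <- factor(rep(st, each = reps), levels = st)

    baseline <- stats::rlnorm(ng, config$baselineLogMean, config$baselineLogSd)
    lengths <- stats::setNames(
        sample(seq(config$geneLengthRange[1L], config$geneLengthRange[2L]),
               ng, replace = TRUE), genes)

    isDE <- stats::runif(ng) < config$fracDE
    tmplIdx <- integer(ng)
    tmplIdx[isDE] <- sample.int(length(config$plantedProfiles), sum(isDE),
                                replace = TRUE, prob = config$profileWeights)
    levelsMat <- matrix(0L, ng, t)   # per-gene stage levels
    for (k in seq_along(config$plantedProfiles)) {
        hit <- which(tmplIdx == k)
        if (length(hit))
            levelsMat[hit, ] <- matrix(config$plantedProfiles[[k]],
                                       length(hit), t, byrow = TRUE)
    }

    mu <- baseline * 2^(levelsMat * config$effectLog2FC)  # genes x stages
    counts <- matrix(0, ng, t * reps, dimnames = list(genes, samples))
    for (j in seq_len(t * reps))
        counts[, j] <- stats::rnbinom(ng, mu = mu[, as.integer(stage[j])],
                                      size = 1 / config$nbDispersion)

    pairs <- utils::combn(seq_len(t), 2L)
    truth <- data.frame(gene_id = genes, is_de = isDE,
                        profile_template = ifelse(isDE, vapply(tmplIdx, function(k)
                            if (k == 0L) "" else paste(config$plantedProfiles[[k]],
                                                       collapse = ","), ""), ""),
                        stringsAsFactors = FALSE)
    for (p in seq_len(ncol(pairs))) {
        i <- pairs[1L, p]; j <- pairs[2L, p]
        truth[[paste0("log2fc_", st[i], "_", st[j])]] <-
            (levelsMat[, j] - levelsMat[, i]) * config$effectLog2FC
    }
    se <- StageExperiment(counts, stage, lengths = lengths,
                          replicate = rep(seq_len(reps), t), stageLevels = st)
    list(se = se, truth = truth)
}

#' Simulate a term annotation enriched for planted DE genes
#'
#' Terms sample member genes without replacement; "enriched" terms weight
#' planted DE genes by `enrichmentOdds`. Category/subcategory metadata cycle
#' through a small fixed hierarchy so the DIA roll-up is exercised.
#'
#' @param config a [simulationConfig()].
#' @param truth truth table from [simulateCounts()].
#' @return data.frame of class `TermAnnotation` with columns `term_id`,
#'   `name`, `category`, `subcategory`, `is_enriched`, and list-column
#'   `genes`.
#' @export
simulateAnnotation <- function(config, truth) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed + 1L)
    if (config$termSizeRange[2L] > nrow(truth))
        stop("term size range exceeds number of genes")
    nT <- config$nTerms
    nEnr <- round(config$fracEnrichedTerms * nT)
    isEnr <- seq_len(nT) <= nEnr
    cats <- c("Metabolism", "Genetic Information Processing",
              "Environmental Information Processing", "Cellular Processes")
    subs <- c("Lipid Metabolism", "Carbohydrate Metabolism",
              "Translation", "Signal Transduction", "Transport and Catabolism")
    w0 <- ifelse(truth$is_de, config$enrichmentOdds, 1)
    sizes <- sample(seq(config$termSizeRange[1L], config$termSizeRange[2L]),
                    nT, replace = TRUE)
    genes <- lapply(seq_len(nT), function(i) {
        w <- if (isEnr[i]) w0 else rep(1, nrow(truth))
        sort(sample(truth$gene_id, sizes[i], prob = w))
    })
    ann <- data.frame(term_id = sprintf("TERM%04d", seq_len(nT)),
                      name = sprintf("synthetic term %d", seq_len(nT)),
                      category = cats[(seq_len(nT) - 1L) %% length(cats) + 1L],
                      subcategory = subs[(seq_len(nT) - 1L) %% length(subs) + 1L],
                      is_enriched = isEnr, stringsAsFactors = FALSE)
    ann$genes <- genes
    class(ann) <- c("TermAnnotation", "data.frame")
    ann
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits `counts.tsv`, `samples.tsv`, `lengths.tsv`, `truth.tsv`,
#' `terms.gmt`, and a `manifest.json` recording the generating configuration,
#' in the dialects read back by [readCounts()], [readSamples()],
#' [readLengths()] and [readGMT()].
#'
#' @param sim list from [simulateCounts()] (elements `se`, `truth`).
#' @param dir output directory (created if needed).
#' @param annotation optional [simulateAnnotation()] table.
#' @param config optional configuration to record in the manifest.
#' @return invisibly, the vector of files written.
#' @export
writeFixture <- function(sim, dir, annotation = NULL, config = NULL) {
    se <- sim$se
    if (is.null(se) || nrow(se) == 0L)
        stop("empty dataset: nothing to write")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cnt <- assay(se, "counts")
    files <- file.path(dir, c("counts.tsv", "samples.tsv", "lengths.tsv", "truth.tsv"))
    writeTSV(data.frame(gene_id = rownames(cnt), cnt, check.names = FALSE), files[1L])
    writeTSV(data.frame(sample_id = colnames(se),
                        stage = as.character(colData(se)$stage),
                        replicate = colData(se)$replicate %||% seq_len(ncol(se))),
             files[2L])
    writeTSV(data.frame(gene_id = rownames(se),
                        length_bp = rowData(se)$length_bp), files[3L])
    writeTSV(sim$truth, files[4L])
    if (!is.null(annotation)) {
        writeGMT(annotation, file.path(dir, "terms.gmt"))
        files <- c(files, file.path(dir, "terms.gmt"))
    }
    if (!is.null(config)) {
        mf <- file.path(dir, "manifest.json")
        cfgOut <- unclass(config)
        jsonlite::write_json(cfgOut, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        files <- c(files, mf)
    }
    invisible(files)
}
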