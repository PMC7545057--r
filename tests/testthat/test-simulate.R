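test_that("simulation is a pure function of the configuration", {
    cfg <- simulationConfig(nGenes = 200, seed = 5)
    s1 <- simulateCounts(cfg)
    s2 <- simulateCounts(cfg)
    expect_identical(SummarizedExperiment::assay(s1$se, "counts"),
                     SummarizedExperiment::assay(s2$se, "counts"))
    expect_identical(s1$truth, s2$truth)
    # a different seed changes the draw
    s3 <- simulateCounts(simulationConfig(nGenes = 200, seed = 6))
    expect_false(identical(SummarizedExperiment::assay(s1$se, "counts"),
                           SummarizedExperiment::assay(s3$se, "counts")))
})

test_that("fracDE = 0 plants nothing and group differences are centered", {
    sim <- simulateCounts(simulationConfig(nGenes = 1500, fracDE = 0, seed = 3))
    fcCols <- grep("^log2fc_", colnames(sim$truth))
    expect_true(all(sim$truth[, fcCols] == 0))
    expect_false(any(sim$truth$is_de))
    # sign test on L vs D replicate-mean differences: no systematic direction
    cm <- SummarizedExperiment::assay(sim$se, "counts")
    st <- sampleStages(sim$se)
    d <- rowMeans(cm[, st == "D"]) - rowMeans(cm[, st == "L"])
    d <- d[d != 0]
    bt <- stats::binom.test(sum(d > 0), length(d), 0.5)
    expect_gt(bt$p.value, 0.01)
})

test_that("planted effects have the configured magnitude and dispersion", {
    cfg <- simulationConfig(nGenes = 2000, effectLog2FC = 2, seed = 9)
    sim <- simulateCounts(cfg)
    cm <- SummarizedExperiment::assay(sim$se, "counts")
    st <- sampleStages(sim$se)
    # planted up-genes between affected stages: mean log2 ratio ~ 2 (count scale)
    up <- sim$truth$log2fc_L_D > 0
    ratio <- log2(rowMeans(cm[up, st == "D"]) / rowMeans(cm[up, st == "L"]))
    expect_lt(abs(mean(ratio) - 2), 0.15)
    # NB mean-variance: var ~ mu + phi mu^2 for flat genes, within MC tolerance
    flat <- !sim$truth$is_de
    mu <- rowMeans(cm[flat, ])
    v <- apply(cm[flat, ], 1, stats::var)
    keep <- mu > 50
    phiHat <- stats::median((v[keep] - mu[keep]) / mu[keep]^2)
    expect_lt(abs(phiHat - cfg$nbDispersion), 0.05)
})

test_that("invalid configurations name the offending field", {
    expect_error(simulationConfig(fracDE = 1.5), "fracDE")
    expect_error(simulationConfig(nbDispersion = 0), "nbDispersion")
    expect_error(simulationConfig(plantedProfiles = list(c(1L, 0L, 0L))),
                 "plantedProfiles")
    expect_error(simulationConfig(termSizeRange = c(50, 10)), "termSizeRange")
})

test_that("annotation enrichment follows the configured odds", {
    cfg0 <- simulationConfig(nGenes = 1000, nTerms = 50, fracEnrichedTerms = 0.5,
                             enrichmentOdds = 1, seed = 21)
    sim <- simulateCounts(cfg0)
    ann0 <- simulateAnnotation(cfg0, sim$truth)
    deFrac <- function(ann, truth) {
        de <- truth$gene_id[truth$is_de]
        vapply(ann$genes, function(g) mean(g %in% de), 0)
    }
    f0 <- deFrac(ann0, sim$truth)
    # odds 1: "enriched" terms are no different from the global DE fraction
    expect_lt(abs(mean(f0[ann0$is_enriched]) - mean(sim$truth$is_de)), 0.05)

    cfg1 <- simulationConfig(nGenes = 1000, nTerms = 50, fracEnrichedTerms = 0.5,
                             enrichmentOdds = 10, fracDE = 0.1, seed = 22)
    sim1 <- simulateCounts(cfg1)
    ann1 <- simulateAnnotation(cfg1, sim1$truth)
    f1 <- deFrac(ann1, sim1$truth)
    expect_gt(mean(f1[ann1$is_enriched]), mean(f1[!ann1$is_enriched]))
    # every term non-empty, sizes within range
    sz <- lengths(ann1$genes)
    expect_true(all(sz >= cfg1$termSizeRange[1] & sz <= cfg1$termSizeRange[2]))
})

test_that("fixtures round-trip and regenerate from their manifest", {
    cfg <- simulationConfig(nGenes = 120, nTerms = 10, seed = 13)
    sim <- simulateCounts(cfg)
    ann <- simulateAnnotation(cfg, sim$truth)
    dir <- withr::local_tempdir()
    writeFixture(sim, dir, annotation = ann, config = cfg)

    se2 <- readStageExperiment(file.path(dir, "counts.tsv"),
                               file.path(dir, "samples.tsv"),
                               file.path(dir, "lengths.tsv"))
    expect_equal(SummarizedExperiment::assay(se2, "counts"),
                 SummarizedExperiment::assay(sim$se, "counts"))
    expect_equal(geneLengths(se2), geneLengths(sim$se))
    ann2 <- readGMT(file.path(dir, "terms.gmt"))
    expect_equal(ann2$term_id, ann$term_id)
    expect_equal(ann2$genes, ann$genes)

    # identical GMT bytes for a fixed seed
    dir2 <- withr::local_tempdir()
    writeFixture(simulateCounts(cfg), dir2,
                 annotation = simulateAnnotation(cfg, sim$truth))
    expect_identical(readLines(file.path(dir, "terms.gmt")),
                     readLines(file.path(dir2, "terms.gmt")))

    # regeneration from the recorded manifest
    mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
    mf$plantedProfiles <- lapply(seq_len(nrow(mf$plantedProfiles)),
                                 function(i) mf$plantedProfiles[i, ])
    cfg3 <- do.call(simulationConfig, mf)
    sim3 <- simulateCounts(cfg3)
    expect_identical(SummarizedExperiment::assay(sim3$se, "counts"),
                     SummarizedExperiment::assay(sim$se, "counts"))

    # empty dataset refuses to write
    empty <- sim; empty$se <- sim$se[0, ]
    expect_error(writeFixture(empty, withr::local_tempdir()), "empty")
})
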