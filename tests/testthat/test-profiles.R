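test_that("candidate enumeration is exhaustive and ordered", {
    expect_equal(nrow(enumerateProfiles(3, 2)), 25L)
    expect_equal(nrow(enumerateProfiles(3, 1)), 9L)
    p22 <- enumerateProfiles(2, 2)
    expect_equal(nrow(p22), 5L)
    expect_equal(unname(p22[, 2]), -2:2)
    expect_true(all(p22[, 1] == 0))
    # the (2c+1)^(t-1) law over the full supported range
    for (t in 2:5) for (c in 1:3)
        expect_equal(nrow(enumerateProfiles(t, c)), (2L * c + 1L)^(t - 1L))
    expect_error(enumerateProfiles(1, 2), "at least 2")
})

test_that("profile selection honors m and matches exhaustive max-min", {
    cand <- enumerateProfiles(3, 2)
    expect_equal(nrow(selectModelProfiles(cand, 30)), 25L)
    sel20 <- selectModelProfiles(cand, 20)
    expect_equal(nrow(sel20), 20L)
    expect_equal(rownames(sel20), as.character(0:19))

    # t=3, c=1, m=3: exhaustive search over all 3-subsets containing the flat
    # profile, maximizing the minimum pairwise distance, ties to the
    # lexicographically smallest candidate-id set
    cand9 <- enumerateProfiles(3, 1)
    sel3 <- selectModelProfiles(cand9, 3)
    flat <- which(apply(cand9, 1, function(z) all(z == 0)))
    best <- NULL; bestScore <- -Inf
    for (sub in utils::combn(setdiff(1:9, flat), 2, simplify = FALSE)) {
        trio <- sort(c(flat, sub))
        d <- utils::combn(trio, 2, function(ij)
            profileDistance(cand9[ij[1], ], cand9[ij[2], ]))
        score <- min(d)
        if (score > bestScore + 1e-12) { bestScore <- score; best <- trio }
    }
    expect_equal(sort(attr(sel3, "candidate_id")),
                 as.integer(rownames(cand9)[best]))
})

test_that("gene assignment finds exact matches and handles flat genes", {
    prof <- selectModelProfiles(enumerateProfiles(3, 2), 20)
    # a gene whose transform equals a profile's levels gets correlation 1
    target <- prof[which(apply(prof, 1, paste, collapse = ",") == "0,1,1"), ]
    means <- rbind(match = 2^c(3, 4, 4), const = c(7, 7, 7))
    colnames(means) <- c("L", "D", "NP")
    asg <- assignProfiles(means, prof, pseudocount = 0)
    expect_equal(asg$correlation[1], 1)
    expect_equal(paste(prof[as.character(asg$profile_id[1]), ], collapse = ","),
                 "0,1,1")
    # constant gene -> the flat profile
    flatId <- as.integer(rownames(prof)[apply(prof, 1, function(z) all(z == 0))])
    expect_equal(asg$profile_id[2], flatId)

    # permutation invariance over gene order
    set.seed(12)
    mm <- matrix(stats::rlnorm(60, 3, 1), 20, 3,
                 dimnames = list(paste0("g", 1:20), c("L", "D", "NP")))
    a1 <- assignProfiles(mm, prof)
    ord <- sample(20)
    a2 <- assignProfiles(mm[ord, ], prof)
    expect_equal(a2$profile_id[order(ord)], a1$profile_id)
})

test_that("planted templates are recovered at low noise", {
    # planted templates must be the lowest-id member of their proportionality
    # class within the selected set: correlation cannot distinguish a profile
    # from its scalar multiples, and ties break to the lowest id
    cfg <- simulationConfig(nGenes = 200, fracDE = 1, nbDispersion = 0.005,
                            baselineLogMean = log(500), baselineLogSd = 1,
                            plantedProfiles = list(c(0L, -2L, -2L),
                                                   c(0L, -2L, 0L),
                                                   c(0L, 1L, 0L),
                                                   c(0L, 1L, 1L)),
                            seed = 31)
    sim <- simulateCounts(cfg)
    # count-scale stage means: the scale the templates are planted on
    means <- stageMeans(SummarizedExperiment::assay(sim$se, "counts"),
                        stage = sampleStages(sim$se))
    prof <- selectModelProfiles(enumerateProfiles(3, 2), 20)
    asg <- assignProfiles(means, prof)
    lv <- apply(prof, 1, paste, collapse = ",")
    assignedTmpl <- lv[as.character(asg$profile_id)]
    acc <- mean(assignedTmpl == sim$truth$profile_template)
    expect_gte(acc, 0.9)
})

test_that("profile significance conserves counts and flags plantings", {
    prof <- selectModelProfiles(enumerateProfiles(3, 2), 20)
    # all genes planted on one template -> that profile overwhelmingly significant
    set.seed(8)
    means <- t(replicate(150, 2^(c(0, 1, 2) + stats::rnorm(3, 0, 0.05)) * 50))
    colnames(means) <- c("L", "D", "NP")
    sig <- profileSignificance(means, prof)
    expect_equal(sum(sig$observed), 150L)
    expect_equal(sum(sig$expected), 150, tolerance = 1e-9)
    hot <- sig[sig$levels == "0,1,2", ]
    expect_true(hot$significant)
    expect_lt(hot$p, 1e-6)
    expect_error(profileSignificance(matrix(1, 2, 7), enumerateProfiles(7, 1)),
                 "more than 6")
})

test_that("pattern direction partitions any profile set", {
    expect_equal(patternDirection(c(0, 2, 1), 1, 2), "up")
    expect_equal(patternDirection(c(0, 0, -1), 1, 2), "flat")
    expect_equal(patternDirection(c(0, -1, 2), 1, 2), "down")
    prof <- enumerateProfiles(3, 2)
    dir <- apply(prof, 1, patternDirection, from = 1, to = 2)
    expect_equal(sum(table(dir)), nrow(prof))
    expect_equal(as.vector(table(dir)[c("down", "flat", "up")]),
                 c(10L, 5L, 10L))
})

test_that("significant profiles cluster by correlation components", {
    prof <- enumerateProfiles(3, 1)
    sig <- rep(FALSE, 9)
    lv <- apply(prof, 1, paste, collapse = ",")
    sig[lv %in% c("0,1,2", "0,1,1", "0,-1,-2")] <- TRUE
    cl <- clusterProfiles(prof, sig, corThreshold = 0.7)
    expect_true(all(is.na(cl[!sig])))
    # the two rising profiles are correlated above 0.7, the falling one is not
    expect_equal(cl[lv == "0,1,2"], cl[lv == "0,1,1"])
    expect_false(cl[lv == "0,1,2"] == cl[lv == "0,-1,-2"])
})
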