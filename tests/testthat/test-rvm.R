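test_that("moderated variance has the documented limits", {
    fit <- new("RVMFit", a = 2, b = 0.5, df = 4, logLik = 0, n = 100L,
               convergence = 0L)
    s2 <- c(0.2, 1, 5)
    expect_equal(moderatedVariance(s2, fit), (4 * s2 + 2 / 0.5) / (4 + 2 * 2))
    # d -> Inf at fixed (a, b): moderation vanishes
    fitBig <- new("RVMFit", a = 2, b = 0.5, df = 1e8, logLik = 0, n = 100L,
                  convergence = 0L)
    expect_equal(moderatedVariance(s2, fitBig), s2, tolerance = 1e-6)
})

test_that("RVM fit recovers the variance prior and is deterministic", {
    set.seed(101)
    s2 <- rvmVariances(4000, a = 3, rate = 2, d = 4)
    fit1 <- fitRVM(s2, df = 4)
    fit2 <- fitRVM(s2, df = 4)
    expect_identical(fit1@a, fit2@a)
    # true shape 3, scale 1/rate = 0.5; modest n so a loose Monte-Carlo band
    expect_lt(abs(fit1@a - 3) / 3, 0.25)
    expect_lt(abs(fit1@b - 0.5) / 0.5, 0.25)
    # independent cross-check: limma's scaled-F fit in its parameterization
    # (s^2 ~ s0^2 F(d, d0) with d0 = 2a, s0^2 = 1/(ab))
    if (requireNamespace("limma", quietly = TRUE)) {
        ff <- limma::fitFDist(s2, df1 = 4)
        expect_lt(abs(fit1@a - ff$df2 / 2) / fit1@a, 0.15)
        expect_lt(abs(fit1@b - 1 / (ff$scale * ff$df2 / 2)) / fit1@b, 0.15)
    }
    expect_error(fitRVM(rep(0, 100), df = 4), "degenerate")
    expect_error(fitRVM(stats::runif(20), df = 4), "at least 50")
})

test_that("constant shift of variances moves the scale, not the F-statistic", {
    set.seed(7)
    s2 <- rvmVariances(2000, a = 2.5, rate = 1, d = 4)
    fit <- fitRVM(s2, df = 4)
    fitScaled <- fitRVM(4 * s2, df = 4)
    # scaling variances by c scales 1/b by c, leaves the shape alone
    expect_lt(abs(fitScaled@b - fit@b / 4) / (fit@b / 4), 0.05)
    expect_lt(abs(fitScaled@a - fit@a) / fit@a, 0.05)
    # rescaled data under the rescaled fit reproduce s2*a*b
    expect_equal(4 * s2 * fitScaled@a * fitScaled@b,
                 s2 * fitScaled@a * (4 * fitScaled@b), tolerance = 1e-12)
})

test_that("the moderated t-test matches its quadrature oracle", {
    set.seed(15)
    fit <- fitRVM(rvmVariances(500, 3, 2, 4), df = 4)
    # identical group means -> t 0, p 1
    tt0 <- rvmTTest(1, 1, 0.3, 0.5, 3, 3, fit)
    expect_equal(tt0$t, 0)
    expect_equal(tt0$p, 1)

    # 3 vs 3 toy: p equals numerical integration of the t density at tt$df
    g1 <- c(2.1, 2.5, 1.9); g2 <- c(3.4, 3.1, 3.6)
    tt <- rvmTTest(mean(g1), mean(g2), stats::var(g1), stats::var(g2), 3, 3, fit)
    pOracle <- 2 * stats::integrate(function(u) stats::dt(u, tt$df),
                                    abs(tt$t), Inf)$value
    expect_equal(tt$p, pOracle, tolerance = 1e-6)

    # a -> Inf with a*b fixed: converges to the ordinary pooled t
    ab <- fit@a * fit@b
    fitInf <- new("RVMFit", a = 1e7, b = ab / 1e7, df = 4, logLik = 0,
                  n = 500L, convergence = 0L)
    ttInf <- rvmTTest(mean(g1), mean(g2), stats::var(g1), stats::var(g2),
                      3, 3, fitInf)
    ordinary <- stats::t.test(g2, g1, var.equal = TRUE)
    # with a*b fixed the prior mean of 1/sigma^2 stays ~ab but its weight 2a
    # dominates d, so the moderated variance tends to the prior, not s2;
    # the classical limit instead holds for d -> Inf (checked above). Here we
    # assert the statistic is finite and the ordinary t is reproduced when
    # moderation is switched off by a huge d.
    fitD <- new("RVMFit", a = fit@a, b = fit@b, df = 1e9, logLik = 0,
                n = 500L, convergence = 0L)
    suppressWarnings(ttD <- rvmTTest(mean(g1), mean(g2), stats::var(g1),
                                     stats::var(g2), 3, 3, fitD))
    expect_equal(unname(ttD$t), unname(ordinary$statistic), tolerance = 1e-6)
    expect_true(is.finite(ttInf$t))
    expect_error(rvmTTest(1, 2, 0.1, 0.1, 1, 3, fit), ">= 2")
})

test_that("chi-square count test matches hand and library oracles", {
    # proportional counts -> statistic 0, p 1
    cs0 <- chisqCountTest(10, 20, 1e6, 2e6)
    expect_equal(cs0$statistic, 0)
    expect_equal(cs0$p, 1)

    # hand-evaluated table
    cs <- chisqCountTest(100, 40, 1e6, 1e6)
    expect_equal(cs$statistic, 25.71609, tolerance = 1e-5)

    # random tables vs stats::chisq.test (no continuity correction)
    set.seed(33)
    for (i in 1:20) {
        n1 <- sample(1e4:1e6, 1); n2 <- sample(1e4:1e6, 1)
        c1 <- sample(0:500, 1); c2 <- sample(0:500, 1)
        if (c1 + c2 == 0) next
        ours <- chisqCountTest(c1, c2, n1, n2)
        ref <- suppressWarnings(stats::chisq.test(
            matrix(c(c1, n1 - c1, c2, n2 - c2), 2, byrow = TRUE),
            correct = FALSE))
        expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
        expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-9)
    }
    expect_error(chisqCountTest(10, 5, 5, 100), "exceeds")
    expect_error(chisqCountTest(1, 1, 0, 10), "> 0")
})

test_that("BH adjustment reproduces the step-up rule", {
    expect_equal(bhFDR(0.03), 0.03)
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    # permutation invariance after matching back by index
    set.seed(4)
    p <- stats::runif(50)
    ord <- sample(50)
    expect_equal(bhFDR(p[ord])[order(ord)], bhFDR(p))
    expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calling gates on both p and FDR; DIA filter is strict", {
    rec <- data.frame(log2fc = c(1, -1.5, 0.5), p_rvm = c(0.04, 0.01, 0.2),
                      fdr = c(0.2, 0.01, 0.5))
    out <- callDEGs(rec)
    expect_equal(out$is_deg, c(FALSE, TRUE, FALSE))  # FDR gate holds
    expect_equal(out$direction, c("none", "down", "none"))

    expect_false(diaFilter(1.0, 1e-5))          # fold change 2 exactly fails ">"
    expect_true(diaFilter(2, 1e-4))
    expect_false(diaFilter(2, 0.001))           # p boundary is strict too
    # filter count on a simulated table matches a one-line scan
    set.seed(9)
    fc <- stats::rnorm(1000, 0, 2); p <- stats::runif(1000)^3
    expect_equal(sum(diaFilter(fc, p)), sum(abs(fc) > 1 & p < 0.001))
})

test_that("planted DEG recovery matches its frozen ground-truth oracle", {
    # union-over-comparisons sensitivity/FDR against the simulator's per-gene
    # is_de labels, at the generator's default conditions. RPKM total-count
    # normalization carries a composition shift from the planted mass
    # imbalance, which costs FDR; values frozen from the oracle at this seed.
    sim <- simulateCounts(simulationConfig())
    deg <- testDEG(computeRPKM(sim$se))
    calledAny <- tapply(deg$is_deg, deg$gene_id, any)[sim$truth$gene_id]
    sens <- sum(calledAny & sim$truth$is_de) / sum(sim$truth$is_de)
    fdr <- sum(calledAny & !sim$truth$is_de) / sum(calledAny)
    expect_gt(sens, 0.8)
    expect_equal(sens, 0.891, tolerance = 0.005)
    expect_equal(fdr, 0.162, tolerance = 0.01)
})
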