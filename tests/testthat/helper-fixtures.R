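# small in-code fixtures shared across tests

# 2 genes x 6 samples toy with known counts
toySE <- function() {
    cnt <- matrix(c(10, 20, 30, 40, 50, 60,
                    90, 80, 70, 60, 50, 40), nrow = 2, byrow = TRUE,
                  dimnames = list(c("gA", "gB"),
                                  c("L1", "L2", "D1", "D2", "NP1", "NP2")))
    StageExperiment(cnt, rep(c("L", "D", "NP"), each = 2),
                    lengths = c(gA = 1000, gB = 2000))
}

# simulate variances from the random variance model: 1/sigma^2 ~ Gamma(a, rate),
# s^2 | sigma^2 ~ sigma^2 * chisq_d / d
rvmVariances <- function(n, a, rate, d) {
    tau <- stats::rgamma(n, shape = a, rate = rate)
    (1 / tau) * stats::rchisq(n, d) / d
}

# profile-likelihood grid search over the variance-prior shape: for each a on a
# grid, the scale is optimized numerically; returns the grid argmax
gridRVMShape <- function(s2, d, aGrid = seq(1, 8, by = 0.05)) {
    s2 <- s2[s2 > 0]
    ll <- vapply(aGrid, function(a) {
        f <- function(logb) {
            b <- exp(logb)
            sum(stats::df(s2 * a * b, d, 2 * a, log = TRUE) + log(a * b))
        }
        stats::optimize(f, c(-12, 12), maximum = TRUE)$objective
    }, 0)
    aGrid[which.max(ll)]
}
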