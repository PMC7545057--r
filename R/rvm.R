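#' Fit the random variance model to per-gene sample variances
#'
#' The random variance model borrows variance information across genes by
#' assuming reciprocal true variances are Gamma distributed:
#' 1/sigma^2 ~ Gamma(shape a, scale b). Marginally the per-gene sample
#' variances then satisfy s^2 * a * b ~ F(d, 2a), where d is the residual
#' degrees of freedom of each gene's variance estimate. (a, b) are estimated
#' by maximum likelihood of that F density over all strictly positive
#' variances, with a deterministic moment-matched start, so refits on the
#' same data are identical.
#'
#' @param variances per-gene sample variances (length >= 50 positive values).
#' @param df residual degrees of freedom of each variance (scalar).
#' @return an [RVMFit-class].
#' @examples
#' set.seed(1)
#' s2 <- 1 / rgamma(500, shape = 3, rate = 2) * rchisq(500, 4) / 4
#' fitRVM(s2, df = 4)
#' @export
fitRVM <- function(variances, df) {
    s2 <- variances[!is.na(variances)]
    if (all(s2 == 0)) stop("degenerate variance distribution: all variances zero")
    s2 <- s2[s2 > 0]
    if (length(s2) < 50L)
        stop("need at least 50 strictly positive variances (have ", length(s2), ")")
    if (df <= 0) stop("df must be positive")
    negll <- function(par) {
        a <- exp(par[1L]); b <- exp(par[2L])
        -sum(stats::df(s2 * a * b, df, 2 * a, log = TRUE) + log(a * b))
    }
    # moment-matched start: median(s2)*a0*b0 = F-median at a0
    a0 <- 1.5
    b0 <- stats::qf(0.5, df, 2 * a0) / (stats::median(s2) * a0)
    opt <- stats::optim(log(c(a0, b0)), negll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (opt$convergence != 0L)
        stop("RVM fit did not converge (optim code ", opt$convergence,
             "): ", paste(deparse(opt), collapse = " "))
    new("RVMFit", a = exp(opt$par[1L]), b = exp(opt$par[2L]), df = df,
        logLik = -opt$value, n = length(s2), convergence = opt$convergence)
}

#' Moderated variance under a fitted random variance model
#'
#' Shrinks each sample variance toward the prior:
#' `(d*s^2 + 2/b) / (d + 2a)`. As d grows at fixed (a, b) the moderated
#' variance approaches the sample variance.
#'
#' @param s2 per-gene sample variances.
#' @param fit an [RVMFit-class].
#' @export
moderatedVariance <- function(s2, fit) {
    (fit@df * s2 + 2 / fit@b) / (fit@df + 2 * fit@a)
}

#' RVM-moderated two-sample t-test
#'
#' Two-sample t-test with the pooled within-group variance replaced by its
#' random-variance-model moderated counterpart; the reference distribution
#' gains the prior's 2a pseudo-degrees of freedom: df = d + 2a with
#' d = n1 + n2 - 2. All arguments are vectorized over genes.
#'
#' @param mean1,mean2 group means (gene-wise); the statistic is
#'   `mean2 - mean1` over its standard error.
#' @param var1,var2 group sample variances.
#' @param n1,n2 group sizes (>= 2).
#' @param fit an [RVMFit-class] fitted on the pooled variances.
#' @return list with `t`, `df`, `p` (two-sided), and `s2mod`.
#' @export
rvmTTest <- function(mean1, mean2, var1, var2, n1, n2, fit) {
    if (any(c(n1, n2) < 2L)) stop("each group needs >= 2 samples")
    d <- n1 + n2 - 2
    if (abs(d - fit@df) > 1e-8)
        warning("fit df (", fit@df, ") differs from data df (", d, ")")
    s2 <- ((n1 - 1) * var1 + (n2 - 1) * var2) / d
    s2mod <- moderatedVariance(s2, fit)
    se <- sqrt(s2mod * (1 / n1 + 1 / n2))
    tstat <- ifelse(se == 0, 0, (mean2 - mean1) / se)
    dfMod <- d + 2 * fit@a
    p <- 2 * stats::pt(-abs(tstat), dfMod)
    list(t = tstat, df = dfMod, p = pmax(p, .Machine$double.xmin), s2mod = s2mod)
}

#' Per-gene chi-square test on summed counts
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table
#' `[count, total - count]` for the two groups, testing proportionality of a
#' gene's summed counts to the group library totals. Vectorized over genes.
#'
#' @param count1,count2 gene counts summed over each group's samples.
#' @param total1,total2 group library totals (summed over samples).
#' @return list with `statistic` and `p`.
#' @export
chisqCountTest <- function(count1, count2, total1, total2) {
    if (any(total1 <= 0) || any(total2 <= 0)) stop("library totals must be > 0")
    if (any(count1 > total1) || any(count2 > total2))
        stop("gene count exceeds its library total")
    # closed-form Pearson statistic for the 2x2 table (double to avoid overflow)
    count1 <- as.numeric(count1); count2 <- as.numeric(count2)
    total1 <- as.numeric(total1); total2 <- as.numeric(total2)
    N <- total1 + total2
    stat <- N * (count1 * (total2 - count2) - count2 * (total1 - count1))^2 /
        ((count1 + count2) * (N - count1 - count2) * total1 * total2)
    stat[count1 + count2 == 0] <- 0
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    list(statistic = stat, p = pmax(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR-adjusted q-values via [stats::p.adjust()], with input
#' validation. NA p-values are rejected.
#'
#' @param p p-values in `[0, 1]`.
#' @export
bhFDR <- function(p) {
    if (anyNA(p) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}
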