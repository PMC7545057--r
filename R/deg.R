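#' Stage-pair differential expression testing
#'
#' Runs, for every stage pair of the design (canonically L vs D, L vs NP,
#' D vs NP), the RVM-moderated t-test on log2(RPKM + pseudocount) values and
#' the per-gene chi-square test on summed counts, applies Benjamini-Hochberg
#' FDR control within each comparison, and flags DEGs and DIA-filter passes.
#'
#' Orientation: for comparison "X_vs_Y" the fold change is
#' log2((mean_Y + pseudocount) / (mean_X + pseudocount)), so a gene
#' upregulated in the later stage has positive log2fc.
#'
#' @param se a [StageExperiment-class]; [computeRPKM()] is applied if the
#'   `"rpkm"` assay is absent.
#' @param pseudocount added to stage-mean RPKM before the log2 ratio and to
#'   per-sample RPKM before the log2 transform (default 0.125).
#' @param pCut,fdrCut DEG thresholds: `is_deg` iff `p_rvm < pCut` and
#'   `fdr < fdrCut` (default 0.05 each).
#' @param diaFcCut,diaPCut DIA input filter: fold change strictly greater
#'   than `diaFcCut` and `p_rvm < diaPCut` (defaults 2 and 0.001).
#' @param strictDualTest if `TRUE`, `is_deg` additionally requires the
#'   chi-square p below `pCut`.
#' @return object of class `DEGResult`: a data.frame with one row per gene
#'   per comparison (`gene_id`, `comparison`, `log2fc`, `p_rvm`, `p_chisq`,
#'   `fdr`, `direction`, `is_deg`, `passes_dia_filter`) and the per-comparison
#'   [RVMFit-class]s in `attr(, "fits")`.
#' @examples
#' sim <- simulateCounts(simulationConfig(nGenes = 300, seed = 2))
#' deg <- testDEG(computeRPKM(sim$se))
#' table(deg$comparison, deg$is_deg)
#' @export
testDEG <- function(se, pseudocount = 0.125, pCut = 0.05, fdrCut = 0.05,
                    diaFcCut = 2, diaPCut = 0.001, strictDualTest = FALSE) {
    if (!"rpkm" %in% assayNames(se)) se <- computeRPKM(se)
    st <- stageLevels(se)
    stage <- sampleStages(se)
    counts <- assay(se, "counts")
    logx <- log2(rpkm(se) + pseudocount)
    means <- stageMeans(se)                    # stage-mean RPKM
    pairs <- utils::combn(seq_along(st), 2L)
    fits <- list()
    out <- vector("list", ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
        i <- st[pairs[1L, k]]; j <- st[pairs[2L, k]]
        cmp <- paste0(i, "_vs_", j)
        si <- stage == i; sj <- stage == j
        n1 <- sum(si); n2 <- sum(sj)
        m1 <- rowMeans(logx[, si, drop = FALSE])
        m2 <- rowMeans(logx[, sj, drop = FALSE])
        v1 <- rowVars_(logx[, si, drop = FALSE])
        v2 <- rowVars_(logx[, sj, drop = FALSE])
        s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        fit <- fitRVM(s2, df = n1 + n2 - 2)
        fits[[cmp]] <- fit
        tt <- rvmTTest(m1, m2, v1, v2, n1, n2, fit)
        cs <- chisqCountTest(rowSums(counts[, si, drop = FALSE]),
                             rowSums(counts[, sj, drop = FALSE]),
                             sum(counts[, si]), sum(counts[, sj]))
        log2fc <- log2((means[, j] + pseudocount) / (means[, i] + pseudocount))
        rec <- data.frame(gene_id = rownames(se), comparison = cmp,
                          log2fc = log2fc, p_rvm = tt$p, p_chisq = cs$p,
                          fdr = bhFDR(tt$p), stringsAsFactors = FALSE,
                          row.names = NULL)
        out[[k]] <- rec
    }
    res <- do.call(rbind, out)
    res <- callDEGs(res, pCut = pCut, fdrCut = fdrCut,
                    strictDualTest = strictDualTest)
    res$passes_dia_filter <- diaFilter(res$log2fc, res$p_rvm,
                                       fcCut = diaFcCut, pCut = diaPCut)
    attr(res, "fits") <- fits
    attr(res, "pseudocount") <- pseudocount
    class(res) <- c("DEGResult", "data.frame")
    res
}

rowVars_ <- function(m) {
    n <- ncol(m)
    rowSums((m - rowMeans(m))^2) / (n - 1)
}

#' Flag differentially expressed genes
#'
#' `is_deg` iff the moderated p-value and the FDR are both below their cuts
#' (optionally the chi-square p too); `direction` is the fold-change sign
#' for DEGs and `"none"` otherwise.
#'
#' @param records data.frame with `log2fc`, `p_rvm`, `fdr` (and `p_chisq`
#'   when `strictDualTest`).
#' @param pCut,fdrCut significance thresholds (default 0.05).
#' @param strictDualTest also require `p_chisq < pCut`.
#' @return `records` with `is_deg` and `direction` columns set.
#' @export
callDEGs <- function(records, pCut = 0.05, fdrCut = 0.05,
                     strictDualTest = FALSE) {
    deg <- records$p_rvm < pCut & records$fdr < fdrCut
    if (strictDualTest) deg <- deg & records$p_chisq < pCut
    records$is_deg <- deg
    records$direction <- ifelse(!deg, "none",
                                ifelse(records$log2fc > 0, "up", "down"))
    records
}

#' DIA input filter
#'
#' Flags records with fold change strictly greater than `fcCut` (i.e.
#' `|log2fc| > log2(fcCut)`) and moderated p below `pCut`.
#'
#' @param log2fc,p vectors of log2 fold changes and p-values.
#' @param fcCut fold-change threshold on the natural scale (default 2).
#' @param pCut p-value threshold (default 0.001).
#' @export
diaFilter <- function(log2fc, p, fcCut = 2, pCut = 0.001) {
    abs(log2fc) > log2(fcCut) & p < pCut
}
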