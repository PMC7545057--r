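#' Accessors for StageExperiment
#'
#' `geneLengths()` returns the named vector of gene lengths (bp);
#' `sampleStages()` the per-sample stage factor; `stageLevels()` the ordered
#' stage labels of the design; `rpkm()` the RPKM assay (computing it first
#' errors if absent).
#'
#' @param x a [StageExperiment-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("geneLengths", "StageExperiment", function(x) {
    if (!"length_bp" %in% colnames(rowData(x)))
        stop("no gene lengths recorded; supply 'lengths' to StageExperiment()")
    stats::setNames(rowData(x)$length_bp, rownames(x))
})

#' @rdname accessors
#' @export
setMethod("sampleStages", "StageExperiment", function(x)
    stats::setNames(colData(x)$stage, colnames(x)))

#' @rdname accessors
#' @export
setMethod("stageLevels", "StageExperiment", function(x)
    levels(colData(x)$stage))

#' @rdname accessors
#' @export
setMethod("rpkm", "StageExperiment", function(x) {
    if (!"rpkm" %in% assayNames(x))
        stop("no 'rpkm' assay; run computeRPKM() first")
    assay(x, "rpkm")
})

#' RPKM normalization
#'
#' Computes reads per kilobase of transcript per million mapped reads:
#' `rpkm[g, s] = 1e9 * counts[g, s] / (libsize[s] * length_bp[g])`, where
#' `libsize[s]` is the column sum of the count matrix (the counted-read
#' total; the sequencer-level mapped-read total is not recoverable from a
#' count matrix). The result is stored as an `"rpkm"` assay alongside the
#' counts.
#'
#' @param x a [StageExperiment-class] with a `"counts"` assay and gene
#'   lengths, or a plain counts matrix.
#' @param lengths named gene lengths (bp); required for the matrix method.
#' @param ... unused.
#' @return the object with an `"rpkm"` assay added (matrix method: the RPKM
#'   matrix itself).
#' @examples
#' m <- matrix(c(10, 999990), nrow = 2,
#'             dimnames = list(c("g1", "g2"), "s1"))
#' computeRPKM(m, lengths = c(g1 = 1000, g2 = 2000))["g1", ]  # 10
#' @export
#' @rdname computeRPKM
setMethod("computeRPKM", "StageExperiment", function(x, ...) {
    r <- computeRPKM(assay(x, "counts"), lengths = geneLengths(x))
    assay(x, "rpkm") <- r
    validObject(x)
    x
})

#' @rdname computeRPKM
#' @export
setMethod("computeRPKM", "matrix", function(x, lengths, ...) {
    if (any(x < 0)) stop("counts must be non-negative")
    miss <- setdiff(rownames(x), names(lengths))
    if (length(miss))
        stop("missing gene length for: ", paste(utils::head(miss, 10), collapse = ", "))
    len <- as.numeric(lengths[rownames(x)])
    if (any(len < 1)) stop("gene lengths must be >= 1 bp")
    libsize <- colSums(x)
    if (any(libsize == 0))
        stop("zero library size for sample(s): ",
             paste(colnames(x)[libsize == 0], collapse = ", "))
    1e9 * sweep(x / len, 2, libsize, "/")
})

#' Abundance classification of RPKM values
#'
#' Bins expression values into the three conventional abundance classes:
#' low `[0, 10)`, medium `[10, 500)`, high `[500, Inf)` RPKM. The half-open
#' convention makes the bins a true partition of the non-negative axis while
#' preserving the "high >= 500" edge.
#'
#' @param x non-negative numeric vector of RPKM values.
#' @param lowCut,highCut bin boundaries (default 10 and 500 RPKM).
#' @return factor with levels `low`, `medium`, `high`.
#' @examples
#' classifyAbundance(c(0, 120.146, 537.391))  # low medium high
#' @export
classifyAbundance <- function(x, lowCut = 10, highCut = 500) {
    if (any(is.na(x)) || any(x < 0)) stop("RPKM values must be non-negative")
    cut(x, breaks = c(-Inf, lowCut, highCut, Inf), right = FALSE,
        labels = c("low", "medium", "high"))
}

#' Per-stage mean expression
#'
#' Arithmetic mean of replicate values within each stage, returned as a
#' genes x stages matrix with columns in the design's stage order.
#'
#' @param x a [StageExperiment-class] or a numeric matrix.
#' @param assay assay to average for the `StageExperiment` method
#'   (default `"rpkm"`).
#' @param stage stage factor (matrix method), one level per column group.
#' @param ... unused.
#' @export
#' @rdname stageMeans
setMethod("stageMeans", "StageExperiment", function(x, assay = "rpkm", ...) {
    stageMeans(SummarizedExperiment::assay(x, assay),
               stage = colData(x)$stage)
})

#' @rdname stageMeans
#' @export
setMethod("stageMeans", "matrix", function(x, stage, ...) {
    stage <- as.factor(stage)
    if (any(table(stage)[levels(stage)] == 0) || anyNA(stage))
        stop("every stage needs at least one sample")
    out <- matrix(0, nrow(x), nlevels(stage),
                  dimnames = list(rownames(x), levels(stage)))
    for (s in levels(stage))
        out[, s] <- rowMeans(x[, stage == s, drop = FALSE])
    out
})

#' Stage presence, stage-unique genes and the Venn partition
#'
#' A gene is called present in a stage when its stage-mean expression exceeds
#' `tau` (default 0, i.e. any positive signal). Returns the presence matrix,
#' per-stage totals, the genes unique to a single stage, and the full Venn
#' partition of the stages (all non-empty stage combinations plus the
#' absent-everywhere count).
#'
#' @param means genes x stages matrix of stage-mean expression
#'   (see [stageMeans()]).
#' @param tau presence threshold; presence is `mean > tau`.
#' @return a list of class `StagePresence` with elements `presence`
#'   (logical matrix), `perStageTotals`, `uniqueGenes` (named stage vector),
#'   `uniqueCounts`, `venn` (named counts over stage combinations, `"none"`
#'   for absent-everywhere), and `tau`.
#' @export
stagePresence <- function(means, tau = 0) {
    if (tau < 0) stop("tau must be >= 0")
    pres <- means > tau
    stages <- colnames(means)
    nset <- rowSums(pres)
    uniqueIdx <- which(nset == 1L)
    uniqueGenes <- stats::setNames(
        stages[max.col(pres[uniqueIdx, , drop = FALSE], ties.method = "first")],
        rownames(means)[uniqueIdx])
    combos <- unlist(lapply(seq_along(stages), function(k)
        utils::combn(stages, k, paste, collapse = "&", simplify = FALSE)),
        use.names = FALSE)
    key <- apply(pres, 1L, function(p) paste(stages[p], collapse = "&"))
    venn <- stats::setNames(integer(length(combos) + 1L), c(combos, "none"))
    tab <- table(ifelse(key == "", "none", key))
    venn[names(tab)] <- as.integer(tab)
    structure(list(presence = pres,
                   perStageTotals = colSums(pres),
                   uniqueGenes = uniqueGenes,
                   uniqueCounts = stats::setNames(
                       vapply(stages, function(s) sum(uniqueGenes == s), 0L), stages),
                   venn = venn, tau = tau),
              class = "StagePresence")
}

#' @export
print.StagePresence <- function(x, ...) {
    cat("StagePresence (tau =", x$tau, ")\n")
    cat("  per-stage totals:", paste(names(x$perStageTotals),
        x$perStageTotals, sep = "=", collapse = " "), "\n")
    cat("  unique genes:", paste(names(x$uniqueCounts),
        x$uniqueCounts, sep = "=", collapse = " "), "\n")
    invisible(x)
}

#' Tally stage-unique genes from a labelled table
#'
#' Counts records per stage from a table of `(gene, stage)` labels, e.g. a
#' curated list of uniquely expressed DEGs. Stages with no records report 0;
#' labels outside `stages` are an error.
#'
#' @param records data.frame with a `stage` column (one label per record).
#' @param stages stage labels defining the output order.
#' @return named integer vector of counts per stage.
#' @export
countUniqueByStage <- function(records, stages = c("L", "D", "NP")) {
    lab <- as.character(records$stage)
    bad <- setdiff(unique(lab), stages)
    if (length(bad))
        stop("unknown stage label(s): ", paste(bad, collapse = ", "))
    vapply(stages, function(s) sum(lab == s), 0L)
}
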