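#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assay<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' StageExperiment: an expression matrix with lactation-stage structure
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container for a
#' gene-by-sample expression matrix whose samples belong to ordered
#' physiological stages (default `L` = peak lactation, `D` = dry-off,
#' `NP` = non-lactating/non-pregnant involution). The `"counts"` assay holds
#' raw read counts; [computeRPKM()] adds an `"rpkm"` assay. Gene lengths (bp)
#' live in `rowData(x)$length_bp`, stage labels in `colData(x)$stage`.
#'
#' Validity requires: all assay values finite and non-negative, unique gene
#' and sample identifiers, a stage label for every sample, and at least one
#' sample per stage level.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`.
#' @export
setClass("StageExperiment", contains = "SummarizedExperiment")

setValidity("StageExperiment", function(object) {
    msg <- character()
    if (length(assays(object)) == 0L)
        return("at least one assay required")
    for (nm in assayNames(object)) {
        a <- assay(object, nm)
        if (anyNA(a) || any(!is.finite(a)))
            msg <- c(msg, sprintf("assay '%s' contains missing/non-finite values", nm))
        else if (any(a < 0))
            msg <- c(msg, sprintf("assay '%s' contains negative values", nm))
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicated gene identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated sample identifiers")
    if (!"stage" %in% colnames(colData(object))) {
        msg <- c(msg, "colData must contain a 'stage' column")
    } else {
        st <- colData(object)$stage
        if (!is.factor(st))
            msg <- c(msg, "'stage' must be a factor with the design's stage ordering")
        else {
            if (anyNA(st)) msg <- c(msg, "every sample needs a stage label")
            empty <- setdiff(levels(st), as.character(st))
            if (length(empty))
                msg <- c(msg, sprintf("stage(s) with no samples: %s",
                                      paste(empty, collapse = ", ")))
        }
    }
    if ("length_bp" %in% colnames(rowData(object))) {
        len <- rowData(object)$length_bp
        if (anyNA(len) || any(len < 1))
            msg <- c(msg, "gene lengths must be >= 1 bp")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a StageExperiment
#'
#' @param counts numeric matrix of non-negative read counts, genes x samples,
#'   with row and column names.
#' @param stage character or factor of stage labels, one per sample. If a
#'   character vector, stage order is taken from `stageLevels`.
#' @param lengths optional named numeric vector of gene lengths in bp,
#'   covering every gene in `counts`.
#' @param replicate optional replicate identifiers per sample.
#' @param stageLevels ordered stage labels of the design
#'   (default `c("L","D","NP")` intersected with the observed labels).
#' @return a [StageExperiment-class] object.
#' @examples
#' cnt <- matrix(rpois(12, 50), nrow = 2,
#'               dimnames = list(c("g1","g2"), paste0("s", 1:6)))
#' se <- StageExperiment(cnt, rep(c("L","D","NP"), each = 2),
#'                       lengths = c(g1 = 1000, g2 = 2500))
#' @export
StageExperiment <- function(counts, stage, lengths = NULL, replicate = NULL,
                            stageLevels = c("L", "D", "NP")) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have gene row names and sample column names")
    if (length(stage) != ncol(counts))
        stop("one stage label per sample required")
    if (!is.factor(stage)) {
        lv <- intersect(stageLevels, unique(as.character(stage)))
        extra <- setdiff(unique(as.character(stage)), lv)
        stage <- factor(as.character(stage), levels = c(lv, extra))
    }
    cd <- DataFrame(stage = stage, row.names = colnames(counts))
    if (!is.null(replicate)) cd$replicate <- replicate
    rd <- DataFrame(row.names = rownames(counts))
    if (!is.null(lengths)) {
        miss <- setdiff(rownames(counts), names(lengths))
        if (length(miss))
            stop("missing gene length for: ", paste(utils::head(miss, 10), collapse = ", "))
        rd$length_bp <- as.numeric(lengths[rownames(counts)])
    }
    new("StageExperiment",
        SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd))
}

#' RVMFit: fitted random-variance-model variance prior
#'
#' Holds the maximum-likelihood estimates of the inverse-gamma variance prior
#' of the random variance model: the reciprocal variances 1/sigma^2 are
#' modelled as Gamma(shape `a`, scale `b`), under which the per-gene sample
#' variances satisfy s^2 * a * b ~ F(d, 2a) for residual degrees of freedom
#' `d`. The moderated variance is (d*s^2 + 2/b) / (d + 2a) with d + 2a
#' total degrees of freedom.
#'
#' @slot a shape of the variance prior (positive).
#' @slot b scale of the variance prior (positive).
#' @slot df residual degrees of freedom per gene used in the fit.
#' @slot logLik maximized log-likelihood.
#' @slot n number of (positive) variances used.
#' @slot convergence optimizer convergence code (0 = converged).
#' @export
setClass("RVMFit",
    representation(a = "numeric", b = "numeric", df = "numeric",
                   logLik = "numeric", n = "integer", convergence = "integer"))

setValidity("RVMFit", function(object) {
    msg <- character()
    if (object@a <= 0) msg <- c(msg, "a must be > 0")
    if (object@b <= 0) msg <- c(msg, "b must be > 0")
    if (object@df <= 0) msg <- c(msg, "df must be > 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn StageExperiment compact display
#' @param object a `StageExperiment`
#' @export
setMethod("show", "StageExperiment", function(object) {
    st <- colData(object)$stage
    cat("StageExperiment with", nrow(object), "genes,", ncol(object), "samples\n")
    cat("  stages:", paste(sprintf("%s(%d)", levels(st), table(st)[levels(st)]),
                           collapse = " "), "\n")
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
    if ("length_bp" %in% colnames(rowData(object)))
        cat("  gene lengths: ", min(rowData(object)$length_bp), "-",
            max(rowData(object)$length_bp), " bp\n", sep = "")
})

#' @export
setMethod("show", "RVMFit", function(object) {
    cat("RVMFit (inverse-gamma variance prior)\n")
    cat(sprintf("  a = %.4f, b = %.4f (prior mean variance %.4f)\n",
                object@a, object@b, 1 / (object@b * (object@a - 1))))
    cat(sprintf("  residual df = %g, moderated df = %g\n",
                object@df, object@df + 2 * object@a))
    cat(sprintf("  fitted on %d variances, logLik = %.2f\n",
                object@n, object@logLik))
})
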