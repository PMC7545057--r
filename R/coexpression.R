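#' Pairwise Pearson correlations between genes
#'
#' Correlation of every unordered gene pair across samples, computed on the
#' rows of `x` (typically log2(RPKM + pseudocount)). Zero-variance genes
#' cannot be correlated and are reported in `attr(, "zeroVariance")`; their
#' entries are NA.
#'
#' @param x numeric matrix, genes x samples (>= 3 samples).
#' @param genes optional subset of row names.
#' @return correlation matrix with NA rows/columns for zero-variance genes.
#' @export
pairwisePearson <- function(x, genes = NULL) {
    if (!is.null(genes)) x <- x[genes, , drop = FALSE]
    if (ncol(x) < 3L) stop("need at least 3 samples for correlation")
    zv <- apply(x, 1L, stats::sd) == 0
    r <- suppressWarnings(stats::cor(t(x)))
    r[zv, ] <- NA_real_; r[, zv] <- NA_real_
    attr(r, "zeroVariance") <- rownames(x)[zv]
    r
}

#' Threshold a correlation matrix into a co-expression edge set
#'
#' Keeps each unordered pair with `|r| >= threshold` (or `r >= threshold`
#' when `useAbs = FALSE`); the boundary is inclusive. Self-pairs and
#' NA correlations (zero-variance genes) yield no edges.
#'
#' @param r correlation matrix from [pairwisePearson()].
#' @param threshold correlation threshold in (0, 1] (default 0.92).
#' @param useAbs apply the threshold to `|r|` (default `TRUE`).
#' @return data.frame `gene_a`, `gene_b`, `r` with `gene_a < gene_b`.
#' @export
buildNetwork <- function(r, threshold = 0.92, useAbs = TRUE) {
    if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
    v <- if (useAbs) abs(r) else r
    v[lower.tri(v, diag = TRUE)] <- NA
    idx <- which(!is.na(v) & v >= threshold, arr.ind = TRUE)
    edges <- data.frame(gene_a = rownames(r)[idx[, 1L]],
                        gene_b = colnames(r)[idx[, 2L]],
                        r = r[idx], stringsAsFactors = FALSE)
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
}

#' Co-expression network from an expression matrix, in gene blocks
#'
#' Streams the pairwise correlation computation in blocks of rows so that
#' peak memory is O(blockSize x n) even for DEG sets of ~1e4 genes, keeping
#' only edges passing the threshold. Identical edge set to the all-at-once
#' [pairwisePearson()] + [buildNetwork()] route.
#'
#' @inheritParams pairwisePearson
#' @inheritParams buildNetwork
#' @param blockSize rows per block (default 512).
#' @return edge data.frame as in [buildNetwork()], with
#'   `attr(, "zeroVariance")`.
#' @export
coexpressionNetwork <- function(x, threshold = 0.92, useAbs = TRUE,
                                blockSize = 512L) {
    if (ncol(x) < 3L) stop("need at least 3 samples for correlation")
    if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
    n <- nrow(x)
    zv <- apply(x, 1L, stats::sd) == 0
    keep <- which(!zv)
    xt <- t(x[keep, , drop = FALSE])
    starts <- seq(1L, length(keep), by = blockSize)
    pieces <- list()
    for (s in starts) {
        rows <- s:min(s + blockSize - 1L, length(keep))
        rblock <- stats::cor(xt[, rows, drop = FALSE], xt)  # block x all
        v <- if (useAbs) abs(rblock) else rblock
        # only pairs (i, j) with global index i < j
        mask <- outer(rows, seq_along(keep), "<") & v >= threshold
        idx <- which(mask, arr.ind = TRUE)
        if (nrow(idx)) {
            ga <- rownames(x)[keep[rows[idx[, 1L]]]]
            gb <- rownames(x)[keep[idx[, 2L]]]
            swap <- ga > gb
            tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
            pieces[[length(pieces) + 1L]] <-
                data.frame(gene_a = ga, gene_b = gb, r = rblock[idx],
                           stringsAsFactors = FALSE)
        }
    }
    edges <- if (length(pieces)) do.call(rbind, pieces)
             else data.frame(gene_a = character(), gene_b = character(),
                             r = numeric(), stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
    attr(edges, "zeroVariance") <- rownames(x)[zv]
    edges
}

#' Rank node (hub) genes by co-expression degree
#'
#' Degree = number of incident edges per gene. Genes are sorted by
#' descending degree with ties broken by gene id; when the `topK` boundary
#' falls inside a tie, all tied genes are included and the overflow is
#' reported.
#'
#' @param edges edge data.frame (`gene_a`, `gene_b`).
#' @param genes the gene universe of the network (genes without edges get
#'   degree 0).
#' @param topK number of node genes requested (default 20).
#' @return data.frame `gene_id`, `degree`, `rank` with
#'   `attr(, "full")` (the complete table) and `attr(, "overflow")`.
#' @export
rankNodeGenes <- function(edges, genes, topK = 20L) {
    degree <- stats::setNames(integer(length(genes)), genes)
    if (nrow(edges)) {
        tab <- table(c(edges$gene_a, edges$gene_b))
        degree[names(tab)] <- as.integer(tab)
    }
    full <- data.frame(gene_id = genes, degree = as.integer(degree),
                       stringsAsFactors = FALSE)
    full <- full[order(-full$degree, full$gene_id), , drop = FALSE]
    full$rank <- seq_len(nrow(full))
    rownames(full) <- NULL
    k <- min(topK, nrow(full))
    if (k < nrow(full)) {
        cutDeg <- full$degree[k]
        k <- max(which(full$degree >= cutDeg))  # include ties at the boundary
    }
    top <- full[seq_len(k), , drop = FALSE]
    attr(top, "full") <- full
    attr(top, "overflow") <- k - min(topK, nrow(full))
    top
}
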