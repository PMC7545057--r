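## Plain-text readers and writers for the pipeline's file dialects.
## All TSVs are UTF-8, tab-separated, with a header row.

writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
    invisible(path)
}

readTSV <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' Read a gene-by-sample count matrix
#'
#' Expects a header row of sample ids and one row per gene (gene id first).
#' Duplicated gene ids, missing values, and negative counts are errors that
#' name the offending gene or cell.
#'
#' @param path counts.tsv path.
#' @return numeric matrix, genes x samples.
#' @export
readCounts <- function(path) {
    df <- readTSV(path)
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicated gene id in ", path, ": ", ids[duplicated(ids)][1L])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicated sample id in ", path)
    storage.mode(m) <- "numeric"
    rownames(m) <- ids
    bad <- which(is.na(m) | m < 0, arr.ind = TRUE)
    if (nrow(bad))
        stop("invalid count at gene ", rownames(m)[bad[1L, 1L]],
             ", sample ", colnames(m)[bad[1L, 2L]], " in ", path)
    m
}

#' Read sample metadata
#'
#' Columns `sample_id`, `stage`, and optionally `replicate`.
#'
#' @param path samples.tsv path.
#' @export
readSamples <- function(path) {
    df <- readTSV(path)
    need <- c("sample_id", "stage")
    if (!all(need %in% colnames(df)))
        stop(path, " must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample id in ", path)
    df
}

#' Read gene lengths
#'
#' Columns `gene_id`, `length_bp`; returns a named numeric vector.
#'
#' @param path lengths.tsv path.
#' @export
readLengths <- function(path) {
    df <- readTSV(path)
    if (!all(c("gene_id", "length_bp") %in% colnames(df)))
        stop(path, " must have columns gene_id, length_bp")
    if (anyDuplicated(df$gene_id))
        stop("duplicated gene id in ", path)
    stats::setNames(as.numeric(df$length_bp), df$gene_id)
}

#' Assemble a StageExperiment from fixture files
#'
#' Reads counts, sample metadata, and gene lengths, checks the gene sets
#' agree (reporting the first elements of any symmetric difference), and
#' returns a validated [StageExperiment-class].
#'
#' @param countsPath,samplesPath,lengthsPath file paths.
#' @param stageLevels ordered stage labels.
#' @export
readStageExperiment <- function(countsPath, samplesPath, lengthsPath,
                                stageLevels = c("L", "D", "NP")) {
    cnt <- readCounts(countsPath)
    smp <- readSamples(samplesPath)
    len <- readLengths(lengthsPath)
    if (!setequal(colnames(cnt), smp$sample_id))
        stop("sample sets differ between counts and samples files: ",
             paste(utils::head(c(setdiff(colnames(cnt), smp$sample_id),
                                 setdiff(smp$sample_id, colnames(cnt))), 10),
                   collapse = ", "))
    sdiff <- c(setdiff(rownames(cnt), names(len)),
               setdiff(names(len), rownames(cnt)))
    if (length(sdiff))
        stop("gene sets differ between counts and lengths files: ",
             paste(utils::head(sdiff, 10), collapse = ", "))
    smp <- smp[match(colnames(cnt), smp$sample_id), , drop = FALSE]
    StageExperiment(cnt, smp$stage, lengths = len,
                    replicate = smp$replicate, stageLevels = stageLevels)
}

#' Read a GMT-style term annotation
#'
#' One term per line: term id, TAB, `category|subcategory|name`, TAB, member
#' gene ids (further tab-separated). Lines with fewer than 3 fields and
#' duplicated term ids are errors reporting the line number.
#'
#' @param path terms.gmt path.
#' @return `TermAnnotation` data.frame (see [simulateAnnotation()]).
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3L))
        stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields in ", path)
    ids <- vapply(parts, `[[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicated term id in ", path, ": ", ids[duplicated(ids)][1L])
    meta <- strsplit(vapply(parts, `[[`, "", 2L), "|", fixed = TRUE)
    pick <- function(v, i) if (length(v) >= i) v[[i]] else ""
    ann <- data.frame(term_id = ids,
                      name = vapply(meta, pick, "", 3L),
                      category = vapply(meta, pick, "", 1L),
                      subcategory = vapply(meta, pick, "", 2L),
                      stringsAsFactors = FALSE)
    ann$genes <- lapply(parts, function(p) unique(p[-(1:2)]))
    class(ann) <- c("TermAnnotation", "data.frame")
    ann
}

#' Write a term annotation as GMT
#'
#' @param terms `TermAnnotation` data.frame.
#' @param path output path.
#' @export
writeGMT <- function(terms, path) {
    lines <- vapply(seq_len(nrow(terms)), function(i)
        paste(c(terms$term_id[i],
                paste(terms$category[i], terms$subcategory[i], terms$name[i],
                      sep = "|"),
                terms$genes[[i]]), collapse = "\t"), "")
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Write an RPKM matrix in the counts.tsv dialect
#'
#' Mirrors the counts layout with 6-decimal fixed formatting.
#'
#' @param r RPKM matrix.
#' @param path output path.
#' @export
writeRPKM <- function(r, path) {
    df <- data.frame(gene_id = rownames(r),
                     apply(r, 2L, function(col) sprintf("%.6f", col)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", colnames(r))
    writeTSV(df, path)
}
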