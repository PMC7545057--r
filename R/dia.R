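#' Dynamic Impact Approach term scoring
#'
#' For one stage comparison, scores every annotation term by combining the
#' proportion of DIA-filtered DEGs among its measured member genes with the
#' mean absolute log2 fold change and the mean -log10 p-value of those DEGs:
#'
#'   impact = (|D| / k) * mean(|log2fc|) * mean(-log10 p)
#'
#' where D is the set of DIA-filtered DEGs in the term and k the number of
#' member genes present in the expression data. `impact_up` and
#' `impact_down` apply the same formula to the up- and down-regulated
#' subsets of D (with proportions |D_up|/k, |D_down|/k); the flux —
#' the direction of the impact — is `impact_up - impact_down`. Terms with no
#' measured member genes are skipped (and listed in `attr(, "skipped")`).
#'
#' @param terms a `TermAnnotation` table ([simulateAnnotation()] or
#'   [readGMT()]).
#' @param deg data.frame of per-gene records for one comparison (`gene_id`,
#'   `log2fc`, `p_rvm`, `passes_dia_filter`).
#' @param universe measured gene identifiers (the expression matrix rows).
#' @param combination `"product"` (default, zero exactly when no filtered
#'   DEG exists) or `"sum"` of the three factors, for sensitivity analysis.
#' @param logBase base of the p-value transform (default 10).
#' @return data.frame: `term_id`, `name`, `category`, `subcategory`, `k`,
#'   `n_deg`, `n_up`, `n_down`, `impact`, `impact_up`, `impact_down`,
#'   `flux`.
#' @examples
#' # a 10-gene term with two up (fc 4, p 1e-4) and two down DEGs (p 1e-2)
#' # has impact 0.4 * 2 * 3 = 2.4 and flux 1.6 - 0.8 = +0.8
#' @export
termImpact <- function(terms, deg, universe, combination = c("product", "sum"),
                       logBase = 10) {
    combination <- match.arg(combination)
    stopifnot(all(c("gene_id", "log2fc", "p_rvm", "passes_dia_filter")
                  %in% colnames(deg)))
    deg <- deg[deg$gene_id %in% universe, , drop = FALSE]
    fc <- stats::setNames(deg$log2fc, deg$gene_id)
    lp <- stats::setNames(-log(pmax(deg$p_rvm, 1e-300), base = logBase),
                          deg$gene_id)
    filt <- deg$gene_id[deg$passes_dia_filter]
    rows <- vector("list", nrow(terms))
    skipped <- character()
    score <- function(d, k) {
        if (!length(d)) return(0)
        prop <- length(d) / k
        if (combination == "product") prop * mean(abs(fc[d])) * mean(lp[d])
        else prop + mean(abs(fc[d])) + mean(lp[d])
    }
    for (i in seq_len(nrow(terms))) {
        members <- intersect(terms$genes[[i]], universe)
        k <- length(members)
        if (k == 0L) {
            skipped <- c(skipped, terms$term_id[i])
            next
        }
        d <- intersect(members, filt)
        up <- d[fc[d] > 0]
        down <- d[fc[d] < 0]
        iu <- score(up, k); id <- score(down, k)
        rows[[i]] <- data.frame(term_id = terms$term_id[i],
                                name = terms$name[i],
                                category = terms$category[i],
                                subcategory = terms$subcategory[i],
                                k = k, n_deg = length(d), n_up = length(up),
                                n_down = length(down),
                                impact = score(d, k),
                                impact_up = iu, impact_down = id,
                                flux = iu - id, stringsAsFactors = FALSE)
    }
    if (length(skipped))
        message("skipped ", length(skipped),
                " term(s) with no measured member gene")
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(out))
        out <- data.frame(term_id = character(), name = character(),
                          category = character(), subcategory = character(),
                          k = integer(), n_deg = integer(), n_up = integer(),
                          n_down = integer(), impact = numeric(),
                          impact_up = numeric(), impact_down = numeric(),
                          flux = numeric(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
}

#' Normalize term impacts to a 0-100 scale
#'
#' Divides by the maximum impact among the scored terms of one comparison
#' and scales to 100, so the most impacted term maps to 100 (the bar-length
#' convention of DIA summary figures). All-zero tables stay zero.
#'
#' @param impacts data.frame from [termImpact()].
#' @return `impacts` with an `impact_norm` column.
#' @export
normalizeImpacts <- function(impacts) {
    mx <- if (nrow(impacts)) max(impacts$impact) else 0
    impacts$impact_norm <- if (mx > 0) 100 * impacts$impact / mx
                           else rep(0, nrow(impacts))
    impacts
}

#' Category and subcategory roll-up of term impacts
#'
#' Unweighted means of term impact and flux within each subcategory and
#' category. Terms lacking category metadata are grouped under
#' `"uncategorized"` with a warning.
#'
#' @param impacts data.frame from [termImpact()] (one comparison, or with a
#'   `comparison` column for several).
#' @return list with data.frames `bySubcategory` and `byCategory`
#'   (`n_terms`, `mean_impact`, `mean_flux` per group and comparison).
#' @export
summarizeCategories <- function(impacts) {
    if (!nrow(impacts))
        return(list(byCategory = impacts, bySubcategory = impacts))
    missing <- is.na(impacts$category) | impacts$category == ""
    if (any(missing)) {
        warning(sum(missing), " term(s) without category metadata grouped ",
                "under 'uncategorized'")
        impacts$category[missing] <- "uncategorized"
        impacts$subcategory[missing | is.na(impacts$subcategory) |
                            impacts$subcategory == ""] <- "uncategorized"
    }
    if (!"comparison" %in% colnames(impacts)) impacts$comparison <- "all"
    roll <- function(keys) {
        agg <- stats::aggregate(impacts[, c("impact", "flux")],
                                by = impacts[keys], FUN = mean)
        names(agg)[names(agg) == "impact"] <- "mean_impact"
        names(agg)[names(agg) == "flux"] <- "mean_flux"
        cnt <- stats::aggregate(list(n_terms = impacts$impact),
                                by = impacts[keys], FUN = length)
        out <- merge(cnt, agg, by = keys, sort = TRUE)
        out[do.call(order, out[keys]), , drop = FALSE]
    }
    list(byCategory = roll(c("comparison", "category")),
         bySubcategory = roll(c("comparison", "category", "subcategory")))
}

#' Top impacted terms across comparisons
#'
#' Ranks terms by their impact averaged over the supplied comparisons
#' (descending, ties by term id) and returns the top `n` with the mean flux
#' sign attached.
#'
#' @param impacts data.frame from [termImpact()] with a `comparison` column
#'   (a single comparison works too).
#' @param n number of terms to return (default 10).
#' @return data.frame `term_id`, `name`, `mean_impact`, `mean_flux`,
#'   `direction`, `rank`.
#' @export
topImpacted <- function(impacts, n = 10L) {
    if (!"comparison" %in% colnames(impacts)) impacts$comparison <- "all"
    agg <- stats::aggregate(impacts[, c("impact", "flux")],
                            by = impacts[c("term_id", "name")], FUN = mean)
    agg <- agg[order(-agg$impact, agg$term_id), , drop = FALSE]
    agg$direction <- ifelse(agg$flux > 0, "activated",
                            ifelse(agg$flux < 0, "inhibited", "none"))
    names(agg)[names(agg) == "impact"] <- "mean_impact"
    names(agg)[names(agg) == "flux"] <- "mean_flux"
    agg$rank <- seq_len(nrow(agg))
    rownames(agg) <- NULL
    utils::head(agg, n)
}
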