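#' Enumerate candidate model profiles
#'
#' All integer temporal templates over `t` timepoints that start at level 0
#' and change by at most `c` units between adjacent timepoints — exactly
#' `(2c+1)^(t-1)` of them. Rows are ordered lexicographically by step vector
#' and carry stable 0-based candidate ids as row names.
#'
#' @param t number of timepoints (>= 2).
#' @param c maximum unit change between adjacent timepoints (>= 1).
#' @return integer matrix (profiles x t) of levels; row names are candidate
#'   ids `"0"`, `"1"`, ...
#' @examples
#' nrow(enumerateProfiles(3, 2))  # 25
#' @export
enumerateProfiles <- function(t, c) {
    if (t < 2) stop("need at least 2 timepoints")
    if (c < 1) stop("max unit change must be >= 1")
    steps <- as.matrix(expand.grid(rep(list(seq.int(-c, c)), t - 1),
                                   KEEP.OUT.ATTRS = FALSE))
    ord <- do.call(order, as.data.frame(steps))
    steps <- steps[ord, , drop = FALSE]
    lv <- cbind(0L, matrixStats_rowCumsum(steps))
    storage.mode(lv) <- "integer"
    dimnames(lv) <- list(as.character(seq_len(nrow(lv)) - 1L),
                         paste0("t", seq_len(t)))
    lv
}

matrixStats_rowCumsum <- function(m) {
    if (ncol(m) == 1L) return(m)
    t(apply(m, 1L, cumsum))
}

#' Distance between two model profiles
#'
#' `1 - Pearson correlation` of the level vectors. Correlation with the flat
#' (zero-variance) profile is undefined; by convention the flat profile is at
#' distance 1 from every non-flat profile and 0 from itself.
#'
#' @param x,y integer level vectors.
#' @export
profileDistance <- function(x, y) {
    fx <- stats::sd(x) == 0
    fy <- stats::sd(y) == 0
    if (fx && fy) return(0)
    if (fx || fy) return(1)
    1 - stats::cor(x, y)
}

#' Select representative model profiles (greedy max-min)
#'
#' Starting from the flat profile, repeatedly adds the candidate whose
#' minimum [profileDistance()] to the already-chosen set is largest, ties
#' broken by lowest candidate id, until `m` profiles are chosen. Selected
#' profiles are renumbered 0..m-1 in candidate-id order; the originating
#' candidate id is kept as an attribute.
#'
#' @param candidates matrix from [enumerateProfiles()].
#' @param m maximum number of model profiles (default 20).
#' @return level matrix of the selected profiles, row names `"0"`..`"m-1"`,
#'   with `attr(, "candidate_id")`.
#' @export
selectModelProfiles <- function(candidates, m = 20L) {
    if (m < 1) stop("m must be >= 1")
    n <- nrow(candidates)
    if (m >= n) {
        out <- candidates
        attr(out, "candidate_id") <- as.integer(rownames(candidates))
        rownames(out) <- as.character(seq_len(n) - 1L)
        return(out)
    }
    D <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, j) profileDistance(candidates[i, ],
                                                        candidates[j, ])))
    flat <- which(apply(candidates, 1L, function(z) all(z == 0L)))
    chosen <- flat
    while (length(chosen) < m) {
        rest <- setdiff(seq_len(n), chosen)
        minD <- apply(D[rest, chosen, drop = FALSE], 1L, min)
        chosen <- c(chosen, rest[which(minD == max(minD))[1L]])  # rest is id-ordered
    }
    chosen <- sort(chosen)
    out <- candidates[chosen, , drop = FALSE]
    attr(out, "candidate_id") <- as.integer(rownames(candidates)[chosen])
    rownames(out) <- as.character(seq_along(chosen) - 1L)
    out
}

# log2 ratio of each stage mean to the first stage; rows anchored at 0
profileTransform <- function(means, pseudocount = 0.125) {
    x <- log2(means + pseudocount)
    if (any(!is.finite(x)))
        stop("undefined transform: zero stage mean with zero pseudocount")
    x - x[, 1L]
}

#' Assign genes to their most-correlated model profile
#'
#' Each gene's stage means are transformed to log2 ratios against the first
#' stage (so every transformed vector starts at 0, matching profile
#' anchoring) and the gene is assigned to the profile with maximal Pearson
#' correlation to its transformed vector. Flat (constant) genes go to the
#' flat profile; the correlation of a non-flat gene with the flat profile is
#' taken as 0. Ties break to the lowest profile id.
#'
#' @param means genes x stages matrix of stage-mean expression.
#' @param profiles level matrix from [selectModelProfiles()] (or
#'   [enumerateProfiles()]).
#' @param pseudocount added to means before the log2 ratio.
#' @return data.frame `gene_id`, `profile_id`, `correlation`.
#' @export
assignProfiles <- function(means, profiles, pseudocount = 0.125) {
    if (nrow(profiles) < 1L) stop("need at least one profile")
    if (is.null(rownames(means)))
        rownames(means) <- paste0("gene", seq_len(nrow(means)))
    x <- profileTransform(means, pseudocount)
    ids <- as.integer(rownames(profiles))
    geneSd <- apply(x, 1L, stats::sd)
    profSd <- apply(profiles, 1L, stats::sd)
    flatProf <- which(profSd == 0)
    cors <- matrix(0, nrow(x), nrow(profiles))
    nonflat <- which(profSd > 0)
    if (length(nonflat) && any(geneSd > 0))
        cors[geneSd > 0, nonflat] <-
            stats::cor(t(x[geneSd > 0, , drop = FALSE]),
                       t(profiles[nonflat, , drop = FALSE]))
    best <- max.col(cors, ties.method = "first")
    corBest <- cors[cbind(seq_len(nrow(x)), best)]
    if (length(flatProf)) {
        best[geneSd == 0] <- flatProf[1L]
        corBest[geneSd == 0] <- 1   # exact match to flat by convention
    } else if (any(geneSd == 0)) {
        corBest[geneSd == 0] <- 0
    }
    data.frame(gene_id = rownames(means), profile_id = ids[best],
               correlation = corBest, stringsAsFactors = FALSE)
}

#' Profile significance by exact stage-order permutation
#'
#' Builds the null by enumerating all t! orderings of the stage columns,
#' re-assigning every gene under each ordering, and averaging per-profile
#' counts to obtain expected counts. Each profile's p-value is the binomial
#' upper tail P(X >= observed) at success probability expected/total, with
#' Bonferroni correction across profiles.
#'
#' @inheritParams assignProfiles
#' @param alpha family-wise significance level for the Bonferroni flag
#'   (default 0.05).
#' @return data.frame `profile_id`, `levels` (comma-joined), `observed`,
#'   `expected`, `p`, `p_bonferroni`, `significant`.
#' @export
profileSignificance <- function(means, profiles, pseudocount = 0.125,
                                alpha = 0.05) {
    t <- ncol(means)
    if (factorial(t) > 720)
        stop("more than 6 timepoints: exact permutation infeasible, ",
             "use a sampling null (not implemented)")
    ids <- as.integer(rownames(profiles))
    observed <- tabulateAssignments(assignProfiles(means, profiles, pseudocount),
                                    ids)
    perms <- permutations_(t)
    expCounts <- rowMeans(vapply(seq_len(nrow(perms)), function(k) {
        tabulateAssignments(assignProfiles(means[, perms[k, ], drop = FALSE],
                                           profiles, pseudocount), ids)
    }, numeric(length(ids))))
    total <- nrow(means)
    p <- stats::pbinom(observed - 1L, total, expCounts / total,
                       lower.tail = FALSE)
    pb <- pmin(1, p * nrow(profiles))
    data.frame(profile_id = ids,
               levels = apply(profiles, 1L, paste, collapse = ","),
               observed = observed, expected = expCounts, p = p,
               p_bonferroni = pb, significant = pb < alpha,
               stringsAsFactors = FALSE, row.names = NULL)
}

tabulateAssignments <- function(assignment, ids) {
    vapply(ids, function(i) sum(assignment$profile_id == i), 0L)
}

permutations_ <- function(t) {
    if (t == 1L) return(matrix(1L, 1L, 1L))
    sub <- permutations_(t - 1L)
    do.call(rbind, lapply(seq_len(t), function(i)
        cbind(i, sub + (sub >= i))))
}

#' Direction of a profile between two timepoints
#'
#' @param levels integer level vector of a profile.
#' @param from,to timepoint indices.
#' @return `"up"`, `"down"` or `"flat"` by the sign of
#'   `levels[to] - levels[from]`.
#' @export
patternDirection <- function(levels, from, to) {
    d <- levels[to] - levels[from]
    if (d > 0) "up" else if (d < 0) "down" else "flat"
}

#' Group significant profiles by correlation (single linkage)
#'
#' Profiles whose pairwise level correlation meets `corThreshold` are linked;
#' connected components among the significant profiles form clusters
#' (the colored profile groups of a short time-series analysis).
#' Non-significant profiles get cluster id `NA`.
#'
#' @param profiles level matrix.
#' @param significant logical vector over profiles.
#' @param corThreshold linking threshold (default 0.7).
#' @return integer cluster ids (1-based within significant profiles).
#' @export
clusterProfiles <- function(profiles, significant, corThreshold = 0.7) {
    n <- nrow(profiles)
    cl <- rep(NA_integer_, n)
    sig <- which(significant)
    if (!length(sig)) return(cl)
    corOf <- function(i, j) 1 - profileDistance(profiles[i, ], profiles[j, ])
    adj <- outer(sig, sig, Vectorize(function(i, j) corOf(i, j) >= corThreshold))
    comp <- rep(0L, length(sig)); cur <- 0L
    for (s in seq_along(sig)) {
        if (comp[s] == 0L) {
            cur <- cur + 1L
            queue <- s
            while (length(queue)) {
                v <- queue[[1L]]; queue <- queue[-1L]
                if (comp[v] == 0L) {
                    comp[v] <- cur
                    queue <- c(queue, which(adj[v, ] & comp == 0L))
                }
            }
        }
    }
    cl[sig] <- comp
    cl
}
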