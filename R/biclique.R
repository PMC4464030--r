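#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Per-direction degree statistics of the reliable interaction graph
#'
#' Summaries of the beta-thresholded bipartite graph that drive biclique
#' aggregation. For the miRNA-to-mRNA direction: \code{min_own} /
#' \code{abs_min_own} are the outlier-proof and absolute minimum number of
#' mRNAs targeted by each miRNA with score > beta, and \code{avg_opposite} is
#' the average number of miRNAs targeting each mRNA. The mRNA-to-miRNA
#' direction swaps the roles.
#'
#' @slot avg_opposite average degree of the opposite-side objects.
#' @slot min_own outlier-proof minimum seed degree (lowest 0.15\% of values
#'   discarded under a Gaussian degree assumption).
#' @slot abs_min_own absolute (untrimmed) minimum seed degree.
#' @slot direction \code{"mirna_to_mrna"} or \code{"mrna_to_mirna"}.
#' @slot beta the reliability threshold the statistics were computed at.
#' @export
setClass("DirectionStats", representation(
    avg_opposite = "numeric", min_own = "integer", abs_min_own = "integer",
    direction = "character", beta = "numeric"))

setValidity("DirectionStats", function(object) {
    msg <- character()
    if (object@abs_min_own > object@min_own)
        msg <- c(msg, "abs_min_own must be <= min_own")
    if (object@avg_opposite < 0) msg <- c(msg, "avg_opposite must be >= 0")
    if (!object@direction %in% c("mirna_to_mrna", "mrna_to_mirna"))
        msg <- c(msg, "unknown direction")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DirectionStats", function(object) {
    cat(sprintf(
        "DirectionStats (%s, beta = %.2f): avg_opposite = %.2f, min_own = %d, abs_min_own = %d\n",
        object@direction, object@beta, object@avg_opposite, object@min_own,
        object@abs_min_own))
})

## mean score over the |Cr| x |Cc| block (absent cells count 0)
.blockMean <- function(A, genes, mirnas) {
    sum(A@scores[mirnas, genes, drop = FALSE]) /
        (length(genes) * length(mirnas))
}

#' Compactness (cohesiveness) of a bicluster
#'
#' q(C, A): the sum of interaction scores over all cells of the bicluster
#' block, normalized by the maximum number of possible interactions
#' |Cr| x |Cc| -- i.e. the mean score over the block, with absent interactions
#' counting 0.
#'
#' @param C a [Bicluster-class] (or a list with \code{genes} and
#'   \code{mirnas} character vectors).
#' @param A an [InteractionMatrix-class] whose indices contain all members.
#' @return q in \[0, 1\].
#' @export
compactness <- function(C, A) {
    stopifnot(is(A, "InteractionMatrix"))
    g <- if (is(C, "Bicluster")) C@genes else C$genes
    m <- if (is(C, "Bicluster")) C@mirnas else C$mirnas
    if (length(g) == 0 || length(m) == 0)
        stop("bicluster has an empty dimension")
    if (!all(g %in% genes(A)) || !all(m %in% mirnas(A)))
        stop("bicluster member absent from the interaction matrix")
    .blockMean(A, g, m)
}

#' Jaccard similarity of two sets
#'
#' @param S1,S2 vectors treated as sets; their union must be non-empty.
#' @return |S1 intersect S2| / |S1 union S2|.
#' @export
jaccardIndex <- function(S1, S2) {
    S1 <- unique(S1); S2 <- unique(S2)
    u <- length(union(S1, S2))
    if (u == 0) stop("both sets are empty")
    length(intersect(S1, S2)) / u
}

#' Degree statistics of the thresholded graph in one direction
#'
#' Interactions with score strictly greater than \code{beta} are retained;
#' degrees are computed on objects with at least one retained interaction.
#' The outlier-proof minimum discards the \code{floor(0.0015 * n)} smallest
#' seed degrees (the lowest 0.15\%, per the 3-sigma rule under a Gaussian
#' degree assumption) before taking the minimum; with small n no trimming
#' occurs.
#'
#' @param A an [InteractionMatrix-class].
#' @param beta reliability threshold in \[0, 1\].
#' @param direction \code{"mirna_to_mrna"} (seeds are miRNAs) or
#'   \code{"mrna_to_mirna"} (seeds are mRNAs).
#' @return a [DirectionStats-class].
#' @export
directionStats <- function(A, beta,
                           direction = c("mirna_to_mrna", "mrna_to_mirna")) {
    direction <- match.arg(direction)
    stopifnot(is(A, "InteractionMatrix"))
    thr <- A@scores > beta
    if (!any(thr)) stop("empty reliable graph: no score above beta")
    rdeg <- Matrix::rowSums(thr)
    cdeg <- Matrix::colSums(thr)
    own <- if (direction == "mirna_to_mrna") rdeg else cdeg
    opp <- if (direction == "mirna_to_mrna") cdeg else rdeg
    own <- own[own > 0]
    opp <- opp[opp > 0]
    n <- length(own)
    drop_n <- floor(0.0015 * n)
    trimmed <- sort(own)[(drop_n + 1L):n]
    methods::new("DirectionStats",
                 avg_opposite = mean(opp),
                 min_own = as.integer(min(trimmed)),
                 abs_min_own = as.integer(min(own)),
                 direction = direction, beta = beta)
}

.newBicluster <- function(id, genes, mirnas, A, level = 1L) {
    genes <- sort(unique(genes)); mirnas <- sort(unique(mirnas))
    methods::new("Bicluster", id = id, genes = genes, mirnas = mirnas,
                 level = as.integer(level),
                 compactness = .blockMean(A, genes, mirnas))
}

#' Initial single-seed bicliques
#'
#' One biclique per seed object with at least one retained (score > beta)
#' interaction: the seed together with all its beta-reliable partners. Ids
#' are sequential integers (as strings), assigned in lexicographic seed
#' order, starting after \code{id_offset}.
#'
#' @inheritParams directionStats
#' @param id_offset integer added to the sequential ids (used to keep ids
#'   unique when both directions are extracted).
#' @return list of [Bicluster-class] objects.
#' @export
initialBicliques <- function(A, beta,
                             direction = c("mirna_to_mrna", "mrna_to_mirna"),
                             id_offset = 0L) {
    direction <- match.arg(direction)
    thr <- A@scores > beta
    seeds <- if (direction == "mirna_to_mrna") {
        keep <- Matrix::rowSums(thr) > 0
        sort(rownames(thr)[keep])
    } else {
        keep <- Matrix::colSums(thr) > 0
        sort(colnames(thr)[keep])
    }
    out <- vector("list", length(seeds))
    for (i in seq_along(seeds)) {
        s <- seeds[i]
        if (direction == "mirna_to_mrna") {
            partners <- colnames(thr)[thr[s, ]]
            out[[i]] <- .newBicluster(as.character(i + id_offset),
                                      partners, s, A)
        } else {
            partners <- rownames(thr)[thr[, s]]
            out[[i]] <- .newBicluster(as.character(i + id_offset),
                                      s, partners, A)
        }
    }
    out
}

## aggregate of two bicliques: intersect on the non-seed dimension, union on
## the seed dimension (for mirna_to_mrna: Cr'" = Cr' n Cr", Cc'" = Cc' u Cc")
.aggregatePair <- function(b1, b2, direction) {
    if (direction == "mirna_to_mrna")
        list(genes = intersect(b1@genes, b2@genes),
             mirnas = union(b1@mirnas, b2@mirnas))
    else
        list(genes = union(b1@genes, b2@genes),
             mirnas = intersect(b1@mirnas, b2@mirnas))
}

## admissibility + objective for one candidate pair; NULL if inadmissible
.pairObjective <- function(b1, b2, stats, A) {
    direction <- stats@direction
    agg <- .aggregatePair(b1, b2, direction)
    inter_dim <- if (direction == "mirna_to_mrna") agg$genes else agg$mirnas
    union_dim <- if (direction == "mirna_to_mrna") agg$mirnas else agg$genes
    if (length(inter_dim) < stats@min_own) return(NULL)
    if (length(union_dim) > stats@avg_opposite) return(NULL)
    jac <- if (direction == "mirna_to_mrna")
        jaccardIndex(b1@genes, b2@genes)
    else jaccardIndex(b1@mirnas, b2@mirnas)
    q <- .blockMean(A, agg$genes, agg$mirnas)
    list(objective = jac * q, agg = agg)
}

#' Greedy aggregation of bicliques
#'
#' Repeatedly aggregates the admissible pair maximizing jaccard x q: the
#' Jaccard similarity of the two bicliques on the intersected dimension times
#' the compactness of the aggregate. A pair is admissible when the aggregate
#' keeps at least \code{min_own} members on the intersected dimension and at
#' most \code{avg_opposite} members on the united dimension. Ties are broken
#' by the lexicographically smallest joined id; the aggregate's id joins the
#' founders' ids with \code{"_"}. Stops when no admissible pair remains.
#'
#' @param bicliques list of [Bicluster-class] objects (one direction).
#' @param stats the [DirectionStats-class] for the same direction and beta.
#' @param A the [InteractionMatrix-class].
#' @param trace when \code{TRUE}, attach attribute \code{"trace"}: one row per
#'   greedy step with the chosen pair and its objective.
#' @return list of [Bicluster-class] objects after aggregation, sorted by id.
#' @export
aggregateBicliques <- function(bicliques, stats, A, trace = FALSE) {
    stopifnot(is(stats, "DirectionStats"))
    pool <- bicliques
    names(pool) <- vapply(pool, biclusterId, "")
    pool <- pool[order(names(pool))]
    steps <- list()

    score_against <- function(id, others) {
        res <- list()
        for (oid in others) {
            po <- .pairObjective(pool[[id]], pool[[oid]], stats, A)
            if (!is.null(po))
                res[[.joinIds(id, oid)]] <-
                    list(id1 = id, id2 = oid, objective = po$objective,
                         agg = po$agg)
        }
        res
    }

    ids <- names(pool)
    cand <- list()
    if (length(ids) > 1)
        for (i in seq_len(length(ids) - 1L))
            cand <- c(cand, score_against(ids[i], ids[(i + 1L):length(ids)]))

    while (length(cand) > 0) {
        obj <- vapply(cand, `[[`, 0, "objective")
        best <- which(obj == max(obj))
        pick <- best[order(names(cand)[best])][1L]
        ch <- cand[[pick]]
        new_id <- .joinIds(ch$id1, ch$id2)
        if (trace)
            steps[[length(steps) + 1L]] <-
                data.frame(id1 = ch$id1, id2 = ch$id2,
                           objective = ch$objective,
                           stringsAsFactors = FALSE)
        pool[[ch$id1]] <- NULL
        pool[[ch$id2]] <- NULL
        agg <- .newBicluster(new_id, ch$agg$genes, ch$agg$mirnas, A)
        ## drop stale candidates, score the aggregate against survivors
        stale <- vapply(cand, function(x)
            x$id1 %in% c(ch$id1, ch$id2) || x$id2 %in% c(ch$id1, ch$id2),
            logical(1))
        cand <- cand[!stale]
        pool[[new_id]] <- agg
        cand <- c(cand, score_against(new_id, setdiff(names(pool), new_id)))
    }
    out <- pool[order(names(pool))]
    out <- unname(out)
    if (trace)
        attr(out, "trace") <- if (length(steps)) do.call(rbind, steps)
                              else data.frame(id1 = character(),
                                              id2 = character(),
                                              objective = numeric())
    out
}

#' Prune undersized bicliques and report isolated objects
#'
#' Bicliques with fewer than \code{abs_min_mirna} miRNAs or fewer than
#' \code{abs_min_mrna} mRNAs are removed. Objects that appear in no kept
#' biclique are reported as isolated/noise.
#'
#' @param bicliques list of [Bicluster-class] objects.
#' @param abs_min_mirna,abs_min_mrna absolute size thresholds (>= 1).
#' @param universe_mirnas,universe_genes the object universe for the isolated
#'   report; defaults to all objects covered by the input bicliques.
#' @return list with \code{kept} (biclusters) and \code{isolated} (list of
#'   \code{mirnas} and \code{genes}).
#' @export
pruneBicliques <- function(bicliques, abs_min_mirna, abs_min_mrna,
                           universe_mirnas = NULL, universe_genes = NULL) {
    stopifnot(abs_min_mirna >= 1, abs_min_mrna >= 1)
    if (is.null(universe_mirnas))
        universe_mirnas <- sort(unique(unlist(lapply(bicliques, mirnas))))
    if (is.null(universe_genes))
        universe_genes <- sort(unique(unlist(lapply(bicliques, genes))))
    keep <- vapply(bicliques, function(b)
        length(b@mirnas) >= abs_min_mirna && length(b@genes) >= abs_min_mrna,
        logical(1))
    kept <- bicliques[keep]
    cov_m <- unique(unlist(lapply(kept, mirnas)))
    cov_g <- unique(unlist(lapply(kept, genes)))
    list(kept = kept,
         isolated = list(mirnas = setdiff(universe_mirnas, cov_m),
                         genes = setdiff(universe_genes, cov_g)))
}

#' Merge the biclique sets of the two directions
#'
#' Union of both sets with exact duplicates (identical gene set and identical
#' miRNA set) collapsed to a single biclique whose id joins the ids of the
#' collapsed pair.
#'
#' @param set1,set2 lists of [Bicluster-class] objects from the same matrix
#'   and beta.
#' @return combined list, sorted by id.
#' @export
mergeDirections <- function(set1, set2) {
    all <- c(set1, set2)
    if (length(all) == 0) return(list())
    sig <- vapply(all, function(b)
        paste(paste(b@genes, collapse = ","),
              paste(b@mirnas, collapse = ","), sep = "||"), "")
    out <- list()
    for (s in unique(sig)) {
        grp <- all[sig == s]
        b <- grp[[1L]]
        if (length(grp) > 1)
            b@id <- paste(sort(vapply(grp, biclusterId, "")), collapse = "_")
        out[[length(out) + 1L]] <- b
    }
    out[order(vapply(out, biclusterId, ""))]
}

#' Step 1: extract, aggregate, prune and merge bicliques
#'
#' Runs the full first step on the beta-thresholded interaction graph:
#' direction statistics, initial single-seed bicliques, greedy jaccard x q
#' aggregation in each requested direction, pruning against the absolute
#' minimum sizes, and the merge of the two directions.
#'
#' @param A an [InteractionMatrix-class].
#' @param beta reliability threshold in \[0, 1\].
#' @param direction \code{"both"} (default), \code{"mirna_to_mrna"} or
#'   \code{"mrna_to_mirna"}.
#' @return list with \code{bicliques}, \code{isolated} (objects of A in no
#'   kept biclique) and \code{stats} (per-direction [DirectionStats-class]).
#' @export
extractBicliques <- function(A, beta, direction = "both") {
    stopifnot(is(A, "InteractionMatrix"))
    st_m <- directionStats(A, beta, "mirna_to_mrna")
    st_g <- directionStats(A, beta, "mrna_to_mirna")
    sets <- list()
    offset <- 0L
    if (direction %in% c("both", "mirna_to_mrna")) {
        ini <- initialBicliques(A, beta, "mirna_to_mrna", id_offset = offset)
        offset <- offset + length(ini)
        sets$m2g <- aggregateBicliques(ini, st_m, A)
    }
    if (direction %in% c("both", "mrna_to_mirna")) {
        ini <- initialBicliques(A, beta, "mrna_to_mirna", id_offset = offset)
        sets$g2m <- aggregateBicliques(ini, st_g, A)
    }
    merged <- if (length(sets) == 2) mergeDirections(sets$m2g, sets$g2m)
              else sets[[1L]]
    pr <- pruneBicliques(merged,
                         abs_min_mirna = st_g@abs_min_own,
                         abs_min_mrna = st_m@abs_min_own,
                         universe_mirnas = mirnas(A),
                         universe_genes = genes(A))
    list(bicliques = pr$kept, isolated = pr$isolated,
         stats = list(mirna_to_mrna = st_m, mrna_to_mirna = st_g))
}
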