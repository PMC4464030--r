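#' @include AllClasses.R AllGenerics.R biclique.R
NULL

#' Score-profile embeddings of miRNAs or genes
#'
#' Coordinates used by overlap detection and merge-candidate search: a miRNA
#' is embedded as its score vector over all genes (its row of A), a gene as
#' its score vector over all miRNAs (its column). Absent interactions give 0.
#'
#' @param A an [InteractionMatrix-class].
#' @param dimension \code{"mirna"} or \code{"gene"}.
#' @return dense numeric matrix, one row per object, rownames = object ids.
#' @export
embedObjects <- function(A, dimension = c("mirna", "gene")) {
    dimension <- match.arg(dimension)
    m <- as.matrix(A@scores)
    if (dimension == "mirna") m else t(m)
}

## both embeddings at once (the hierarchy functions need both dimensions)
.embeddings <- function(A) {
    list(mirna = embedObjects(A, "mirna"), gene = embedObjects(A, "gene"))
}

## Misclassified exclusive members of one dimension of a bicluster pair.
## Returns a list(add1 = members to add to b1, add2 = ...), or NULL when the
## dimension has no exclusive member on one side or the separator cannot be
## trained (degenerate coordinates).
.overlapDimension <- function(mem1, mem2, emb, cost = 1) {
    ex1 <- setdiff(mem1, mem2)
    ex2 <- setdiff(mem2, mem1)
    if (length(ex1) == 0 || length(ex2) == 0) return(NULL)
    x <- emb[c(ex1, ex2), , drop = FALSE]
    y <- factor(rep(c("a", "b"), c(length(ex1), length(ex2))),
                levels = c("a", "b"))
    fit <- tryCatch(
        e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE),
        error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    pred <- tryCatch(stats::predict(fit, x), error = function(e) NULL)
    if (is.null(pred)) return(NULL)
    mis <- pred != y
    list(add1 = c(ex1, ex2)[mis & y == "b"],   # b's members classified as a
         add2 = c(ex1, ex2)[mis & y == "a"])   # a's members classified as b
}

#' Detect overlap between two biclusters via separating hyperplanes
#'
#' For each dimension (genes, miRNAs), a linear max-margin classifier is
#' trained on the exclusive members of the two biclusters (shared members are
#' excluded) and applied back to the same members. A misclassified object
#' possibly belongs to both biclusters and is added to the one that did not
#' previously contain it; members are never removed. A dimension with no
#' exclusive member on one side is skipped.
#'
#' @param C1,C2 distinct [Bicluster-class] objects from the same level.
#' @param A the [InteractionMatrix-class] (used to refresh compactness).
#' @param embeddings optional result of the internal embedding step; computed
#'   from \code{A} when missing.
#' @param cost SVM regularization constant (default 1).
#' @return list with updated \code{C1}, \code{C2} and the raw \code{additions}
#'   (per bicluster, per dimension).
#' @export
detectOverlapPair <- function(C1, C2, A, embeddings = NULL, cost = 1) {
    stopifnot(is(C1, "Bicluster"), is(C2, "Bicluster"))
    if (identical(C1@id, C2@id) ||
        (setequal(C1@genes, C2@genes) && setequal(C1@mirnas, C2@mirnas)))
        stop("overlap detection needs two distinct biclusters")
    if (is.null(embeddings)) embeddings <- .embeddings(A)
    gdim <- .overlapDimension(C1@genes, C2@genes, embeddings$gene, cost)
    mdim <- .overlapDimension(C1@mirnas, C2@mirnas, embeddings$mirna, cost)
    add1g <- gdim$add1 %||% character(); add2g <- gdim$add2 %||% character()
    add1m <- mdim$add1 %||% character(); add2m <- mdim$add2 %||% character()
    if (length(add1g) || length(add1m))
        C1 <- .newBicluster(C1@id, union(C1@genes, add1g),
                            union(C1@mirnas, add1m), A, C1@level)
    if (length(add2g) || length(add2m))
        C2 <- .newBicluster(C2@id, union(C2@genes, add2g),
                            union(C2@mirnas, add2m), A, C2@level)
    list(C1 = C1, C2 = C2,
         additions = list(C1 = list(genes = add1g, mirnas = add1m),
                          C2 = list(genes = add2g, mirnas = add2m)))
}

#' One overlap-augmentation pass over a level
#'
#' Applies [detectOverlapPair()] to every unordered pair of biclusters at the
#' level (pairs visited in lexicographic id order) with batch semantics: all
#' additions are collected first and applied together at the end of the pass,
#' so the outcome does not depend on the pair ordering.
#'
#' @param level list of [Bicluster-class] objects.
#' @param A the [InteractionMatrix-class].
#' @param embeddings optional precomputed embeddings.
#' @param cost SVM regularization constant.
#' @return the augmented level (members only ever grow).
#' @export
overlapPass <- function(level, A, embeddings = NULL, cost = 1) {
    if (length(level) < 2) return(level)
    if (is.null(embeddings)) embeddings <- .embeddings(A)
    ids <- vapply(level, biclusterId, "")
    level <- level[order(ids)]
    ids <- sort(ids)
    addg <- stats::setNames(rep(list(character()), length(level)), ids)
    addm <- addg
    for (i in seq_len(length(level) - 1L)) {
        for (j in (i + 1L):length(level)) {
            b1 <- level[[i]]; b2 <- level[[j]]
            if (setequal(b1@genes, b2@genes) &&
                setequal(b1@mirnas, b2@mirnas)) next
            gdim <- .overlapDimension(b1@genes, b2@genes, embeddings$gene,
                                      cost)
            mdim <- .overlapDimension(b1@mirnas, b2@mirnas, embeddings$mirna,
                                      cost)
            addg[[i]] <- c(addg[[i]], gdim$add1 %||% character())
            addg[[j]] <- c(addg[[j]], gdim$add2 %||% character())
            addm[[i]] <- c(addm[[i]], mdim$add1 %||% character())
            addm[[j]] <- c(addm[[j]], mdim$add2 %||% character())
        }
    }
    out <- vector("list", length(level))
    for (i in seq_along(level)) {
        b <- level[[i]]
        if (length(addg[[i]]) || length(addm[[i]]))
            b <- .newBicluster(b@id, union(b@genes, addg[[i]]),
                               union(b@mirnas, addm[[i]]), A, b@level)
        out[[i]] <- b
    }
    out
}

## centroid and RMS radius of a member set in one embedding
.clusterGeometry <- function(members, emb) {
    x <- emb[members, , drop = FALSE]
    ctr <- colMeans(x)
    d2 <- rowSums(sweep(x, 2, ctr)^2)
    list(centroid = ctr, sigma = sqrt(mean(d2)))
}

#' Merge-candidate pairs at a level
#'
#' Two biclusters are candidates for merging when they are close on at least
#' one dimension: dist(C', C'') - 2 sigma(C') - 2 sigma(C'') <= 0, where dist
#' is the Euclidean distance between the member centroids in the score-profile
#' embedding and sigma is the RMS distance of members to their centroid.
#'
#' @param level list of at least two [Bicluster-class] objects.
#' @param A the [InteractionMatrix-class].
#' @param embeddings optional precomputed embeddings.
#' @return data.frame with columns \code{id1}, \code{id2} (id1 < id2), one row
#'   per candidate pair.
#' @export
mergeCandidates <- function(level, A, embeddings = NULL) {
    if (length(level) < 2)
        return(data.frame(id1 = character(), id2 = character(),
                          stringsAsFactors = FALSE))
    if (is.null(embeddings)) embeddings <- .embeddings(A)
    ids <- vapply(level, biclusterId, "")
    o <- order(ids)
    level <- level[o]; ids <- ids[o]
    geo_g <- lapply(level, function(b)
        .clusterGeometry(b@genes, embeddings$gene))
    geo_m <- lapply(level, function(b)
        .clusterGeometry(b@mirnas, embeddings$mirna))
    res <- list()
    for (i in seq_len(length(level) - 1L)) {
        for (j in (i + 1L):length(level)) {
            close_g <- {
                d <- sqrt(sum((geo_g[[i]]$centroid -
                               geo_g[[j]]$centroid)^2))
                d - 2 * geo_g[[i]]$sigma - 2 * geo_g[[j]]$sigma <= 0
            }
            close_m <- {
                d <- sqrt(sum((geo_m[[i]]$centroid -
                               geo_m[[j]]$centroid)^2))
                d - 2 * geo_m[[i]]$sigma - 2 * geo_m[[j]]$sigma <= 0
            }
            if (close_g || close_m)
                res[[length(res) + 1L]] <- c(ids[i], ids[j])
        }
    }
    if (length(res) == 0)
        return(data.frame(id1 = character(), id2 = character(),
                          stringsAsFactors = FALSE))
    m <- do.call(rbind, res)
    data.frame(id1 = m[, 1], id2 = m[, 2], stringsAsFactors = FALSE)
}

#' Merge close biclusters under the quality constraint
#'
#' Candidate pairs (see [mergeCandidates()]) whose union bicluster satisfies
#' q(union, A) > alpha are merged, each bicluster participating in at most one
#' merge: when a bicluster belongs to several passing pairs, only the merge
#' with maximum union compactness is executed (ties broken by the
#' lexicographically smallest joined id). Merged pairs produce one parent at
#' the next level with both biclusters as children; unmerged biclusters are
#' copied upward unchanged with a self parent link.
#'
#' @param level list of [Bicluster-class] objects at the current level.
#' @param A the [InteractionMatrix-class].
#' @param alpha compactness threshold in \[0, 1\] (strict: q must exceed it).
#' @param embeddings optional precomputed embeddings.
#' @return list with \code{next_level} (biclusters at level + 1),
#'   \code{parents} (named character: child key \code{"<level>:<id>"} ->
#'   parent key), \code{mergeQ} (named numeric: parent key -> union q at merge
#'   time) and \code{n_merges}.
#' @export
mergeLevel <- function(level, A, alpha, embeddings = NULL) {
    stopifnot(alpha >= 0, alpha <= 1)
    if (is.null(embeddings)) embeddings <- .embeddings(A)
    ids <- vapply(level, biclusterId, "")
    names(level) <- ids
    lvl <- level[[1L]]@level
    cand <- mergeCandidates(level, A, embeddings)
    passing <- list()
    if (nrow(cand)) {
        for (r in seq_len(nrow(cand))) {
            b1 <- level[[cand$id1[r]]]; b2 <- level[[cand$id2[r]]]
            q <- .blockMean(A, union(b1@genes, b2@genes),
                            union(b1@mirnas, b2@mirnas))
            if (q > alpha)
                passing[[length(passing) + 1L]] <-
                    list(id1 = cand$id1[r], id2 = cand$id2[r], q = q,
                         joined = .joinIds(cand$id1[r], cand$id2[r]))
        }
    }
    used <- character()
    next_level <- list()
    parents <- character()
    mergeQ <- numeric()
    n_merges <- 0L
    if (length(passing)) {
        qs <- vapply(passing, `[[`, 0, "q")
        jn <- vapply(passing, `[[`, "", "joined")
        for (k in order(-qs, jn)) {
            p <- passing[[k]]
            if (p$id1 %in% used || p$id2 %in% used) next
            used <- c(used, p$id1, p$id2)
            b1 <- level[[p$id1]]; b2 <- level[[p$id2]]
            parent <- .newBicluster(p$joined,
                                    union(b1@genes, b2@genes),
                                    union(b1@mirnas, b2@mirnas),
                                    A, lvl + 1L)
            next_level[[length(next_level) + 1L]] <- parent
            pk <- paste0(lvl + 1L, ":", p$joined)
            parents[paste0(lvl, ":", p$id1)] <- pk
            parents[paste0(lvl, ":", p$id2)] <- pk
            mergeQ[pk] <- p$q
            n_merges <- n_merges + 1L
        }
    }
    for (id in setdiff(ids, used)) {
        b <- level[[id]]
        b@level <- lvl + 1L
        next_level[[length(next_level) + 1L]] <- b
        parents[paste0(lvl, ":", id)] <- paste0(lvl + 1L, ":", id)
    }
    next_level <-
        next_level[order(vapply(next_level, biclusterId, ""))]
    list(next_level = next_level, parents = parents, mergeQ = mergeQ,
         n_merges = n_merges)
}

#' Build the hierarchy of overlapping biclusters
#'
#' Iterates the overlap-and-merge step level by level: one overlap-augmentation pass over
#' all bicluster pairs, then one quality-constrained merge pass; the merged
#' level becomes the next level and the iteration stops when no merge occurred
#' or \code{max_levels} is reached. Level 1 is the step-1 output after the
#' first overlap pass; every level is a complete clustering because unmerged
#' biclusters are copied upward.
#'
#' @param step1_bicliques non-empty list of [Bicluster-class] objects from
#'   [extractBicliques()].
#' @param A the [InteractionMatrix-class].
#' @param alpha merge quality threshold in \[0, 1\].
#' @param beta the step-1 threshold (recorded in the hierarchy).
#' @param max_levels maximum number of levels (default 10).
#' @param cost SVM regularization constant for overlap detection.
#' @return a [Hierarchy-class].
#' @export
buildHierarchy <- function(step1_bicliques, A, alpha, beta = NA_real_,
                           max_levels = 10, cost = 1) {
    if (max_levels < 1) stop("max_levels must be >= 1")
    if (length(step1_bicliques) == 0) stop("no step-1 biclusters")
    emb <- .embeddings(A)
    cur <- lapply(step1_bicliques, function(b) {
        b@level <- 1L
        b
    })
    levels <- list()
    parents <- character()
    mergeQ <- numeric()
    for (l in seq_len(max_levels)) {
        cur <- overlapPass(cur, A, emb, cost)
        levels[[l]] <- cur
        if (l == max_levels) break
        mg <- mergeLevel(cur, A, alpha, emb)
        if (mg$n_merges == 0L) break
        parents <- c(parents, mg$parents)
        mergeQ <- c(mergeQ, mg$mergeQ)
        cur <- mg$next_level
    }
    methods::new("Hierarchy", levels = levels, parents = parents,
                 mergeQ = mergeQ, alpha = alpha, beta = beta)
}

#' Number of levels of a hierarchy
#' @param x a [Hierarchy-class].
#' @return integer level count.
#' @export
nLevels <- function(x) {
    stopifnot(is(x, "Hierarchy"))
    length(x@levels)
}
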