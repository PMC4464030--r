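#' @include AllClasses.R AllGenerics.R ontology.R utils.R
NULL

#' SimGIC semantic similarity of two genes
#'
#' IC-weighted Jaccard of the genes' (ancestor-closed) GO term sets:
#' the sum of IC over the intersection divided by the sum over the union.
#'
#' @param g1,g2 gene symbols.
#' @param store an [AnnotationStore-class].
#' @return similarity in \[0, 1\]; \code{NA} (undefined) when either gene is
#'   unannotated or the union carries zero total information content --
#'   undefined values are excluded from similarity samples, never scored 0.
#' @export
simgic <- function(g1, g2, store) {
    t1 <- store@closed[[g1]]
    t2 <- store@closed[[g2]]
    if (is.null(t1) || is.null(t2)) return(NA_real_)
    ic <- store@ic
    den <- sum(ic[union(t1, t2)], na.rm = TRUE)
    if (den == 0) return(NA_real_)
    sum(ic[intersect(t1, t2)], na.rm = TRUE) / den
}

#' Pairwise SimGIC matrix
#'
#' Computes all pairwise similarities among a set of genes with one sparse
#' cross-product (gene x term incidence weighted by IC).
#'
#' @param store an [AnnotationStore-class].
#' @param genes genes to include; default all annotated genes. Unannotated
#'   genes are dropped.
#' @return symmetric matrix of similarities; entries are \code{NA} where
#'   undefined (zero total IC).
#' @export
simgicMatrix <- function(store, genes = names(store@closed)) {
    genes <- intersect(genes, names(store@closed))
    terms <- names(store@ic)
    tri <- lapply(store@closed[genes], function(ts) match(ts, terms))
    lens <- vapply(tri, length, 0L)
    G <- Matrix::sparseMatrix(
        i = rep(seq_along(genes), lens),
        j = unlist(tri, use.names = FALSE),
        x = 1, dims = c(length(genes), length(terms)),
        dimnames = list(genes, terms))
    W <- G %*% Matrix::Diagonal(x = store@ic)
    inter <- as.matrix(W %*% Matrix::t(G))
    icsum <- Matrix::rowSums(W)
    uni <- outer(icsum, icsum, "+") - inter
    S <- inter / uni
    S[uni == 0] <- NA_real_
    dimnames(S) <- list(genes, genes)
    S
}

## all (or a uniform seeded subsample of) unordered pairs from 1..n
.samplePairs <- function(n, cap, rng) {
    total <- n * (n - 1) / 2
    if (total <= 0) return(cbind(integer(), integer()))
    ks <- if (total <= cap) seq_len(total)
          else sort(.rngSampleInt(rng, total, cap, replace = FALSE))
    csum <- cumsum((n - 1):0)            # pairs with first index <= i
    i <- findInterval(ks - 1L, csum) + 1L
    j <- i + (ks - c(0, csum)[i])
    cbind(i, j)
}

## uniform seeded subsample of a rectangular index grid
.sampleGrid <- function(n1, n2, cap, rng) {
    total <- n1 * n2
    if (total == 0) return(cbind(integer(), integer()))
    ks <- if (total <= cap) seq_len(total)
          else sort(.rngSampleInt(rng, total, cap, replace = FALSE))
    cbind((ks - 1L) %% n1 + 1L, (ks - 1L) %/% n1 + 1L)
}

#' Intra- and inter-bicluster similarity samples
#'
#' The intra sample holds SimGIC values over unordered gene pairs within the
#' bicluster; the inter sample pairs each gene of the bicluster with genes
#' belonging to other biclusters of the same level (and not to the
#' bicluster). Samples larger than \code{cap} pairs are uniformly subsampled
#' (seeded); undefined similarities are dropped.
#'
#' @param C a [Bicluster-class], member of \code{level}.
#' @param level list of [Bicluster-class] at the same hierarchy level.
#' @param store an [AnnotationStore-class].
#' @param cap maximum pairs per sample (default 2000).
#' @param seed integer seed for the subsampling.
#' @param S optional precomputed [simgicMatrix()] covering the level's genes.
#' @return list with numeric vectors \code{intra} and \code{inter} (either
#'   may be empty when fewer than two annotated genes or no other bicluster
#'   exists).
#' @export
similaritySamples <- function(C, level, store, cap = 2000, seed = 1,
                              S = NULL) {
    ann <- intersect(C@genes, names(store@closed))
    others <- setdiff(
        unique(unlist(lapply(level, function(b)
            if (identical(b@id, C@id)) character() else b@genes))),
        C@genes)
    others <- intersect(others, names(store@closed))
    if (is.null(S))
        S <- simgicMatrix(store, union(ann, others))
    rng <- .seededRNG(seed)
    intra <- if (length(ann) >= 2) {
        pr <- .samplePairs(length(ann), cap, rng)
        S[cbind(match(ann, rownames(S))[pr[, 1]],
                match(ann, rownames(S))[pr[, 2]])]
    } else numeric()
    inter <- if (length(ann) >= 1 && length(others) >= 1) {
        pr <- .sampleGrid(length(ann), length(others), cap, rng)
        S[cbind(match(ann, rownames(S))[pr[, 1]],
                match(others, rownames(S))[pr[, 2]])]
    } else numeric()
    list(intra = as.numeric(intra[!is.na(intra)]),
         inter = as.numeric(inter[!is.na(inter)]))
}

## one-tailed Welch test of H1: mean(intra) > mean(inter)
.coherencePValue <- function(intra, inter) {
    if (length(intra) < 2 || length(inter) < 2) return(1)
    if (stats::sd(intra) == 0 && stats::sd(inter) == 0) {
        if (mean(intra) > mean(inter)) return(0)
        return(1)
    }
    out <- tryCatch(
        stats::t.test(intra, inter, alternative = "greater",
                      var.equal = FALSE)$p.value,
        error = function(e) NA_real_)
    if (is.na(out)) {
        if (mean(intra) > mean(inter)) return(0)
        return(1)
    }
    out
}

#' Rank the biclusters of one hierarchy level by functional coherence
#'
#' For every bicluster and each provided ontology namespace, tests H0:
#' mu0(C) = mu(L, C) against H1: mu0(C) > mu(L, C) with a one-tailed Welch
#' two-sample t-test on the intra vs inter SimGIC samples: the lower the
#' p-value, the more functionally coherent the bicluster relative to its
#' level. A bicluster with fewer than two values in either sample gets p = 1.
#'
#' @param level list of [Bicluster-class] objects.
#' @param store_bp [AnnotationStore-class] for Biological Process.
#' @param store_mf optional [AnnotationStore-class] for Molecular Function;
#'   when \code{NULL}, \code{p_mf} is \code{NA}.
#' @param cap maximum pairs per similarity sample.
#' @param seed integer seed for pair subsampling.
#' @return data.frame sorted ascending by (\code{p_bp}, \code{id}) with
#'   columns \code{id}, \code{level}, \code{compactness}, \code{p_bp},
#'   \code{p_mf}, \code{mu0_bp}, \code{mu_inter_bp}, \code{mu0_mf},
#'   \code{mu_inter_mf}, \code{n_annotated}, \code{n_genes}, \code{n_mirnas}.
#' @export
rankLevel <- function(level, store_bp, store_mf = NULL, cap = 2000,
                      seed = 1) {
    stopifnot(length(level) >= 1)
    level <- level[order(vapply(level, biclusterId, ""))]
    lvl_genes <- unique(unlist(lapply(level, genes)))
    S_bp <- simgicMatrix(store_bp, lvl_genes)
    S_mf <- if (!is.null(store_mf)) simgicMatrix(store_mf, lvl_genes)
    rows <- lapply(seq_along(level), function(i) {
        C <- level[[i]]
        sbp <- similaritySamples(C, level, store_bp, cap, seed + i, S = S_bp)
        p_bp <- .coherencePValue(sbp$intra, sbp$inter)
        if (!is.null(store_mf)) {
            smf <- similaritySamples(C, level, store_mf, cap, seed + i,
                                     S = S_mf)
            p_mf <- .coherencePValue(smf$intra, smf$inter)
        } else {
            smf <- list(intra = numeric(), inter = numeric())
            p_mf <- NA_real_
        }
        data.frame(
            id = C@id, level = C@level, compactness = C@compactness,
            p_bp = p_bp, p_mf = p_mf,
            mu0_bp = ifelse(length(sbp$intra), mean(sbp$intra), NA_real_),
            mu_inter_bp = ifelse(length(sbp$inter), mean(sbp$inter),
                                 NA_real_),
            mu0_mf = ifelse(length(smf$intra), mean(smf$intra), NA_real_),
            mu_inter_mf = ifelse(length(smf$inter), mean(smf$inter),
                                 NA_real_),
            n_annotated = length(intersect(C@genes,
                                           names(store_bp@closed))),
            n_genes = length(C@genes), n_mirnas = length(C@mirnas),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$p_bp, out$id), ]
    rownames(out) <- NULL
    out
}

#' Rank every level of a hierarchy
#'
#' @param hierarchy a [Hierarchy-class].
#' @inheritParams rankLevel
#' @return stacked [rankLevel()] tables for all levels.
#' @export
rankHierarchy <- function(hierarchy, store_bp, store_mf = NULL, cap = 2000,
                          seed = 1) {
    stopifnot(is(hierarchy, "Hierarchy"))
    out <- lapply(seq_along(hierarchy@levels), function(l)
        rankLevel(hierarchy@levels[[l]], store_bp, store_mf, cap,
                  seed + 1000L * l))
    do.call(rbind, out)
}
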