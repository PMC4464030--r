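## Fixture builders and independent oracles shared across the suite.

## dense named matrix -> InteractionMatrix
denseToIM <- function(m) {
    idx <- which(m != 0, arr.ind = TRUE)
    buildInteractionMatrix(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]],
                           m[idx])
}

## uniform random dense score matrix with stable names
randomScoreMatrix <- function(n_mirna, n_mrna, seed) {
    set.seed(seed)
    m <- matrix(runif(n_mirna * n_mrna), n_mirna, n_mrna,
                dimnames = list(sprintf("m%02d", seq_len(n_mirna)),
                                sprintf("g%02d", seq_len(n_mrna))))
    m
}

mkBicluster <- function(id, genes, mirnas, A, level = 1L) {
    methods::new("Bicluster", id = id, genes = sort(genes),
                 mirnas = sort(mirnas), level = as.integer(level),
                 compactness = compactness(list(genes = genes,
                                                mirnas = mirnas), A))
}

## hand-built annotation store (for exact SimGIC formula checks)
mkStore <- function(closed, ic, namespace = "BP") {
    methods::new("AnnotationStore", direct = closed, closed = closed,
                 ic = ic, namespace = namespace, logBase = exp(1))
}

## Brute-force oracle for one greedy aggregation run: at every step enumerate
## ALL admissible pairs from scratch (dense arithmetic, no caching) and take
## the jaccard x q argmax with ties broken by the smallest joined id.
## Returns the sequence of chosen joined ids.
oracleAggregationSteps <- function(bicliques, stats, A) {
    dense <- as.matrix(scoreMatrix(A))
    pool <- lapply(bicliques, function(b)
        list(id = biclusterId(b), genes = genes(b), mirnas = mirnas(b)))
    names(pool) <- vapply(pool, `[[`, "", "id")
    m2g <- stats@direction == "mirna_to_mrna"
    steps <- character()
    repeat {
        best <- NULL
        ids <- sort(names(pool))
        for (i in seq_along(ids)) {
            for (j in seq_along(ids)) {
                if (j <= i) next
                b1 <- pool[[ids[i]]]; b2 <- pool[[ids[j]]]
                if (m2g) {
                    gg <- intersect(b1$genes, b2$genes)
                    mm <- union(b1$mirnas, b2$mirnas)
                    if (length(gg) < stats@min_own) next
                    if (length(mm) > stats@avg_opposite) next
                    jac <- length(intersect(b1$genes, b2$genes)) /
                        length(union(b1$genes, b2$genes))
                } else {
                    gg <- union(b1$genes, b2$genes)
                    mm <- intersect(b1$mirnas, b2$mirnas)
                    if (length(mm) < stats@min_own) next
                    if (length(gg) > stats@avg_opposite) next
                    jac <- length(intersect(b1$mirnas, b2$mirnas)) /
                        length(union(b1$mirnas, b2$mirnas))
                }
                q <- mean(dense[mm, gg])
                obj <- jac * q
                joined <- paste(sort(c(ids[i], ids[j])), collapse = "_")
                if (is.null(best) || obj > best$obj ||
                    (obj == best$obj && joined < best$joined))
                    best <- list(obj = obj, joined = joined,
                                 i = ids[i], j = ids[j],
                                 genes = gg, mirnas = mm)
            }
        }
        if (is.null(best)) break
        steps <- c(steps, best$joined)
        pool[[best$i]] <- NULL
        pool[[best$j]] <- NULL
        pool[[best$joined]] <- list(id = best$joined, genes = best$genes,
                                    mirnas = best$mirnas)
    }
    steps
}

.joinIds2 <- function(a, b) paste(sort(c(a, b)), collapse = "_")

## every (gene, mirna) cell of every bicluster scores > beta in A
allBicliquesValid <- function(bicliques, A, beta) {
    dense <- as.matrix(scoreMatrix(A))
    all(vapply(bicliques, function(b)
        all(dense[mirnas(b), genes(b)] > beta), logical(1)))
}
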