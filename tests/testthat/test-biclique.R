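test_that("compactness is the normalized block score sum", {
    m <- matrix(0, 3, 3, dimnames = list(paste0("m", 1:3),
                                         paste0("g", 1:3)))
    m[1:2, 1:2] <- 1
    A <- denseToIM(m)
    expect_equal(compactness(list(genes = c("g1", "g2"),
                                  mirnas = c("m1", "m2")), A), 1.0)
    m[1, 1] <- 0; m[2, 2] <- 0; m[1, 2] <- 1; m[2, 1] <- 1
    m[1, 1] <- 1; m[2, 2] <- 1; m[1, 2] <- 0; m[2, 1] <- 0
    A <- denseToIM(m)
    expect_equal(compactness(list(genes = c("g1", "g2"),
                                  mirnas = c("m1", "m2")), A), 0.5)
    ## 3x2 block summing to 3.0
    m2 <- matrix(0.5, 2, 3, dimnames = list(paste0("m", 1:2),
                                            paste0("g", 1:3)))
    A2 <- denseToIM(m2)
    expect_equal(compactness(list(genes = paste0("g", 1:3),
                                  mirnas = paste0("m", 1:2)), A2), 0.5)
    expect_error(compactness(list(genes = character(), mirnas = "m1"), A2),
                 "empty")
    expect_error(compactness(list(genes = "gX", mirnas = "m1"), A2),
                 "absent")
})

test_that("jaccard similarity handles the boundary cases", {
    expect_equal(jaccardIndex(c("g1", "g2"), c("g2", "g3")), 1 / 3)
    expect_equal(jaccardIndex(c("a", "b"), c("b", "a")), 1)
    expect_equal(jaccardIndex("a", "b"), 0)
    expect_error(jaccardIndex(character(), character()), "empty")
})

test_that("direction statistics count the thresholded graph", {
    m <- matrix(0.6, 3, 3, dimnames = list(paste0("m", 1:3),
                                           paste0("g", 1:3)))
    A <- denseToIM(m)
    st <- directionStats(A, 0.5, "mirna_to_mrna")
    expect_equal(st@avg_opposite, 3)
    expect_equal(st@min_own, 3L)
    expect_equal(st@abs_min_own, 3L)
    expect_error(directionStats(A, 0.7), "empty reliable graph")
    ## the threshold is strict: a score equal to beta does not count
    expect_error(directionStats(A, 0.6), "empty reliable graph")
})

test_that("the outlier-proof minimum trims the lowest 0.15% of degrees", {
    ## 1000 miRNAs: 999 target 10 mRNAs, 1 targets a single mRNA
    mir <- c(rep(sprintf("m%04d", 1:999), each = 10), "m1000")
    gen <- c(rep(sprintf("g%02d", 1:10), times = 999), "g01")
    A <- buildInteractionMatrix(mir, gen, rep(0.9, length(mir)))
    st <- directionStats(A, 0.5, "mirna_to_mrna")
    expect_equal(st@abs_min_own, 1L)   # untrimmed minimum
    expect_equal(st@min_own, 10L)      # floor(0.0015 * 1000) = 1 discarded
})

test_that("initial bicliques pair each seed with its reliable partners", {
    m <- matrix(0, 2, 3, dimnames = list(c("m1", "m2"),
                                         c("g1", "g2", "g3")))
    m["m1", c("g1", "g2")] <- 0.8
    m["m2", "g3"] <- 0.3          # below beta: m2 contributes no biclique
    A <- denseToIM(m)
    bc <- initialBicliques(A, 0.5, "mirna_to_mrna")
    expect_length(bc, 1L)
    expect_equal(genes(bc[[1]]), c("g1", "g2"))
    expect_equal(mirnas(bc[[1]]), "m1")
    expect_equal(biclusterId(bc[[1]]), "1")

    m3 <- matrix(0.6, 3, 3, dimnames = list(paste0("m", 1:3),
                                            paste0("g", 1:3)))
    bc3 <- initialBicliques(denseToIM(m3), 0.5, "mirna_to_mrna")
    expect_length(bc3, 3L)
    expect_true(all(vapply(bc3, function(b) length(genes(b)), 0L) == 3L))
})

test_that("raising beta never increases the initial biclique count", {
    for (s in 1:5) {
        A <- denseToIM(randomScoreMatrix(8, 12, seed = s))
        counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(b)
            length(tryCatch(initialBicliques(A, b, "mirna_to_mrna"),
                            error = function(e) list())), integer(1))
        expect_true(all(diff(counts) <= 0))
    }
})

test_that("aggregation applies the stated set algebra", {
    m <- matrix(0.9, 2, 4, dimnames = list(c("x", "y"),
                                           c("a", "b", "c", "d")))
    m["x", "d"] <- 0; m["y", "a"] <- 0
    A <- denseToIM(m)
    st <- methods::new("DirectionStats", avg_opposite = 2, min_own = 2L,
                       abs_min_own = 2L, direction = "mirna_to_mrna",
                       beta = 0.5)
    bc <- initialBicliques(A, 0.5, "mirna_to_mrna")
    out <- aggregateBicliques(bc, st, A)
    expect_length(out, 1L)
    expect_equal(genes(out[[1]]), c("b", "c"))
    expect_equal(mirnas(out[[1]]), c("x", "y"))
    expect_equal(biclusterId(out[[1]]), "1_2")
})

test_that("bicliques with disjoint gene sets are never aggregated", {
    m <- matrix(0, 2, 4, dimnames = list(c("x", "y"),
                                         c("a", "b", "c", "d")))
    m["x", c("a", "b")] <- 0.9
    m["y", c("c", "d")] <- 0.9
    A <- denseToIM(m)
    st <- directionStats(A, 0.5, "mirna_to_mrna")
    out <- aggregateBicliques(initialBicliques(A, 0.5, "mirna_to_mrna"),
                              st, A)
    expect_length(out, 2L)
})

test_that("greedy choices equal the exhaustive argmax at every step", {
    for (s in 1:4) {
        A <- denseToIM(randomScoreMatrix(8, 8, seed = 100 + s))
        st <- directionStats(A, 0.3, "mirna_to_mrna")
        bc <- initialBicliques(A, 0.3, "mirna_to_mrna")
        out <- aggregateBicliques(bc, st, A, trace = TRUE)
        tr <- attr(out, "trace")
        got <- if (nrow(tr)) mapply(function(a, b) .joinIds2(a, b),
                                    tr$id1, tr$id2) else character()
        expect_equal(unname(got), oracleAggregationSteps(bc, st, A))
    }
})

test_that("step-1 outputs remain bicliques on the thresholded graph", {
    for (s in 1:3) {
        A <- denseToIM(randomScoreMatrix(10, 10, seed = 200 + s))
        beta <- 0.4
        st <- directionStats(A, beta, "mirna_to_mrna")
        out <- aggregateBicliques(initialBicliques(A, beta, "mirna_to_mrna"),
                                  st, A)
        expect_true(allBicliquesValid(out, A, beta))
        ## aggregation strictly reduces the count by one per step
        out2 <- aggregateBicliques(initialBicliques(A, beta,
                                                    "mirna_to_mrna"),
                                   st, A, trace = TRUE)
        expect_equal(length(out2),
                     length(initialBicliques(A, beta, "mirna_to_mrna")) -
                         nrow(attr(out2, "trace")))
    }
})

test_that("aggregation output is invariant to the input ordering", {
    A <- denseToIM(randomScoreMatrix(8, 8, seed = 301))
    st <- directionStats(A, 0.3, "mirna_to_mrna")
    bc <- initialBicliques(A, 0.3, "mirna_to_mrna")
    out1 <- aggregateBicliques(bc, st, A)
    out2 <- aggregateBicliques(rev(bc), st, A)
    sig <- function(x) lapply(x, function(b)
        list(biclusterId(b), genes(b), mirnas(b)))
    expect_equal(sig(out1), sig(out2))
})

test_that("pruning drops undersized bicliques and reports isolated objects", {
    m <- matrix(0.9, 4, 4, dimnames = list(paste0("m", 1:4),
                                           paste0("g", 1:4)))
    A <- denseToIM(m)
    b1 <- mkBicluster("1", c("g1", "g2"), c("m1", "m2"), A)
    b2 <- mkBicluster("2", c("g3", "g4"), c("m3", "m4"), A)
    b3 <- mkBicluster("3", "g1", "m1", A)
    pr <- pruneBicliques(list(b1, b3), abs_min_mirna = 2, abs_min_mrna = 2)
    expect_length(pr$kept, 1L)
    expect_equal(biclusterId(pr$kept[[1]]), "1")

    ## a miRNA unique to a pruned biclique becomes isolated
    b4 <- mkBicluster("4", "g4", "m4", A)
    pr <- pruneBicliques(list(b1, b2, b4), 2, 2)
    expect_length(pr$kept, 2L)
    expect_equal(pr$isolated$mirnas, character(0))
    pr <- pruneBicliques(list(b1, b4), 2, 2)
    expect_equal(pr$isolated$mirnas, "m4")
    expect_equal(pr$isolated$genes, "g4")

    ## all pass: nothing isolated when every object is covered
    pr <- pruneBicliques(list(b1, b2), 2, 2)
    expect_length(pr$isolated$mirnas, 0L)
    expect_length(pr$isolated$genes, 0L)
})

test_that("direction merge collapses exact duplicates only", {
    m <- matrix(0.9, 4, 4, dimnames = list(paste0("m", 1:4),
                                           paste0("g", 1:4)))
    A <- denseToIM(m)
    b1 <- mkBicluster("1", c("g1", "g2"), c("m1", "m2"), A)
    b1dup <- mkBicluster("7", c("g1", "g2"), c("m1", "m2"), A)
    b2 <- mkBicluster("2", c("g1", "g2", "g3"), c("m1", "m2"), A)
    out <- mergeDirections(list(b1), list(b1dup, b2))
    expect_length(out, 2L)
    expect_true("1_7" %in% vapply(out, biclusterId, ""))
    ## subset-but-not-equal bicliques are both retained
    out2 <- mergeDirections(list(b1), list(b2))
    expect_length(out2, 2L)
    ## disjoint sets of sizes 3 and 2 stay 5
    b3 <- mkBicluster("3", "g3", c("m3", "m4"), A)
    b4 <- mkBicluster("4", "g4", c("m3", "m4"), A)
    b5 <- mkBicluster("5", c("g1", "g4"), "m3", A)
    out3 <- mergeDirections(list(b1, b2, b3), list(b4, b5))
    expect_length(out3, 5L)
})
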