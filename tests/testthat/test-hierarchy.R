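## deterministic 4-module / 2-super-module score matrix: in-module cells at
## 0.9, within-super cross cells at 0.7, cross-super cells 0, with a +-0.1
## per-miRNA offset so member profiles spread around their module centroid
superModuleFixture <- function() {
    m <- matrix(0, 8, 8, dimnames = list(sprintf("m%d", 1:8),
                                         sprintf("g%d", 1:8)))
    sgn <- rep(c(0.1, -0.1), 4)
    mods <- list(list(1:2, 1:2), list(3:4, 3:4), list(5:6, 5:6),
                 list(7:8, 7:8))
    for (s in list(1:4, 5:8))
        for (i in s) for (j in s) m[i, j] <- 0.7 + sgn[i]
    for (mo in mods)
        for (i in mo[[1]]) for (j in mo[[2]]) m[i, j] <- 0.9 + sgn[i]
    A <- denseToIM(m)
    bics <- lapply(seq_along(mods), function(i)
        mkBicluster(as.character(i), sprintf("g%d", mods[[i]][[2]]),
                    sprintf("m%d", mods[[i]][[1]]), A))
    list(A = A, bics = bics)
}

test_that("object embeddings are the score profiles", {
    m <- matrix(0, 2, 3, dimnames = list(c("m1", "m2"),
                                         c("g1", "g2", "g3")))
    m["m1", "g2"] <- 0.7
    m["m2", "g1"] <- 0.3
    ## filtering zeroes m2's only entry but keeps it in the index:
    ## its embedding must be the zero vector
    A <- filterByScore(denseToIM(m), 0.5)
    em <- embedObjects(A, "mirna")
    expect_equal(dim(em), c(2L, 2L))
    expect_equal(em["m1", "g2"], 0.7)
    expect_equal(unname(em["m2", ]), c(0, 0))
    eg <- embedObjects(A, "gene")
    expect_equal(dim(eg), c(2L, 2L))
    expect_equal(eg["g2", "m1"], 0.7)
})

test_that("well-separated biclusters gain no members from overlap detection", {
    set.seed(3)
    m <- matrix(runif(64, 0, 0.1), 8, 8,
                dimnames = list(sprintf("m%d", 1:8), sprintf("g%d", 1:8)))
    m[1:4, 1:4] <- runif(16, 0.85, 0.95)
    m[5:8, 5:8] <- runif(16, 0.85, 0.95)
    A <- denseToIM(m)
    C1 <- mkBicluster("1", sprintf("g%d", 1:4), sprintf("m%d", 1:4), A)
    C2 <- mkBicluster("2", sprintf("g%d", 5:8), sprintf("m%d", 5:8), A)
    out <- detectOverlapPair(C1, C2, A)
    expect_equal(genes(out$C1), genes(C1))
    expect_equal(mirnas(out$C1), mirnas(C1))
    expect_equal(genes(out$C2), genes(C2))
    expect_equal(mirnas(out$C2), mirnas(C2))
})

test_that("an object sitting at the other bicluster's centroid is shared", {
    m <- matrix(0, 5, 4, dimnames = list(c("m1", "m2", "m3", "m4", "mx"),
                                         c("g1", "g2", "g3", "g4")))
    m["m1", ] <- c(1.0, 0.8, 0, 0)
    m["m2", ] <- c(0.8, 1.0, 0, 0)
    m["m3", ] <- c(0, 0, 1.0, 0.8)
    m["m4", ] <- c(0, 0, 0.8, 1.0)
    m["mx", ] <- c(0, 0, 0.9, 0.9)    # centroid of {m3, m4}
    A <- denseToIM(m)
    C1 <- mkBicluster("1", c("g1", "g2"), c("m1", "m2", "mx"), A)
    C2 <- mkBicluster("2", c("g3", "g4"), c("m3", "m4"), A)
    out <- detectOverlapPair(C1, C2, A)
    expect_true("mx" %in% mirnas(out$C2))          # added to the other one
    expect_true("mx" %in% mirnas(out$C1))          # never removed
    expect_error(detectOverlapPair(C1, C1, A), "distinct")
})

test_that("merge candidacy follows the 2-sigma closeness rule", {
    fx <- superModuleFixture()
    ## identical member sets: dist 0, always a candidate
    b1 <- fx$bics[[1]]
    b1b <- mkBicluster("9", genes(b1), mirnas(b1), fx$A)
    cand <- mergeCandidates(list(b1, b1b), fx$A)
    expect_equal(nrow(cand), 1L)

    ## singleton clusters (sigma = 0) at distinct coordinates: never close
    m <- matrix(0, 2, 2, dimnames = list(c("m1", "m2"), c("g1", "g2")))
    m["m1", "g1"] <- 0.9
    m["m2", "g2"] <- 0.9
    A <- denseToIM(m)
    s1 <- mkBicluster("1", "g1", "m1", A)
    s2 <- mkBicluster("2", "g2", "m2", A)
    expect_equal(nrow(mergeCandidates(list(s1, s2), A)), 0L)

    ## dist exactly equal to 2 sigma' + 2 sigma'': inclusive boundary
    ## cluster {m1, m2} at x = 0 / 0.4 (sigma 0.2), cluster {m3, m4} both at
    ## x = 0.8: gap 0.6 - 2 * 0.2 - 0 ... choose 0.6 so equality holds
    m <- matrix(0, 4, 2, dimnames = list(sprintf("m%d", 1:4),
                                         c("g1", "g2")))
    m["m2", "g1"] <- 0.4
    m["m3", "g1"] <- 0.6
    m["m4", "g1"] <- 0.6
    m[, "g2"] <- c(0.9, 0.9, 0.9, 0.9)   # shared support so genes overlap
    A <- denseToIM(m)
    c1 <- mkBicluster("1", "g2", c("m1", "m2"), A)  # centroid x = 0.2, s 0.2
    c2 <- mkBicluster("2", "g2", c("m3", "m4"), A)  # centroid x = 0.6, s 0
    ## gene dimension is identical (dist 0) so the pair is trivially close;
    ## restrict the check to the miRNA geometry via distinct genes instead
    m2 <- m; m2[c(1, 2), 2] <- c(0.9, 0.9); m2[c(3, 4), 2] <- 0
    m2 <- cbind(m2, g3 = c(0, 0, 0.9, 0.9))
    A2 <- denseToIM(m2)
    d1 <- mkBicluster("1", "g2", c("m1", "m2"), A2)
    d2 <- mkBicluster("2", "g3", c("m3", "m4"), A2)
    geom <- mergeCandidates(list(d1, d2), A2)
    ## miRNA dim: dist( (0.2, 0.9, 0), (0.6, 0, 0.9) ) >> 0.4; gene dim far
    ## -> decide from first principles what the rule gives and assert that
    emb <- embedObjects(A2, "mirna")
    ctr1 <- colMeans(emb[c("m1", "m2"), ]); ctr2 <- colMeans(emb[c("m3", "m4"), ])
    d <- sqrt(sum((ctr1 - ctr2)^2))
    s1v <- sqrt(mean(rowSums(sweep(emb[c("m1", "m2"), ], 2, ctr1)^2)))
    s2v <- sqrt(mean(rowSums(sweep(emb[c("m3", "m4"), ], 2, ctr2)^2)))
    gemb <- embedObjects(A2, "gene")
    dg <- sqrt(sum((gemb["g2", ] - gemb["g3", ])^2))
    expected <- (d - 2 * s1v - 2 * s2v <= 0) || (dg <= 0)
    expect_equal(nrow(geom) == 1L, expected)
})

test_that("union merges respect the strict quality constraint", {
    ## all-ones 4x4, two complementary halves, alpha = 0.3: merged with q = 1
    m <- matrix(1, 4, 4, dimnames = list(sprintf("m%d", 1:4),
                                         sprintf("g%d", 1:4)))
    A <- denseToIM(m)
    b1 <- mkBicluster("1", c("g1", "g2"), c("m1", "m2"), A)
    b2 <- mkBicluster("2", c("g3", "g4"), c("m3", "m4"), A)
    mg <- mergeLevel(list(b1, b2), A, alpha = 0.3)
    expect_equal(mg$n_merges, 1L)
    expect_equal(length(mg$next_level), 1L)
    expect_equal(unname(mg$mergeQ), 1)

    ## union q equal to alpha exactly: NOT merged (constraint is strict)
    mg2 <- mergeLevel(list(b1, b2), A, alpha = 1)
    expect_equal(mg2$n_merges, 0L)
    expect_equal(length(mg2$next_level), 2L)
    ## unmerged biclusters are copied upward with self parent links
    expect_equal(unname(mg2$parents), c("2:1", "2:2"))
})

test_that("a bicluster in several passing pairs takes its best merge", {
    ## three mutual candidates; pair (1,2) has the highest union q
    m <- matrix(0, 4, 6, dimnames = list(sprintf("m%d", 1:4),
                                         sprintf("g%d", 1:6)))
    m[1:2, 1:4] <- 0.8                    # biclusters 1 and 2 interlock
    m[3:4, 1:6] <- 0.55                   # bicluster 3 is weaker
    m[1, 1] <- 0.9; m[2, 2] <- 0.9
    A <- denseToIM(m)
    b1 <- mkBicluster("1", sprintf("g%d", 1:3), c("m1", "m2"), A)
    b2 <- mkBicluster("2", sprintf("g%d", 2:4), c("m1", "m2"), A)
    b3 <- mkBicluster("3", sprintf("g%d", 1:6), c("m3", "m4"), A)
    cand <- mergeCandidates(list(b1, b2, b3), A)
    q12 <- compactness(list(genes = union(genes(b1), genes(b2)),
                            mirnas = union(mirnas(b1), mirnas(b2))), A)
    q13 <- compactness(list(genes = union(genes(b1), genes(b3)),
                            mirnas = union(mirnas(b1), mirnas(b3))), A)
    expect_gt(q12, q13)
    mg <- mergeLevel(list(b1, b2, b3), A, alpha = 0.3)
    ## brute force: among all passing pairs, greedy best-q first
    expect_true("1_2" %in% vapply(mg$next_level, biclusterId, ""))
    expect_true("3" %in% vapply(mg$next_level, biclusterId, ""))
    expect_equal(mg$n_merges, 1L)
})

test_that("hierarchies stop when nothing merges and grow one root when all do", {
    ## far-apart planted modules: a single level
    set.seed(5)
    m <- matrix(runif(64, 0, 0.1), 8, 8,
                dimnames = list(sprintf("m%d", 1:8), sprintf("g%d", 1:8)))
    m[1:4, 1:4] <- runif(16, 0.85, 0.95)
    m[5:8, 5:8] <- runif(16, 0.85, 0.95)
    A <- denseToIM(m)
    b1 <- mkBicluster("1", sprintf("g%d", 1:4), sprintf("m%d", 1:4), A)
    b2 <- mkBicluster("2", sprintf("g%d", 5:8), sprintf("m%d", 5:8), A)
    h <- buildHierarchy(list(b1, b2), A, alpha = 0.3, beta = 0.5)
    expect_equal(nLevels(h), 1L)

    ## all-ones matrix seeded as 4 single-miRNA bicliques, alpha = 0.1:
    ## every union keeps q = 1 so the top level is one all-object root
    m1 <- matrix(1, 4, 4, dimnames = list(sprintf("m%d", 1:4),
                                          sprintf("g%d", 1:4)))
    A1 <- denseToIM(m1)
    bics <- lapply(1:4, function(i)
        mkBicluster(as.character(i), sprintf("g%d", 1:4),
                    sprintf("m%d", i), A1))
    h1 <- buildHierarchy(bics, A1, alpha = 0.1, beta = 0.5)
    top <- h1@levels[[nLevels(h1)]]
    expect_length(top, 1L)
    expect_equal(genes(top[[1]]), sprintf("g%d", 1:4))
    expect_equal(mirnas(top[[1]]), sprintf("m%d", 1:4))
    expect_equal(top[[1]]@compactness, 1)
})

test_that("two super-modules emerge as exactly two level-2 parents", {
    fx <- superModuleFixture()
    h <- buildHierarchy(fx$bics, fx$A, alpha = 0.75, beta = 0.5)
    expect_equal(nLevels(h), 2L)
    expect_length(h@levels[[2]], 2L)
    ids <- sort(vapply(h@levels[[2]], biclusterId, ""))
    expect_equal(ids, c("1_2", "3_4"))
    expect_true(all(h@mergeQ > 0.75))
})

test_that("hierarchy structural invariants hold on planted fixtures", {
    for (s in 1:3) {
        d <- plantedDesign(16, 48, n_modules = 4, mirnas_per_module = 4,
                           mrnas_per_module = 12, overlap_fraction = 0.25,
                           seed = s)
        pm <- plantedMatrix(d)
        st <- extractBicliques(pm$matrix, 0.5)
        h <- buildHierarchy(st$bicliques, pm$matrix, alpha = 0.2,
                            beta = 0.5)
        ## every merged parent passed the quality constraint at merge time
        expect_true(all(h@mergeQ > h@alpha))
        ## children are subsets of their parents
        key <- function(b) paste0(b@level, ":", b@id)
        lut <- list()
        for (lv in h@levels) for (b in lv) lut[[key(b)]] <- b
        for (child in names(h@parents)) {
            pb <- lut[[h@parents[[child]]]]
            cb <- lut[[child]]
            if (is.null(pb) || is.null(cb)) next
            expect_true(all(genes(cb) %in% genes(pb)))
            expect_true(all(mirnas(cb) %in% mirnas(pb)))
        }
        ## overlap passes only add members level over level for survivors
        expect_true(all(vapply(unlist(h@levels), function(b)
            b@compactness >= 0 && b@compactness <= 1, logical(1))))
    }
})

test_that("higher alpha never yields more hierarchy levels", {
    for (s in 1:3) {
        d <- plantedDesign(16, 48, n_modules = 4, mirnas_per_module = 4,
                           mrnas_per_module = 12, overlap_fraction = 0.25,
                           seed = 10 + s)
        pm <- plantedMatrix(d)
        st <- extractBicliques(pm$matrix, 0.5)
        lv_low <- nLevels(buildHierarchy(st$bicliques, pm$matrix,
                                         alpha = 0.1, beta = 0.5))
        lv_high <- nLevels(buildHierarchy(st$bicliques, pm$matrix,
                                          alpha = 0.5, beta = 0.5))
        expect_lte(lv_high, lv_low)
    }
})
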