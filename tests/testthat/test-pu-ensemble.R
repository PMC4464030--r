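test_that("nontraditional members emit probabilities and are seeded", {
    data <- puScores(2000, d = 2, prior = 0.5, label_frequency_c = 0.5,
                     separation = 0.6, seed = 4)
    m1 <- fitNontraditional(data, K = 5, seed = 9)
    m2 <- fitNontraditional(data, K = 5, seed = 9)
    expect_identical(lapply(m1@members, `[[`, "sampleIds"),
                     lapply(m2@members, `[[`, "sampleIds"))
    g <- ensembleScore(m1, data)
    expect_true(all(g >= 0 & g <= 1))
    ## separable classes: the ranking must recover the hidden truth
    expect_gte(evaluateAUROC(g, data@truth), 0.95)
})

test_that("fitting without positives fails loudly", {
    data <- puDataset(matrix(runif(20), 10, 2), rep(FALSE, 10))
    expect_error(fitNontraditional(data, K = 2, seed = 1), "positive")
})

test_that("ensemble scores average only the members that saw an example", {
    X <- matrix(c(0.5, 0.5), 1, 2)
    data <- puDataset(X, labeled = FALSE, pairIds = "p1")
    mem <- function(p, ids) list(coef = c(stats::qlogis(p), 0, 0), rate = 1,
                                 sampleIds = ids)
    ## both members saw p1: plain mean
    model <- methods::new("PUEnsembleModel",
                          members = list(mem(0.2, "p1"), mem(0.8, "p1")),
                          labelFrequency = NA_real_,
                          stage = "nontraditional",
                          featureNames = c("a", "b"))
    expect_equal(ensembleScore(model, data), 0.5)
    ## only the first member saw p1
    model@members <- list(mem(0.2, "p1"), mem(0.8, "other"))
    expect_equal(ensembleScore(model, data), 0.2)
    ## no member saw p1: fall back to the all-member mean
    model@members <- list(mem(0.2, "o1"), mem(0.8, "o2"))
    expect_equal(ensembleScore(model, data), 0.5)
    ## invariant to member order
    model@members <- list(mem(0.8, "o2"), mem(0.2, "o1"))
    expect_equal(ensembleScore(model, data), 0.5)
})

test_that("label frequency is recovered on SCAR simulations", {
    data <- puScores(10000, d = 2, prior = 0.5, label_frequency_c = 0.5,
                     separation = 0.6, seed = 21)
    model <- fitNontraditional(data, K = 10, seed = 21)
    c_hat <- estimateLabelFrequency(model, data, 0.2, seed = 21)
    expect_gte(c_hat, 0.45)
    expect_lte(c_hat, 0.55)

    full <- puScores(5000, d = 2, prior = 0.5, label_frequency_c = 1,
                     separation = 0.6, seed = 22)
    m2 <- fitNontraditional(full, K = 10, seed = 22)
    expect_gte(estimateLabelFrequency(m2, full, 0.2, seed = 22), 0.9)

    expect_error(estimateLabelFrequency(model, data, 0.00001, seed = 1),
                 "holdout")
})

test_that("weighted stage with c = 1 reduces to the nontraditional ranking", {
    data <- puScores(4000, d = 2, prior = 0.5, label_frequency_c = 1,
                     separation = 0.4, seed = 31)
    nt <- fitNontraditional(data, K = 5, seed = 31)
    wm <- fitWeighted(data, nt, c = 1, K = 5, seed = 32)
    expect_equal(wm@labelFrequency, 1)
    g <- ensembleScore(nt, data)
    w <- ensembleScore(wm, data)
    expect_gte(stats::cor(g, w, method = "spearman"), 0.99)
    expect_error(fitWeighted(data, nt, c = 1.5, K = 2, seed = 1), "\\(0, 1\\]")
    expect_error(fitWeighted(data, nt, c = 0, K = 2, seed = 1), "\\(0, 1\\]")
})

test_that("weighted scores track the generative posterior", {
    data <- puScores(10000, d = 2, prior = 0.5, label_frequency_c = 0.5,
                     separation = 0.6, seed = 41)
    res <- puCombine(data, K = 10, seed = 41)
    ## disjoint class supports: the true posterior is the 0/1 truth
    mad <- mean(abs(res$scores - as.numeric(data@truth)))
    expect_lte(mad, 0.1)
    expect_true(all(res$scores >= 0 & res$scores <= 1))
})

test_that("baseline combiners follow their formulas", {
    expect_equal(unname(baselineSA(rbind(c(0.2, 0.4, 0.6)))), 0.4,
                 ignore_attr = TRUE)
    expect_equal(as.numeric(baselineSA(matrix(1.0, 1, 1))), 1.0)
    expect_equal(as.numeric(baselineSA(rbind(c(0.5, NA)))), 0.5)
    expect_warning(out <- baselineSA(rbind(c(NA_real_, NA_real_))),
                   "all scores missing")
    expect_equal(as.numeric(out), 0)
    expect_equal(attr(out, "all_missing"), 1L)

    X <- rbind(c(0.2, 0.4, 0.6), c(1, 0, 0))
    expect_equal(baselineWSA(X, c(1, 1, 1)), as.numeric(baselineSA(X)))
    expect_equal(baselineWSA(rbind(c(1, 0, 0)), c(2, 1, 1)), 0.5)
    expect_equal(baselineWSA(rbind(c(0.3, 0.9)), c(1, 0)), 0.3)
    expect_error(baselineWSA(X, c(0, 0, 0)), "all zero")
})

test_that("coverage counts match an exhaustive scan of the ranking", {
    ## perfect ranking: all 5 validated genes first among 100
    sc <- stats::setNames(seq(1, 0.01, length.out = 100), paste0("G", 1:100))
    val <- paste0("G", 1:5)
    out <- evaluateCoverage(sc, val, 100)
    expect_equal(out$k, 5L)

    ## a validated gene missing from the scored set: 100% unreachable
    out <- evaluateCoverage(sc, c("G1", "ABSENT"), c(50, 100))
    expect_equal(out$k, c(1L, NA_integer_))

    expect_error(evaluateCoverage(sc, character()), "empty")
    expect_error(evaluateCoverage(sc, "ABSENT"), "no validated gene")

    ## brute-force oracle on random scores
    set.seed(7)
    sc <- stats::setNames(runif(1000), paste0("G", 1:1000))
    val <- paste0("G", sample(1000, 10))
    out <- evaluateCoverage(sc, val, 50)
    ord <- names(sc)[order(-sc, names(sc))]
    k_brute <- NA_integer_
    need <- ceiling(0.5 * length(val))
    for (k in seq_along(ord))
        if (sum(ord[seq_len(k)] %in% val) >= need) { k_brute <- k; break }
    expect_equal(out$k, k_brute)
})

test_that("AUPRC follows the precision-recall geometry", {
    expect_equal(evaluateAUPRC(c(0.9, 0.8, 0.2, 0.1),
                               c(TRUE, TRUE, FALSE, FALSE)), 1.0)
    ## constant scores collapse to a single PR point at the prevalence
    expect_equal(evaluateAUPRC(rep(0.5, 10), c(rep(TRUE, 3), rep(FALSE, 7))),
                 0.3)
    expect_error(evaluateAUPRC(runif(5), rep(TRUE, 5)), "both classes")
    ## random scores: AUPRC concentrates on the prevalence
    set.seed(11)
    truth <- runif(10000) < 0.1
    auprc <- evaluateAUPRC(runif(10000), truth)
    expect_lt(abs(auprc - 0.1), 0.03)
})

test_that("rank-based AUROC agrees with an independent implementation", {
    skip_if_not_installed("pROC")
    set.seed(5)
    sc <- runif(400)
    truth <- runif(400) < stats::plogis(4 * sc - 2)
    ours <- evaluateAUROC(sc, truth)
    ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = sc,
                                          quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
})
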