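#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a positive-unlabeled dataset of prediction-score vectors
#'
#' @param features numeric matrix (pairs x algorithms); \code{NA} cells are
#'   imputed with \code{impute} (default 0: the absence of a prediction is
#'   treated as evidence of non-interaction for that algorithm).
#' @param labeled logical vector: \code{TRUE} for experimentally validated
#'   (positive-labeled) pairs.
#' @param pairIds unique pair keys; default \code{"pair<i>"}.
#' @param truth optional hidden true class (synthetic data), evaluation only.
#' @param impute value replacing missing scores.
#' @return a [PUDataset-class].
#' @export
puDataset <- function(features, labeled, pairIds = NULL, truth = NULL,
                      impute = 0) {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    features[is.na(features)] <- impute
    if (is.null(pairIds))
        pairIds <- paste0("pair", seq_len(nrow(features)))
    methods::new("PUDataset", features = features,
                 labeled = as.logical(labeled),
                 pairIds = as.character(pairIds), truth = truth)
}

#' Build a PUDataset from a prediction table
#'
#' @param records data.frame from [readPredictions()] /[markValidated()].
#' @param impute value replacing missing scores (default 0).
#' @return a [PUDataset-class]; pair ids are \code{"mirna|gene"}.
#' @export
puDatasetFromRecords <- function(records, impute = 0) {
    algo <- setdiff(names(records), c("mirna", "gene", "validated"))
    feats <- as.matrix(records[algo])
    if (any(rowSums(!is.na(feats)) == 0))
        stop("record with all scores missing")
    puDataset(feats, records$validated,
              paste(records$mirna, records$gene, sep = "|"), impute = impute)
}

## One logistic member on (X, y, w). Separation and fractional weights are
## expected here, so warnings are muted; non-convergence surfaces as an error
## the caller retries on.
.fitLogistic <- function(X, y, w = NULL) {
    Xd <- cbind(`(Intercept)` = 1, X)
    fit <- suppressWarnings(stats::glm.fit(
        Xd, y, weights = w, family = stats::quasibinomial()))
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    if (!all(is.finite(cf))) stop("logistic member did not converge")
    cf
}

## Member probability mapped back to the population base rate: the member was
## trained on an undersampled negative class (sampling rate r), so
## logit_pop = logit_member + log(r).
.predictMember <- function(member, X) {
    eta <- drop(cbind(1, X) %*% member$coef) + log(member$rate)
    stats::plogis(eta)
}

#' Fit the nontraditional (labeled-vs-unlabeled) PU ensemble
#'
#' Stage 2 of the PU combiner: K probabilistic classifiers, each trained on
#' all positive (labeled) examples plus \code{negatives_per_member} unlabeled
#' examples sampled with replacement. Member outputs estimate
#' g(x) = P(labeled | x) at the population base rate.
#'
#' @param data a [PUDataset-class] with at least one labeled and one unlabeled
#'   example.
#' @param K number of ensemble members (default 10).
#' @param negatives_per_member unlabeled examples per member; default = number
#'   of positives (balanced members).
#' @param seed integer seed; the member samples are fully determined by it.
#' @param max_retries refits allowed for a degenerate member sample.
#' @return a [PUEnsembleModel-class], stage \code{"nontraditional"}.
#' @export
fitNontraditional <- function(data, K = 10, negatives_per_member = NULL,
                              seed = 1, max_retries = 5) {
    stopifnot(is(data, "PUDataset"), K >= 1)
    pos <- which(data@labeled)
    unl <- which(!data@labeled)
    if (length(pos) == 0) stop("no positive (labeled) examples")
    if (length(unl) == 0) stop("no unlabeled examples")
    if (is.null(negatives_per_member)) negatives_per_member <- length(pos)
    if (negatives_per_member > length(unl))
        stop("negatives_per_member exceeds the number of unlabeled examples")
    X <- data@features
    y <- as.numeric(data@labeled)
    rng <- .seededRNG(seed)
    members <- vector("list", K)
    for (k in seq_len(K)) {
        cf <- NULL
        for (try in seq_len(max_retries)) {
            smp <- unl[.rngSampleInt(rng, length(unl), negatives_per_member,
                                     replace = TRUE)]
            idx <- c(pos, smp)
            cf <- tryCatch(.fitLogistic(X[idx, , drop = FALSE], y[idx]),
                           error = function(e) NULL)
            if (!is.null(cf)) break
        }
        if (is.null(cf)) stop("member ", k, " could not be fit")
        members[[k]] <- list(
            coef = cf, rate = negatives_per_member / length(unl),
            sampleIds = unique(data@pairIds[c(pos, smp)]))
    }
    methods::new("PUEnsembleModel", members = members,
                 labelFrequency = NA_real_, stage = "nontraditional",
                 featureNames = colnames(X) %||% paste0("f", seq_len(ncol(X))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score examples with a PU ensemble
#'
#' Each example is scored by averaging the outputs of the members whose
#' training sample contained its pair id; an example seen by no member gets
#' the average over all K members.
#'
#' @param model a fitted [PUEnsembleModel-class].
#' @param data a [PUDataset-class]; features must match the model's columns.
#' @return numeric vector in \[0, 1\], one score per example; invariant to
#'   member order.
#' @export
ensembleScore <- function(model, data) {
    stopifnot(is(model, "PUEnsembleModel"), is(data, "PUDataset"))
    X <- data@features
    K <- length(model@members)
    P <- vapply(model@members, function(m) .predictMember(m, X),
                numeric(nrow(X)))
    P <- matrix(P, nrow = nrow(X), ncol = K)
    Seen <- vapply(model@members,
                   function(m) data@pairIds %in% m$sampleIds,
                   logical(nrow(X)))
    Seen <- matrix(Seen, nrow = nrow(X), ncol = K)
    nseen <- rowSums(Seen)
    out <- ifelse(nseen > 0, rowSums(P * Seen) / pmax(nseen, 1),
                  rowMeans(P))
    pmin(pmax(out, 0), 1)
}

#' Estimate the SCAR label frequency c
#'
#' Under the selected-completely-at-random assumption, positives are labeled
#' with a constant probability c, so the nontraditional score g(x) of a true
#' positive converges to c. The estimator holds out a random fraction of the
#' labeled positives and returns their mean g (Elkan-Noto e1).
#'
#' @param model a stage-\code{"nontraditional"} [PUEnsembleModel-class].
#' @param data the [PUDataset-class] the model was fit on.
#' @param holdout_fraction fraction of positives held out (default 0.2); the
#'   holdout must contain at least one example.
#' @param seed integer seed for the holdout draw.
#' @return estimated c, clipped to (1e-6, 1\].
#' @export
estimateLabelFrequency <- function(model, data, holdout_fraction = 0.2,
                                   seed = 1) {
    stopifnot(is(model, "PUEnsembleModel"), is(data, "PUDataset"))
    pos <- which(data@labeled)
    if (length(pos) < 2) stop("need at least two positives")
    nh <- floor(holdout_fraction * length(pos))
    if (nh < 1) stop("holdout of size 0; increase holdout_fraction")
    rng <- .seededRNG(seed)
    hold <- pos[.rngSampleInt(rng, length(pos), nh, replace = FALSE)]
    g <- ensembleScore(model, data)[hold]
    if (all(g == 0)) stop("model uninformative: all holdout scores are zero")
    min(max(mean(g), 1e-6), 1)
}

#' Fit the weighted (final) PU ensemble
#'
#' Stage 3 of the PU combiner: every unlabeled example x enters twice, as a
#' positive with weight w(x) = ((1 - c)/c) * g(x)/(1 - g(x)) (capped) and as a
#' negative with weight 1 - min(w(x), 1); labeled examples are positives with
#' weight 1. The weighted set is bagged exactly like the nontraditional stage;
#' the resulting per-pair score is the calibrated probability that the
#' interaction is a true positive.
#'
#' @param data a [PUDataset-class].
#' @param nontraditional the stage-2 model supplying g(x).
#' @param c label frequency in (0, 1\] (see [estimateLabelFrequency()]).
#' @param K number of members (default 10).
#' @param negatives_per_member negative-role rows per member; default = number
#'   of labeled positives.
#' @param weight_cap upper bound on w(x) (default 50), guarding against
#'   divide-by-near-one blowup when g(x) is close to 1.
#' @param seed integer seed.
#' @param max_retries refits allowed for a degenerate member sample.
#' @return a [PUEnsembleModel-class], stage \code{"weighted"}, with
#'   \code{labelFrequency = c}.
#' @export
fitWeighted <- function(data, nontraditional, c, K = 10,
                        negatives_per_member = NULL, weight_cap = 50,
                        seed = 1, max_retries = 5) {
    stopifnot(is(data, "PUDataset"), is(nontraditional, "PUEnsembleModel"))
    if (c <= 0 || c > 1) stop("label frequency c must be in (0, 1]")
    g <- ensembleScore(nontraditional, data)
    pos <- which(data@labeled)
    unl <- which(!data@labeled)
    if (length(pos) == 0) stop("no positive (labeled) examples")
    w <- pmin(((1 - c) / c) * g[unl] / pmax(1 - g[unl], 1e-12), weight_cap)
    ## positive-role rows: labeled (weight 1) + unlabeled duplicates (weight w)
    posX <- rbind(data@features[pos, , drop = FALSE],
                  data@features[unl, , drop = FALSE])
    posW <- c(rep(1, length(pos)), w)
    posId <- data@pairIds[c(pos, unl)]
    keep <- posW > 0
    posX <- posX[keep, , drop = FALSE]
    posW <- posW[keep]; posId <- posId[keep]
    ## negative-role rows: unlabeled with weight 1 - min(w, 1)
    negX <- data@features[unl, , drop = FALSE]
    negW <- 1 - pmin(w, 1)
    negId <- data@pairIds[unl]
    if (is.null(negatives_per_member)) negatives_per_member <- length(pos)
    negatives_per_member <- min(negatives_per_member, nrow(negX))
    if (nrow(negX) == 0 || all(negW == 0))
        stop("no negative-role mass; c too small for this data")
    rng <- .seededRNG(seed)
    members <- vector("list", K)
    for (k in seq_len(K)) {
        cf <- NULL
        smp <- NULL
        for (try in seq_len(max_retries)) {
            smp <- .rngSampleInt(rng, nrow(negX), negatives_per_member,
                                 replace = TRUE)
            if (sum(negW[smp]) == 0) next
            Xk <- rbind(posX, negX[smp, , drop = FALSE])
            yk <- c(rep(1, nrow(posX)), rep(0, length(smp)))
            wk <- c(posW, negW[smp])
            cf <- tryCatch(.fitLogistic(Xk, yk, wk), error = function(e) NULL)
            if (!is.null(cf)) break
        }
        if (is.null(cf)) stop("weighted member ", k, " could not be fit")
        members[[k]] <- list(
            coef = cf, rate = negatives_per_member / nrow(negX),
            sampleIds = unique(c(posId, negId[smp])))
    }
    methods::new("PUEnsembleModel", members = members, labelFrequency = c,
                 stage = "weighted",
                 featureNames = colnames(data@features) %||%
                     paste0("f", seq_len(ncol(data@features))))
}

#' Run the full three-step PU combiner
#'
#' Convenience wrapper: fit the nontraditional ensemble, estimate the label
#' frequency c on held-out positives, fit the weighted ensemble, and return
#' the final per-pair reliability scores.
#'
#' @param data a [PUDataset-class].
#' @param K ensemble size for both stages.
#' @param holdout_fraction positives held out for the c estimate.
#' @param seed integer seed (stages draw independent substreams).
#' @param ... passed on to [fitNontraditional()] and [fitWeighted()].
#' @return list with \code{scores} (numeric, per pair), \code{c} and both
#'   fitted models.
#' @export
puCombine <- function(data, K = 10, holdout_fraction = 0.2, seed = 1, ...) {
    nt <- fitNontraditional(data, K = K, seed = seed, ...)
    c_hat <- estimateLabelFrequency(nt, data, holdout_fraction, seed = seed + 1)
    wm <- fitWeighted(data, nt, c_hat, K = K, seed = seed + 2, ...)
    list(scores = ensembleScore(wm, data), c = c_hat,
         nontraditional = nt, weighted = wm)
}

#' Score averaging baseline (SA)
#'
#' Equally weights the contribution of each upstream prediction algorithm:
#' the per-pair score is the arithmetic mean of the non-missing scores.
#'
#' @param features numeric matrix (pairs x algorithms), \code{NA} = missing.
#' @return numeric vector; rows with every score missing get 0, and their
#'   count is attached as attribute \code{"all_missing"} with a warning.
#' @export
baselineSA <- function(features) {
    features <- as.matrix(features)
    out <- rowMeans(features, na.rm = TRUE)
    bad <- !is.finite(out)
    if (any(bad)) {
        warning(sum(bad), " row(s) with all scores missing scored 0")
        out[bad] <- 0
    }
    attr(out, "all_missing") <- sum(bad)
    out
}

#' Weighted score averaging baseline (WSA)
#'
#' Weights each algorithm proportionally to its reliability (e.g. F-score
#' derived); weights are renormalized over the non-missing entries of each
#' row.
#'
#' @param features numeric matrix (pairs x algorithms), \code{NA} = missing.
#' @param weights non-negative weights, one per algorithm, not all zero.
#' @return numeric vector of weighted means.
#' @export
baselineWSA <- function(features, weights) {
    features <- as.matrix(features)
    weights <- as.numeric(weights)
    stopifnot(length(weights) == ncol(features), all(weights >= 0))
    if (all(weights == 0)) stop("weights must not be all zero")
    W <- matrix(weights, nrow(features), ncol(features), byrow = TRUE)
    W[is.na(features)] <- 0
    num <- rowSums(W * features, na.rm = TRUE)
    den <- rowSums(W)
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
        warning(sum(den == 0),
                " row(s) with no positively weighted score scored 0")
    out
}

#' Interactions needed to cover a percentage of validated targets
#'
#' For one miRNA, ranks the scored genes by descending reliability and reports,
#' for each requested percentage p, the smallest number k of top-ranked
#' interactions whose gene set contains at least \code{ceiling(p/100 *
#' |validated|)} validated genes. When the scored set contains fewer validated
#' genes than required, the percentage is not reachable and \code{NA} is
#' reported.
#'
#' @param scores named numeric vector: gene -> reliability score.
#' @param validated character vector of validated target genes (non-empty,
#'   and at least one must be among the scored genes).
#' @param coverage_percents percentages on the 0-100 scale.
#' @return data.frame with columns \code{percent}, \code{required} (validated
#'   genes needed) and \code{k} (interactions to return; \code{NA} = not
#'   reachable).
#' @export
evaluateCoverage <- function(scores, validated,
                             coverage_percents = seq(10, 70, by = 10)) {
    validated <- unique(as.character(validated))
    if (length(validated) == 0) stop("validated set is empty")
    if (is.null(names(scores))) stop("scores must be named by gene")
    if (!any(names(scores) %in% validated))
        stop("no validated gene among the scored genes")
    o <- order(-scores, names(scores))
    hits <- cumsum(names(scores)[o] %in% validated)
    out <- data.frame(percent = coverage_percents,
                      required = ceiling(coverage_percents / 100 *
                                         length(validated)))
    out$k <- vapply(out$required, function(r) {
        if (r == 0) return(0L)
        i <- which(hits >= r)
        if (length(i)) i[1L] else NA_integer_
    }, integer(1))
    out
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation over all score thresholds, grouping tied scores at
#' a single operating point (so constant scores yield AUPRC = prevalence).
#'
#' @param scores numeric vector of predicted reliabilities.
#' @param truth logical vector: \code{TRUE} for validated interactions; both
#'   classes must be present.
#' @return AUPRC in \[0, 1\].
#' @export
evaluateAUPRC <- function(scores, truth) {
    truth <- as.logical(truth)
    stopifnot(length(scores) == length(truth))
    P <- sum(truth)
    if (P == 0 || P == length(truth))
        stop("truth must contain both classes")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; y <- truth[o]
    last <- cumsum(!duplicated(s, fromLast = FALSE))  # group index per row
    grp_end <- which(!duplicated(rev(s)))             # positions from tail
    grp_end <- length(s) + 1L - rev(grp_end)          # last row of each group
    tp <- cumsum(y)[grp_end]
    n_at <- grp_end
    recall <- tp / P
    precision <- tp / n_at
    sum(diff(c(0, recall)) * precision)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling; used to judge
#' how well a score vector separates a known binary truth.
#'
#' @param scores numeric vector.
#' @param truth logical vector; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
evaluateAUROC <- function(scores, truth) {
    truth <- as.logical(truth)
    P <- sum(truth); N <- sum(!truth)
    if (P == 0 || N == 0) stop("truth must contain both classes")
    r <- rank(scores, ties.method = "average")
    (sum(r[truth]) - P * (P + 1) / 2) / (P * N)
}
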