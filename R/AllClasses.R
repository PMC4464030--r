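#' @import methods
#' @importFrom Matrix sparseMatrix Matrix t rowSums colSums
NULL

setClassUnion("logicalOrNULL", c("logical", "NULL"))

#' Weighted bipartite miRNA x mRNA interaction matrix
#'
#' Holds the adjacency matrix A of the interaction graph: one row per miRNA,
#' one column per gene (mRNA), entries in \[0, 1\] giving the reliability score
#' of each candidate interaction. Absent entries mean score 0. Row and column
#' names are kept lexicographically sorted so every downstream computation is
#' deterministic.
#'
#' @slot scores a sparse \code{dgCMatrix}; rows = miRNAs, columns = genes,
#'   values in \[0, 1\].
#'
#' @seealso [buildInteractionMatrix()], [filterByScore()], [compactness()]
#' @export
setClass("InteractionMatrix", representation(scores = "Matrix"))

setValidity("InteractionMatrix", function(object) {
    m <- object@scores
    msg <- character()
    if (is.null(rownames(m)) && nrow(m) > 0)
        msg <- c(msg, "miRNA (row) names are required")
    if (is.null(colnames(m)) && ncol(m) > 0)
        msg <- c(msg, "gene (column) names are required")
    if (nrow(m) > 0 && is.unsorted(rownames(m), strictly = TRUE))
        msg <- c(msg, "miRNA index must be strictly sorted")
    if (ncol(m) > 0 && is.unsorted(colnames(m), strictly = TRUE))
        msg <- c(msg, "gene index must be strictly sorted")
    v <- m@x
    if (length(v) && (min(v) < 0 || max(v) > 1))
        msg <- c(msg, "all scores must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' A miRNA-gene bicluster (regulatory module)
#'
#' A bicluster pairs a gene set Cr with a miRNA set Cc. During step 1 the pair
#' is a biclique on the beta-thresholded graph (every gene interacts with every
#' miRNA above beta); after overlap detection and merging this is relaxed and
#' cohesiveness is tracked through the compactness q(C, A), the mean score over
#' all |Cr| x |Cc| cells of the block.
#'
#' The \code{id} records lineage: aggregated or merged biclusters join their
#' founders' ids with \code{"_"} (e.g. \code{"379_405"}).
#'
#' @slot id character lineage identifier.
#' @slot genes character vector, the gene (mRNA) members Cr.
#' @slot mirnas character vector, the miRNA members Cc.
#' @slot level integer hierarchy level (1 = leaves).
#' @slot compactness numeric, q(C, A) at last computation.
#' @export
setClass("Bicluster", representation(
    id = "character", genes = "character", mirnas = "character",
    level = "integer", compactness = "numeric"))

setValidity("Bicluster", function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "id must be a single non-empty string")
    if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate genes")
    if (anyDuplicated(object@mirnas)) msg <- c(msg, "duplicate miRNAs")
    if (length(msg)) msg else TRUE
})

#' Hierarchy of overlapping biclusters
#'
#' Ordered levels of biclusters produced by iterated overlap detection and
#' quality-constrained merging. Level 1 holds the step-1 bicliques after the
#' first overlap pass; each later level is produced by merging close bicluster
#' pairs whose union compactness exceeds \code{alpha}, with unmerged biclusters
#' copied upward unchanged.
#'
#' @slot levels list of lists of [Bicluster-class] objects, bottom-up.
#' @slot parents named character; child bicluster id -> parent id (ids are
#'   prefixed with the level, e.g. \code{"2:379_405"}, so copied-up biclusters
#'   stay distinguishable across levels).
#' @slot mergeQ named numeric; for every merged (non-leaf, non-copied) parent,
#'   the union compactness measured at merge time.
#' @slot alpha,beta the thresholds the hierarchy was built with.
#' @export
setClass("Hierarchy", representation(
    levels = "list", parents = "character", mergeQ = "numeric",
    alpha = "numeric", beta = "numeric"))

#' Positive-unlabeled training set of prediction-score vectors
#'
#' Each row of \code{features} is the score vector of one candidate miRNA-gene
#' pair over the upstream prediction algorithms; \code{labeled} flags the
#' experimentally validated (positive-labeled) pairs, everything else is
#' unlabeled. \code{truth} optionally carries the hidden true class of
#' synthetic data, for evaluation only.
#'
#' @slot features numeric matrix, n x d, finite after imputation.
#' @slot labeled logical vector of length n.
#' @slot pairIds character vector of length n, unique pair keys.
#' @slot truth logical vector of length n or NULL (synthetic data only).
#' @export
setClass("PUDataset", representation(
    features = "matrix", labeled = "logical", pairIds = "character",
    truth = "logicalOrNULL"))

setValidity("PUDataset", function(object) {
    n <- nrow(object@features)
    msg <- character()
    if (ncol(object@features) < 1L) msg <- c(msg, "need at least one feature")
    if (length(object@labeled) != n) msg <- c(msg, "labeled length != n")
    if (length(object@pairIds) != n) msg <- c(msg, "pairIds length != n")
    if (anyDuplicated(object@pairIds)) msg <- c(msg, "duplicate pairIds")
    if (!all(is.finite(object@features)))
        msg <- c(msg, "features must be finite (impute first)")
    if (length(msg)) msg else TRUE
})

#' Bagged positive-unlabeled ensemble model
#'
#' K logistic members, each trained on all positive-role examples plus a
#' bootstrap sample of negative-role examples. Because members undersample the
#' negative class, raw member probabilities are mapped back to the population
#' base rate (case-control intercept correction) before averaging. The
#' \code{nontraditional} stage discriminates labeled vs unlabeled and its
#' output g(x) estimates P(labeled | x); the \code{weighted} stage applies
#' Elkan-Noto weighting with the label frequency c and outputs the calibrated
#' probability that an interaction is a true positive.
#'
#' @slot members list of fitted members (coefficients, sampling rate, sampled
#'   pair ids).
#' @slot labelFrequency numeric in (0, 1\]; NA until estimated.
#' @slot stage \code{"nontraditional"} or \code{"weighted"}.
#' @slot featureNames character, column order the model expects.
#' @export
setClass("PUEnsembleModel", representation(
    members = "list", labelFrequency = "numeric", stage = "character",
    featureNames = "character"))

setValidity("PUEnsembleModel", function(object) {
    msg <- character()
    if (length(object@members) < 1L) msg <- c(msg, "K must be >= 1")
    if (!object@stage %in% c("nontraditional", "weighted"))
        msg <- c(msg, "unknown stage")
    c0 <- object@labelFrequency
    if (!is.na(c0) && (c0 <= 0 || c0 > 1))
        msg <- c(msg, "labelFrequency must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Ontology graph (OBO subset)
#'
#' A DAG of ontology terms; \code{parents} keeps is_a and part_of edges, both
#' treated as subsumption. Obsolete terms are excluded at read time.
#'
#' @slot terms character vector of term ids.
#' @slot parents named list; term id -> character vector of parent ids.
#' @slot namespace named character; term id -> namespace tag (e.g. "BP", "MF").
#' @export
setClass("OntologyGraph", representation(
    terms = "character", parents = "list", namespace = "character"))

setValidity("OntologyGraph", function(object) {
    msg <- character()
    allp <- unique(unlist(object@parents, use.names = FALSE))
    if (length(allp) && !all(allp %in% object@terms))
        msg <- c(msg, "dangling parent term(s)")
    if (length(msg)) msg else TRUE
})

#' Gene annotation store with information content
#'
#' Direct and ancestor-closed GO(x) term sets per gene, restricted to one
#' namespace, plus the per-term information content IC(t) = -log p(t) where
#' p(t) is the fraction of annotated genes whose closed set contains t.
#'
#' @slot direct named list; gene -> direct term ids.
#' @slot closed named list; gene -> ancestor-closed term ids.
#' @slot ic named numeric; term -> information content (terms with p = 0 are
#'   absent).
#' @slot namespace single character namespace tag.
#' @slot logBase numeric, logarithm base used for IC.
#' @export
setClass("AnnotationStore", representation(
    direct = "list", closed = "list", ic = "numeric",
    namespace = "character", logBase = "numeric"))

setValidity("AnnotationStore", function(object) {
    msg <- character()
    if (length(object@ic) && min(object@ic) < -1e-12)
        msg <- c(msg, "negative information content")
    ok <- mapply(function(d, cl) all(d %in% cl),
                 object@direct, object@closed[names(object@direct)])
    if (length(ok) && !all(ok))
        msg <- c(msg, "direct sets must be subsets of closed sets")
    if (length(msg)) msg else TRUE
})
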