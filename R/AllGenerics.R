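#' @include AllClasses.R
NULL

#' miRNA identifiers of an object
#' @param x an object holding miRNAs.
#' @return character vector of miRNA ids.
#' @export
setGeneric("mirnas", function(x) standardGeneric("mirnas"))

#' Gene (mRNA) identifiers of an object
#' @param x an object holding genes.
#' @return character vector of gene symbols.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Dense/sparse score matrix of an interaction object
#' @param x an [InteractionMatrix-class].
#' @return the underlying sparse score matrix (miRNAs x genes).
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' Number of stored (non-zero) interactions
#' @param x an [InteractionMatrix-class].
#' @return integer count of stored entries.
#' @export
setGeneric("interactionCount", function(x) standardGeneric("interactionCount"))

#' Bicluster identifier
#' @param x a [Bicluster-class].
#' @return the lineage id string.
#' @export
setGeneric("biclusterId", function(x) standardGeneric("biclusterId"))

#' Levels of a bicluster hierarchy
#' @param x a [Hierarchy-class].
#' @return list of levels, each a list of [Bicluster-class] objects.
#' @export
setGeneric("hierarchyLevels", function(x) standardGeneric("hierarchyLevels"))

#' Parent links of a bicluster hierarchy
#' @param x a [Hierarchy-class].
#' @return named character vector, child key -> parent key.
#' @export
setGeneric("parentLinks", function(x) standardGeneric("parentLinks"))

#' Per-term information content table
#' @param x an [AnnotationStore-class].
#' @return named numeric vector of IC values.
#' @export
setGeneric("termIC", function(x) standardGeneric("termIC"))

setMethod("mirnas", "InteractionMatrix", function(x) rownames(x@scores))
setMethod("genes", "InteractionMatrix", function(x) colnames(x@scores))
setMethod("scoreMatrix", "InteractionMatrix", function(x) x@scores)
setMethod("interactionCount", "InteractionMatrix",
          function(x) length(x@scores@x))
setMethod("mirnas", "Bicluster", function(x) x@mirnas)
setMethod("genes", "Bicluster", function(x) x@genes)
setMethod("biclusterId", "Bicluster", function(x) x@id)
setMethod("hierarchyLevels", "Hierarchy", function(x) x@levels)
setMethod("parentLinks", "Hierarchy", function(x) x@parents)
setMethod("termIC", "AnnotationStore", function(x) x@ic)

#' @describeIn InteractionMatrix dimensions (miRNAs, genes).
#' @param x an \code{InteractionMatrix}.
#' @export
setMethod("dim", "InteractionMatrix", function(x) dim(x@scores))

setMethod("show", "InteractionMatrix", function(object) {
    cat(sprintf("InteractionMatrix: %d miRNAs x %d genes, %d scored pairs\n",
                nrow(object@scores), ncol(object@scores),
                length(object@scores@x)))
    if (length(object@scores@x))
        cat(sprintf("  score range [%.3f, %.3f]\n",
                    min(object@scores@x), max(object@scores@x)))
})

setMethod("show", "Bicluster", function(object) {
    cat(sprintf("Bicluster %s (level %d): %d genes x %d miRNAs, q = %.3f\n",
                object@id, object@level, length(object@genes),
                length(object@mirnas), object@compactness))
})

setMethod("show", "Hierarchy", function(object) {
    cat(sprintf("Hierarchy: %d level(s), alpha = %.2f, beta = %.2f\n",
                length(object@levels), object@alpha, object@beta))
    for (l in seq_along(object@levels))
        cat(sprintf("  level %d: %d bicluster(s)\n", l,
                    length(object@levels[[l]])))
})

setMethod("show", "PUDataset", function(object) {
    cat(sprintf("PUDataset: %d pairs x %d algorithms, %d labeled positive\n",
                nrow(object@features), ncol(object@features),
                sum(object@labeled)))
})

setMethod("show", "PUEnsembleModel", function(object) {
    cat(sprintf("PUEnsembleModel (%s): K = %d members, c = %s\n",
                object@stage, length(object@members),
                ifelse(is.na(object@labelFrequency), "not estimated",
                       sprintf("%.3f", object@labelFrequency))))
})

setMethod("show", "OntologyGraph", function(object) {
    cat(sprintf("OntologyGraph: %d terms (%s)\n", length(object@terms),
                paste(sprintf("%s: %d", names(table(object@namespace)),
                              table(object@namespace)), collapse = ", ")))
})

setMethod("show", "AnnotationStore", function(object) {
    cat(sprintf(
        "AnnotationStore [%s]: %d genes, %d terms with finite IC\n",
        object@namespace, length(object@direct), length(object@ic)))
})
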