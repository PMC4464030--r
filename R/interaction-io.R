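#' @include AllClasses.R AllGenerics.R
NULL

#' Read a miRNA-target prediction score table
#'
#' Reads a tab-delimited table with one row per candidate miRNA-gene pair and
#' one score column per upstream prediction algorithm. Missing cells (the
#' \code{missing_token}) become \code{NA}; they are imputed later, per
#' algorithm, when a feature matrix is built (see [puDataset()]).
#'
#' @param path TSV file; header must name \code{mirna}, \code{gene} and the
#'   algorithm columns.
#' @param algorithm_names character vector naming the score columns to read;
#'   defaults to every column after \code{mirna} and \code{gene}.
#' @param missing_token string marking a missing score (default \code{"NA"};
#'   empty cells are always treated as missing).
#' @return a \code{data.frame} with columns \code{mirna}, \code{gene},
#'   \code{validated} (all \code{FALSE}) and one numeric column per algorithm,
#'   row order preserved.
#' @export
readPredictions <- function(path, algorithm_names = NULL,
                            missing_token = "NA") {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             na.strings = NULL, quote = "",
                             fileEncoding = "UTF-8")
    if (!all(c("mirna", "gene") %in% names(raw)))
        stop("prediction table must have 'mirna' and 'gene' columns")
    if (is.null(algorithm_names))
        algorithm_names <- setdiff(names(raw), c("mirna", "gene"))
    if (!all(algorithm_names %in% names(raw)))
        stop("missing algorithm column(s): ",
             paste(setdiff(algorithm_names, names(raw)), collapse = ", "))
    if (nrow(raw) == 0)
        return(cbind(data.frame(mirna = character(), gene = character(),
                                stringsAsFactors = FALSE),
                     stats::setNames(as.data.frame(
                         replicate(length(algorithm_names), numeric(),
                                   simplify = FALSE)), algorithm_names),
                     data.frame(validated = logical())))
    if (any(!nzchar(raw$mirna)) || any(!nzchar(raw$gene)))
        stop("empty mirna or gene identifier")
    key <- paste(raw$mirna, raw$gene, sep = "\t")
    if (anyDuplicated(key)) {
        d <- key[duplicated(key)][1L]
        stop("duplicate (miRNA, gene) pair: (",
             sub("\t", ", ", d, fixed = TRUE), ")")
    }
    scores <- lapply(algorithm_names, function(a) {
        cell <- raw[[a]]
        miss <- cell == missing_token | cell == ""
        val <- suppressWarnings(as.numeric(cell))
        bad <- which(!miss & is.na(val))
        if (length(bad))
            stop(sprintf("non-numeric score '%s' in column '%s' at line %d",
                         cell[bad[1L]], a, bad[1L] + 1L))
        val[miss] <- NA_real_
        val
    })
    out <- data.frame(mirna = raw$mirna, gene = raw$gene,
                      stringsAsFactors = FALSE)
    out[algorithm_names] <- scores
    out$validated <- FALSE
    out
}

#' Write a prediction table in the dialect [readPredictions()] consumes
#'
#' @param records data.frame as returned by [readPredictions()].
#' @param path output TSV path.
#' @param missing_token string written for \code{NA} scores.
#' @return invisibly, \code{path}.
#' @export
writePredictions <- function(records, path, missing_token = "NA") {
    out <- records[setdiff(names(records), "validated")]
    for (a in setdiff(names(out), c("mirna", "gene"))) {
        col <- ifelse(is.na(out[[a]]), missing_token,
                      format(out[[a]], trim = TRUE, digits = 15,
                             scientific = FALSE))
        out[[a]] <- col
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Flag experimentally validated pairs as positive labels
#'
#' @param records prediction table from [readPredictions()].
#' @param validated_pairs two-column data.frame (\code{mirna}, \code{gene}) or
#'   character matrix of validated pairs.
#' @return the table with \code{validated} set exactly for listed pairs, plus
#'   an attribute \code{"unmatched"}: the validated pairs not present among the
#'   records (reported, never silently dropped).
#' @export
markValidated <- function(records, validated_pairs) {
    vp <- as.data.frame(validated_pairs, stringsAsFactors = FALSE)
    if (ncol(vp) < 2 && nrow(vp) > 0)
        stop("validated_pairs needs (mirna, gene) columns")
    key <- paste(records$mirna, records$gene, sep = "\t")
    vkey <- if (nrow(vp)) unique(paste(vp[[1L]], vp[[2L]], sep = "\t"))
            else character()
    records$validated <- key %in% vkey
    un <- setdiff(vkey, key)
    unmatched <- if (length(un)) {
        parts <- strsplit(un, "\t", fixed = TRUE)
        data.frame(mirna = vapply(parts, `[`, "", 1L),
                   gene = vapply(parts, `[`, "", 2L),
                   stringsAsFactors = FALSE)
    } else data.frame(mirna = character(), gene = character(),
                      stringsAsFactors = FALSE)
    attr(records, "unmatched") <- unmatched
    records
}

#' Read a two-column validated-interaction list
#'
#' @param path TSV with columns \code{mirna} and \code{gene} (header optional
#'   but recommended).
#' @return data.frame with \code{mirna} and \code{gene} columns.
#' @export
readValidated <- function(path) {
    first <- readLines(path, n = 1L)
    hdr <- grepl("^mirna\t", first)
    v <- utils::read.delim(path, header = hdr, sep = "\t",
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
    names(v)[1:2] <- c("mirna", "gene")
    v[, 1:2]
}

#' Build the weighted interaction matrix A
#'
#' @param mirna,gene,score parallel vectors: one candidate interaction per
#'   element, scores in \[0, 1\]. Alternatively \code{mirna} may be a
#'   data.frame holding all three columns.
#' @return an [InteractionMatrix-class] with lexicographically sorted indices.
#' @export
buildInteractionMatrix <- function(mirna, gene = NULL, score = NULL) {
    if (is.data.frame(mirna)) {
        df <- mirna
        mirna <- df[[1L]]; gene <- df[[2L]]; score <- df[[3L]]
    }
    score <- as.numeric(score)
    if (length(score) && (min(score) < 0 || max(score) > 1))
        stop("interaction scores must lie in [0, 1]")
    key <- paste(mirna, gene, sep = "\t")
    if (anyDuplicated(key))
        stop("duplicate (miRNA, gene) pair in matrix input")
    ridx <- sort(unique(as.character(mirna)))
    cidx <- sort(unique(as.character(gene)))
    m <- Matrix::sparseMatrix(
        i = match(mirna, ridx), j = match(gene, cidx), x = score,
        dims = c(length(ridx), length(cidx)),
        dimnames = list(ridx, cidx))
    methods::new("InteractionMatrix", scores = methods::as(m, "CsparseMatrix"))
}

#' Drop interactions below a reliability threshold
#'
#' Entries with score >= \code{threshold} are retained; the miRNA and gene
#' indices are unchanged, so rows or columns may become empty. Idempotent and
#' monotone: the retained-entry count is non-increasing in the threshold.
#'
#' @param matrix an [InteractionMatrix-class].
#' @param threshold reliability cutoff in \[0, 1\].
#' @return a filtered [InteractionMatrix-class] on the same indices.
#' @export
filterByScore <- function(matrix, threshold) {
    stopifnot(is(matrix, "InteractionMatrix"),
              threshold >= 0, threshold <= 1)
    m <- matrix@scores
    m@x[m@x < threshold] <- 0
    methods::new("InteractionMatrix", scores = Matrix::drop0(m))
}

#' @importFrom Matrix drop0
NULL

#' Export an interaction matrix as a three-column TSV
#'
#' @param matrix an [InteractionMatrix-class].
#' @param path output path; columns \code{mirna}, \code{gene}, \code{score}.
#' @return invisibly, \code{path}.
#' @export
writeInteractionMatrix <- function(matrix, path) {
    m <- methods::as(matrix@scores, "TsparseMatrix")
    o <- order(rownames(matrix@scores)[m@i + 1L],
               colnames(matrix@scores)[m@j + 1L])
    df <- data.frame(mirna = rownames(matrix@scores)[m@i + 1L][o],
                     gene = colnames(matrix@scores)[m@j + 1L][o],
                     score = format(m@x[o], trim = TRUE, digits = 15,
                                    scientific = FALSE),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a three-column interaction TSV back into a matrix
#'
#' @param path TSV with columns \code{mirna}, \code{gene}, \code{score}.
#' @return an [InteractionMatrix-class].
#' @export
readInteractionMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                            colClasses = c("character", "character",
                                           "numeric"),
                            fileEncoding = "UTF-8")
    buildInteractionMatrix(df$mirna, df$gene, df$score)
}
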