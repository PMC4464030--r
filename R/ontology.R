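#' @include AllClasses.R AllGenerics.R
NULL

.NS_MAP <- c(biological_process = "BP", molecular_function = "MF",
             cellular_component = "CC")

#' Read an ontology graph from an OBO 1.2 file
#'
#' Loads all \verb{[Term]} stanzas; obsolete terms are skipped; \code{is_a}
#' and \code{part_of} relationships are both kept as subsumption edges, other
#' relationships are ignored. The graph must be acyclic and every referenced
#' parent must itself be a loaded term.
#'
#' @param path an OBO 1.2 format file.
#' @return an [OntologyGraph-class].
#' @export
readOBO <- function(path) {
    lines <- readLines(path, warn = FALSE)
    terms <- character()
    parents <- list()
    namespace <- character()
    cur <- NULL
    cur_parents <- character()
    cur_ns <- NA_character_
    cur_obsolete <- FALSE
    in_term <- FALSE
    flush <- function() {
        if (!is.null(cur) && !cur_obsolete) {
            terms <<- c(terms, cur)
            parents[[cur]] <<- unique(cur_parents)
            namespace[cur] <<- cur_ns
        }
    }
    for (ln in lines) {
        ln <- sub("!.*$", "", ln)           # strip trailing comments
        ln <- trimws(ln)
        if (ln == "[Term]") {
            flush()
            in_term <- TRUE
            cur <- NULL; cur_parents <- character()
            cur_ns <- NA_character_; cur_obsolete <- FALSE
        } else if (grepl("^\\[", ln)) {      # [Typedef] etc.
            flush()
            in_term <- FALSE
            cur <- NULL
        } else if (in_term && nzchar(ln)) {
            if (grepl("^id:", ln)) {
                cur <- trimws(sub("^id:", "", ln))
            } else if (grepl("^is_a:", ln)) {
                cur_parents <- c(cur_parents,
                                 trimws(sub("^is_a:", "", ln)))
            } else if (grepl("^relationship:\\s*part_of\\s", ln)) {
                cur_parents <- c(
                    cur_parents,
                    trimws(sub("^relationship:\\s*part_of\\s+", "", ln)))
            } else if (grepl("^namespace:", ln)) {
                ns <- trimws(sub("^namespace:", "", ln))
                cur_ns <- unname(.NS_MAP[ns])
                if (is.na(cur_ns)) cur_ns <- ns
            } else if (grepl("^is_obsolete:\\s*true", ln)) {
                cur_obsolete <- TRUE
            }
        }
    }
    flush()
    if (anyDuplicated(terms)) stop("duplicate term id in OBO file")
    dangling <- setdiff(unique(unlist(parents)), terms)
    if (length(dangling))
        stop("dangling parent term(s): ",
             paste(utils::head(dangling, 5), collapse = ", "))
    g <- methods::new("OntologyGraph", terms = terms, parents = parents,
                      namespace = namespace)
    cyc <- .findCycle(g)
    if (!is.null(cyc))
        stop("ontology graph contains a cycle: ",
             paste(cyc, collapse = " -> "))
    g
}

## Kahn topological sort; returns one cycle (as a term path) or NULL
.findCycle <- function(graph) {
    indeg <- stats::setNames(integer(length(graph@terms)), graph@terms)
    children <- stats::setNames(
        vector("list", length(graph@terms)), graph@terms)
    for (t in graph@terms)
        for (p in graph@parents[[t]]) {
            indeg[t] <- indeg[t] + 1L
            children[[p]] <- c(children[[p]], t)
        }
    queue <- names(indeg)[indeg == 0L]
    seen <- 0L
    while (length(queue)) {
        t <- queue[1L]; queue <- queue[-1L]
        seen <- seen + 1L
        for (ch in children[[t]]) {
            indeg[ch] <- indeg[ch] - 1L
            if (indeg[ch] == 0L) queue <- c(queue, ch)
        }
    }
    if (seen == length(graph@terms)) return(NULL)
    ## walk parent edges inside the residual graph until a repeat
    residual <- names(indeg)[indeg > 0L]
    path <- residual[1L]
    repeat {
        nxt <- intersect(graph@parents[[path[length(path)]]], residual)[1L]
        if (nxt %in% path)
            return(c(path[which(path == nxt):length(path)], nxt))
        path <- c(path, nxt)
    }
}

#' Read gene annotations from a GAF 2.x file
#'
#' Keeps the gene symbol (column 3) and term id (column 5); rows whose
#' qualifier (column 4) contains \code{NOT} are dropped, as are rows naming a
#' term absent from \code{graph} (their count is attached as attribute
#' \code{"dropped_terms"}). Gene symbols are uppercased so matching against
#' interaction tables is deterministic.
#'
#' @param path GAF 2.x file; comment lines start with \code{!}.
#' @param graph the [OntologyGraph-class] the annotations refer to.
#' @return named list: gene symbol -> character vector of direct term ids.
#' @export
readGAF <- function(path, graph) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    direct <- list()
    dropped <- 0L
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 5)
            stop("malformed GAF line ", i, ": fewer than 5 columns")
        if (grepl("NOT", f[4L], fixed = TRUE)) next
        gene <- toupper(f[3L])
        term <- f[5L]
        if (!nzchar(gene) || !nzchar(term))
            stop("malformed GAF line ", i, ": empty gene or term")
        if (!term %in% graph@terms) {
            dropped <- dropped + 1L
            next
        }
        direct[[gene]] <- unique(c(direct[[gene]], term))
    }
    attr(direct, "dropped_terms") <- dropped
    direct
}

## ancestors (inclusive) of each term, memoized; restricted to the namespace
.ancestorClosure <- function(graph, ns_terms) {
    memo <- new.env(parent = emptyenv())
    anc <- function(t) {
        if (!is.null(memo[[t]])) return(memo[[t]])
        ps <- intersect(graph@parents[[t]], ns_terms)
        out <- t
        for (p in ps) out <- c(out, anc(p))
        out <- unique(out)
        memo[[t]] <- out
        out
    }
    stats::setNames(lapply(ns_terms, anc), ns_terms)
}

#' Close annotations over ancestors and score term information content
#'
#' Builds GO(x) for every gene by uniting its direct terms with all their
#' ancestors inside the chosen namespace, then scores every term with
#' IC(t) = -log p(t), where p(t) is the fraction of annotated genes whose
#' closed set contains t. Terms annotating no gene (p = 0) are absent from
#' the IC table; the namespace root has p = 1 and IC = 0.
#'
#' @param direct named list: gene -> direct term ids (see [readGAF()]).
#' @param graph the [OntologyGraph-class].
#' @param namespace namespace tag to restrict to (e.g. \code{"BP"}).
#' @param closed when \code{FALSE}, GO(x) keeps only the direct terms
#'   (ancestor closure is the conventional choice for SimGIC and the
#'   default).
#' @param log_base base of the IC logarithm (default e).
#' @return an [AnnotationStore-class].
#' @export
buildAnnotationStore <- function(direct, graph, namespace = "BP",
                                 closed = TRUE, log_base = exp(1)) {
    ns_terms <- graph@terms[graph@namespace == namespace &
                            !is.na(graph@namespace)]
    if (length(ns_terms) == 0)
        stop("no term in namespace ", namespace)
    dset <- lapply(direct, function(ts) intersect(ts, ns_terms))
    dset <- dset[vapply(dset, length, 0L) > 0]
    if (length(dset) == 0)
        stop("no annotation in namespace ", namespace)
    closure <- .ancestorClosure(graph, ns_terms)
    cset <- if (closed)
        lapply(dset, function(ts)
            sort(unique(unlist(closure[ts], use.names = FALSE))))
    else lapply(dset, sort)
    counts <- table(unlist(cset, use.names = FALSE))
    p <- as.numeric(counts) / length(cset)
    ic <- stats::setNames(-log(p, base = log_base), names(counts))
    ic[ic < 0] <- 0    # guard against -0
    methods::new("AnnotationStore", direct = dset, closed = cset, ic = ic,
                 namespace = namespace, logBase = log_base)
}

#' Export the information-content table
#'
#' @param store an [AnnotationStore-class].
#' @param path optional TSV output path; when \code{NULL} the table is only
#'   returned.
#' @return data.frame with columns \code{term}, \code{namespace}, \code{p},
#'   \code{ic}.
#' @export
icTable <- function(store, path = NULL) {
    p <- store@logBase^(-store@ic)
    df <- data.frame(term = names(store@ic), namespace = store@namespace,
                     p = p, ic = unname(store@ic),
                     stringsAsFactors = FALSE)
    df <- df[order(df$term), ]
    rownames(df) <- NULL
    if (!is.null(path))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, fileEncoding = "UTF-8")
    df
}

#' Ancestor-closed term sets of an annotation store
#' @param store an [AnnotationStore-class].
#' @param gene optional single gene; when missing, the full named list.
#' @return the closed term set(s).
#' @export
geneAnnotations <- function(store, gene) {
    if (missing(gene)) return(store@closed)
    store@closed[[gene]]
}
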