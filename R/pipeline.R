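#' @include AllClasses.R AllGenerics.R biclique.R hierarchy.R ranking.R
NULL

#' Export a hierarchy (with manifest) as JSON
#'
#' The JSON carries a manifest (alpha, beta, package version, extra fields),
#' every level's biclusters (id, members, compactness), the parent links and
#' the merge-time compactness of every merged parent. Export followed by
#' [readHierarchyJSON()] is lossless.
#'
#' @param hierarchy a [Hierarchy-class].
#' @param path output path.
#' @param manifest named list of extra manifest fields (seeds, inputs, ...).
#' @return invisibly, \code{path}.
#' @export
writeHierarchyJSON <- function(hierarchy, path, manifest = list()) {
    obj <- list(
        manifest = c(list(alpha = hierarchy@alpha, beta = hierarchy@beta,
                          n_levels = length(hierarchy@levels),
                          generator = paste0("mgrnet ", as.character(
                              utils::packageVersion("mgrnet")))),
                     manifest),
        levels = lapply(hierarchy@levels, function(lv)
            lapply(lv, function(b)
                list(id = b@id, level = b@level, genes = as.list(b@genes),
                     mirnas = as.list(b@mirnas),
                     compactness = b@compactness))),
        parents = as.list(hierarchy@parents),
        merge_q = as.list(hierarchy@mergeQ))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Read a hierarchy back from its JSON export
#'
#' @param path a file written by [writeHierarchyJSON()].
#' @return a [Hierarchy-class].
#' @export
readHierarchyJSON <- function(path) {
    obj <- jsonlite::read_json(path)
    levels <- lapply(obj$levels, function(lv)
        lapply(lv, function(b)
            methods::new("Bicluster", id = b$id,
                         genes = sort(unlist(b$genes) %||% character()),
                         mirnas = sort(unlist(b$mirnas) %||% character()),
                         level = as.integer(b$level),
                         compactness = as.numeric(b$compactness))))
    methods::new("Hierarchy", levels = levels,
                 parents = unlist(obj$parents) %||%
                     stats::setNames(character(), character()),
                 mergeQ = unlist(obj$merge_q) %||%
                     stats::setNames(numeric(), character()),
                 alpha = as.numeric(obj$manifest$alpha),
                 beta = as.numeric(obj$manifest$beta %||% NA_real_))
}

#' Query biclusters of a ranked hierarchy
#'
#' Filters compose in AND: a bicluster is returned only if it satisfies every
#' provided filter. Member filters (genes and/or miRNAs) use AND by default
#' (all listed members must belong to the bicluster) with an OR switch.
#'
#' @param hierarchy a [Hierarchy-class].
#' @param ranking data.frame from [rankHierarchy()] (or [rankLevel()]); when
#'   \code{NULL}, a minimal table is derived from the hierarchy and p-value
#'   filters are unavailable.
#' @param levels integer vector of levels to keep.
#' @param max_p_bp,max_p_mf p-value ceilings.
#' @param min_compactness compactness floor.
#' @param members character vector of gene symbols and/or miRNA ids.
#' @param member_logic \code{"and"} (default) or \code{"or"}.
#' @param id exact bicluster id filter; an unknown id yields an empty result
#'   with a message.
#' @return filtered data.frame, sortable by any column.
#' @export
queryBiclusters <- function(hierarchy, ranking = NULL, levels = NULL,
                            max_p_bp = NULL, max_p_mf = NULL,
                            min_compactness = NULL, members = NULL,
                            member_logic = c("and", "or"), id = NULL) {
    stopifnot(is(hierarchy, "Hierarchy"))
    member_logic <- match.arg(member_logic)
    if (is.null(ranking)) {
        ranking <- do.call(rbind, lapply(hierarchy@levels, function(lv)
            do.call(rbind, lapply(lv, function(b)
                data.frame(id = b@id, level = b@level,
                           compactness = b@compactness,
                           p_bp = NA_real_, p_mf = NA_real_,
                           n_genes = length(b@genes),
                           n_mirnas = length(b@mirnas),
                           stringsAsFactors = FALSE)))))
    }
    out <- ranking
    if (!is.null(levels)) out <- out[out$level %in% levels, ]
    if (!is.null(max_p_bp)) out <- out[!is.na(out$p_bp) &
                                       out$p_bp <= max_p_bp, ]
    if (!is.null(max_p_mf)) out <- out[!is.na(out$p_mf) &
                                       out$p_mf <= max_p_mf, ]
    if (!is.null(min_compactness))
        out <- out[out$compactness >= min_compactness, ]
    if (!is.null(id)) {
        if (!id %in% out$id) {
            message("bicluster id '", id, "' not found")
            return(out[0, ])
        }
        out <- out[out$id == id, ]
    }
    if (!is.null(members) && nrow(out)) {
        lut <- list()
        for (lv in hierarchy@levels)
            for (b in lv)
                lut[[paste0(b@level, ":", b@id)]] <- c(b@genes, b@mirnas)
        keep <- vapply(seq_len(nrow(out)), function(r) {
            mem <- lut[[paste0(out$level[r], ":", out$id[r])]]
            if (is.null(mem)) return(FALSE)
            hit <- members %in% mem
            if (member_logic == "and") all(hit) else any(hit)
        }, logical(1))
        out <- out[keep, ]
    }
    rownames(out) <- NULL
    out
}

#' Export one bicluster as a bipartite interaction graph
#'
#' Nodes are the bicluster's miRNAs and genes; edges are their recorded
#' interactions with score at least \code{min_edge_score}, the score kept as
#' an edge attribute. With \code{hide_isolated}, nodes of degree 0 after
#' filtering are removed.
#'
#' @param bicluster a [Bicluster-class].
#' @param A the [InteractionMatrix-class].
#' @param min_edge_score minimum score for an edge to be drawn (default 0).
#' @param hide_isolated drop zero-degree nodes (default \code{FALSE}).
#' @param path optional output file (GraphML).
#' @return an \code{igraph} bipartite graph (invisibly when \code{path} is
#'   given).
#' @export
exportNetwork <- function(bicluster, A, min_edge_score = 0,
                          hide_isolated = FALSE, path = NULL) {
    stopifnot(is(bicluster, "Bicluster"), is(A, "InteractionMatrix"))
    sub <- A@scores[bicluster@mirnas, bicluster@genes, drop = FALSE]
    idx <- which(as.matrix(sub) >= min_edge_score &
                 as.matrix(sub) > 0, arr.ind = TRUE)
    edges <- data.frame(from = rownames(sub)[idx[, 1]],
                        to = colnames(sub)[idx[, 2]],
                        score = as.matrix(sub)[idx],
                        stringsAsFactors = FALSE)
    vertices <- data.frame(
        name = c(bicluster@mirnas, bicluster@genes),
        type = rep(c(TRUE, FALSE),
                   c(length(bicluster@mirnas), length(bicluster@genes))),
        kind = rep(c("mirna", "gene"),
                   c(length(bicluster@mirnas), length(bicluster@genes))),
        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = vertices)
    if (hide_isolated)
        g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
    if (!is.null(path)) {
        igraph::write_graph(g, path, format = "graphml")
        return(invisible(g))
    }
    g
}

#' Export a hierarchy as a GraphML tree
#'
#' Nodes are biclusters (keyed \code{"<level>:<id>"}, with size and
#' compactness attributes); edges are child -> parent links.
#'
#' @param hierarchy a [Hierarchy-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
exportHierarchyGraphML <- function(hierarchy, path) {
    nodes <- do.call(rbind, lapply(hierarchy@levels, function(lv)
        do.call(rbind, lapply(lv, function(b)
            data.frame(name = paste0(b@level, ":", b@id), level = b@level,
                       n_genes = length(b@genes),
                       n_mirnas = length(b@mirnas),
                       compactness = b@compactness,
                       stringsAsFactors = FALSE)))))
    pl <- hierarchy@parents
    pl <- pl[pl != names(pl) & pl %in% nodes$name & names(pl) %in% nodes$name]
    edges <- data.frame(from = names(pl), to = unname(pl),
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

#' Run the full pipeline: combine, bicluster, rank
#'
#' Orchestrates the three stages end to end and writes an artifact bundle:
#' the combined per-pair reliability scores (TSV), the bicluster hierarchy
#' (JSON), the functional ranking (TSV, when an ontology and annotations are
#' supplied) and a manifest recording every parameter and seed. Re-running
#' with an identical configuration reproduces identical outputs.
#'
#' @param config named list:
#'   \describe{
#'     \item{predictions}{path to the prediction-score TSV (required).}
#'     \item{validated}{path to the validated-pair TSV (required for
#'       \code{method = "pu"}).}
#'     \item{method}{\code{"pu"} (default), \code{"sa"} or \code{"wsa"}.}
#'     \item{weights}{numeric algorithm weights (\code{"wsa"} only).}
#'     \item{K, seed, holdout_fraction}{PU combiner settings.}
#'     \item{beta, alpha, max_levels}{biclustering settings (defaults 0.5,
#'       0.3, 10).}
#'     \item{obo, gaf}{optional ontology + annotation paths enabling the
#'       ranking stage.}
#'     \item{cap}{similarity-sample cap (default 2000).}
#'     \item{out_dir}{output directory (required).}
#'   }
#' @return list with the scored records, the interaction matrix, the
#'   hierarchy, the ranking (or \code{NULL}) and the manifest, plus files in
#'   \code{out_dir}.
#' @export
runPipeline <- function(config) {
    required <- c("predictions", "out_dir")
    miss <- setdiff(required, names(config))
    if (length(miss))
        stop("missing config field(s): ", paste(miss, collapse = ", "))
    method <- config$method %||% "pu"
    if (method == "pu" && is.null(config$validated))
        stop("method 'pu' needs a validated-interaction list")
    for (f in c("predictions", "validated", "obo", "gaf"))
        if (!is.null(config[[f]]) && !file.exists(config[[f]]))
            stop("input file not found: ", config[[f]])
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(config$seed %||% 1L)
    K <- config$K %||% 10
    beta <- config$beta %||% 0.5
    alpha <- config$alpha %||% 0.3
    max_levels <- config$max_levels %||% 10
    cap <- config$cap %||% 2000

    message("reading predictions: ", config$predictions)
    rec <- readPredictions(config$predictions)
    if (!is.null(config$validated))
        rec <- markValidated(rec, readValidated(config$validated))
    algo <- setdiff(names(rec), c("mirna", "gene", "validated"))
    scores <- switch(
        method,
        pu = {
            data <- puDatasetFromRecords(rec)
            puCombine(data, K = K,
                      holdout_fraction = config$holdout_fraction %||% 0.2,
                      seed = seed)$scores
        },
        sa = as.numeric(baselineSA(rec[algo])),
        wsa = baselineWSA(rec[algo],
                          config$weights %||% rep(1, length(algo))),
        stop("unknown method: ", method))
    message(sprintf("combined %d pairs (%d validated) with method '%s'",
                    nrow(rec), sum(rec$validated), method))
    A <- buildInteractionMatrix(rec$mirna, rec$gene, scores)
    scores_path <- file.path(config$out_dir, "scores.tsv")
    writeInteractionMatrix(A, scores_path)

    step1 <- extractBicliques(A, beta)
    message(sprintf("step 1: %d biclique(s), %d isolated miRNA(s), %d isolated gene(s)",
                    length(step1$bicliques), length(step1$isolated$mirnas),
                    length(step1$isolated$genes)))
    if (length(step1$bicliques) == 0)
        stop("no biclique survived step 1; lower beta")
    h <- buildHierarchy(step1$bicliques, A, alpha = alpha, beta = beta,
                        max_levels = max_levels)
    message(sprintf("hierarchy: %d level(s)", length(h@levels)))
    manifest <- list(method = method, K = K, seed = seed, alpha = alpha,
                     beta = beta, max_levels = max_levels, cap = cap,
                     predictions = basename(config$predictions))
    hier_path <- file.path(config$out_dir, "hierarchy.json")
    writeHierarchyJSON(h, hier_path, manifest)

    ranking <- NULL
    if (!is.null(config$obo) && !is.null(config$gaf)) {
        graph <- readOBO(config$obo)
        direct <- readGAF(config$gaf, graph)
        store_bp <- tryCatch(buildAnnotationStore(direct, graph, "BP"),
                             error = function(e) NULL)
        store_mf <- tryCatch(buildAnnotationStore(direct, graph, "MF"),
                             error = function(e) NULL)
        if (is.null(store_bp) && !is.null(store_mf)) {
            store_bp <- store_mf; store_mf <- NULL
        }
        if (!is.null(store_bp)) {
            ranking <- rankHierarchy(h, store_bp, store_mf, cap = cap,
                                     seed = seed)
            utils::write.table(
                ranking, file.path(config$out_dir, "ranking.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            message(sprintf("ranked %d bicluster-level entries",
                            nrow(ranking)))
        }
    }
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(records = rec, scores = scores, matrix = A, hierarchy = h,
         ranking = ranking, manifest = manifest)
}
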