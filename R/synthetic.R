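#' @include AllClasses.R AllGenerics.R utils.R interaction-io.R
NULL

#' Design of a planted-bicluster interaction matrix
#'
#' Describes the ground truth of a synthetic score matrix: disjoint
#' consecutive miRNA x gene modules whose in-module scores are drawn from
#' \code{signal_range} while background cells are drawn from
#' \code{noise_range} (and sparsified). Separability is controlled
#' explicitly: the signal lower bound must exceed the noise upper bound.
#'
#' @param n_mirna,n_mrna matrix dimensions.
#' @param modules either \code{NULL} (laid out automatically from
#'   \code{n_modules} x \code{mirnas_per_module} x \code{mrnas_per_module})
#'   or a list of \code{list(mirnas = <indices>, genes = <indices>)}.
#' @param n_modules,mirnas_per_module,mrnas_per_module automatic layout:
#'   consecutive disjoint blocks.
#' @param signal_range,noise_range uniform score ranges, subsets of \[0, 1\]
#'   with \code{signal_range[1] > noise_range[2]}.
#' @param overlap_fraction fraction of each module's miRNAs also planted into
#'   the next module (cyclically), in \[0, 1).
#' @param seed integer seed.
#' @return a \code{"PlantedDesign"} list.
#' @export
plantedDesign <- function(n_mirna, n_mrna, modules = NULL, n_modules = 4,
                          mirnas_per_module = 10, mrnas_per_module = 40,
                          signal_range = c(0.7, 1.0),
                          noise_range = c(0.0, 0.2),
                          overlap_fraction = 0, seed = 1) {
    if (is.null(modules)) {
        stopifnot(n_modules * mirnas_per_module <= n_mirna,
                  n_modules * mrnas_per_module <= n_mrna)
        modules <- lapply(seq_len(n_modules), function(m)
            list(mirnas = ((m - 1) * mirnas_per_module + 1):
                     (m * mirnas_per_module),
                 genes = ((m - 1) * mrnas_per_module + 1):
                     (m * mrnas_per_module)))
    }
    for (mod in modules) {
        if (max(mod$mirnas) > n_mirna || max(mod$genes) > n_mrna ||
            min(mod$mirnas) < 1 || min(mod$genes) < 1)
            stop("module indices outside the matrix bounds")
    }
    if (signal_range[1] <= noise_range[2])
        stop("signal range must lie strictly above the noise range")
    if (overlap_fraction < 0 || overlap_fraction >= 1)
        stop("overlap_fraction must be in [0, 1)")
    structure(list(n_mirna = n_mirna, n_mrna = n_mrna, modules = modules,
                   signal_range = signal_range, noise_range = noise_range,
                   overlap_fraction = overlap_fraction, seed = seed),
              class = "PlantedDesign")
}

#' Generate a planted-bicluster interaction matrix
#'
#' Background cells are drawn uniformly from the design's noise range and
#' sparsified (values below 0.05 are dropped, keeping the matrix sparse like
#' real prediction data); in-module cells are drawn uniformly from the signal
#' range. When \code{overlap_fraction > 0}, the leading fraction of each
#' module's miRNAs is additionally planted into the next module (cyclically),
#' producing overlapping ground-truth modules. A pure function of the
#' design's seed and parameters.
#'
#' @param design a [plantedDesign()].
#' @param sparsify_below background scores below this value become absent
#'   (default 0.05).
#' @return list with \code{matrix} (an [InteractionMatrix-class]) and
#'   \code{truth}: per module, the planted miRNA and gene name sets.
#' @export
plantedMatrix <- function(design, sparsify_below = 0.05) {
    stopifnot(inherits(design, "PlantedDesign"))
    rng <- .seededRNG(design$seed)
    ## uppercase gene symbols so GAF-normalized annotations match directly
    mir <- sprintf("mir%04d", seq_len(design$n_mirna))
    gen <- sprintf("G%04d", seq_len(design$n_mrna))
    M <- matrix(.rngRunif(rng, design$n_mirna * design$n_mrna,
                          design$noise_range[1], design$noise_range[2]),
                design$n_mirna, design$n_mrna)
    M[M < sparsify_below] <- 0
    truth <- vector("list", length(design$modules))
    planted <- lapply(design$modules, function(mod) mod$mirnas)
    nmod <- length(design$modules)
    if (design$overlap_fraction > 0 && nmod > 1) {
        for (m in seq_len(nmod)) {
            nxt <- if (m == nmod) 1L else m + 1L
            k <- ceiling(design$overlap_fraction *
                         length(design$modules[[m]]$mirnas))
            planted[[nxt]] <- unique(c(planted[[nxt]],
                design$modules[[m]]$mirnas[seq_len(k)]))
        }
    }
    for (m in seq_len(nmod)) {
        rows <- sort(planted[[m]])
        cols <- design$modules[[m]]$genes
        M[rows, cols] <- .rngRunif(rng, length(rows) * length(cols),
                                   design$signal_range[1],
                                   design$signal_range[2])
        truth[[m]] <- list(mirnas = mir[rows], genes = gen[cols])
    }
    idx <- which(M > 0, arr.ind = TRUE)
    A <- buildInteractionMatrix(mir[idx[, 1]], gen[idx[, 2]], M[idx])
    list(matrix = A, truth = truth)
}

#' Generate a positive-unlabeled score dataset with hidden truth
#'
#' True classes are Bernoulli(\code{prior}); feature vectors are independent
#' per-dimension uniforms on shifted intervals -- positives on
#' \code{U(separation, 1)}, negatives on \code{U(0, 1 - separation)} -- so
#' class overlap is controlled directly by \code{separation} (0 = identical
#' distributions, >= 0.5 = disjoint supports). Positives are labeled with
#' constant probability \code{label_frequency_c}, independent of the features
#' (the selected-completely-at-random mechanism); everything else is
#' unlabeled. The hidden truth is returned for evaluation only.
#'
#' @param n number of examples.
#' @param d number of score features.
#' @param prior true positive-class probability, in (0, 1).
#' @param label_frequency_c probability that a true positive is labeled.
#' @param separation class-conditional shift in \[0, 1\].
#' @param seed integer seed.
#' @return a [PUDataset-class] with slot \code{truth} filled.
#' @export
puScores <- function(n, d = 2, prior = 0.5, label_frequency_c = 0.5,
                     separation = 0.6, seed = 1) {
    stopifnot(prior > 0, prior < 1, label_frequency_c > 0,
              label_frequency_c <= 1, separation >= 0, separation <= 1)
    rng <- .seededRNG(seed)
    truth <- .rngRbinom(rng, n, prior) == 1L
    X <- matrix(.rngRunif(rng, n * d), n, d)
    s <- separation
    X[truth, ] <- s + X[truth, , drop = FALSE] * (1 - s)
    X[!truth, ] <- X[!truth, , drop = FALSE] * (1 - s)
    labeled <- truth & (.rngRbinom(rng, n, label_frequency_c) == 1L)
    colnames(X) <- paste0("algo", seq_len(d))
    puDataset(X, labeled, truth = truth)
}

#' Generate a toy ontology with controlled term sharing
#'
#' Builds a random tree-structured DAG of the stated depth (a root chain
#' guarantees the depth; remaining terms attach to random non-leaf-level
#' terms). Genes belonging to a coherent group share a dedicated deep
#' (high-IC) term planted as a fresh leaf, plus random terms; all other genes
#' are annotated with random terms only. A pure function of the seed.
#'
#' @param n_terms number of tree terms (>= depth).
#' @param depth tree depth (root = depth 1).
#' @param n_genes number of genes (named \code{GENE0001}, ...).
#' @param coherent_groups list of gene index vectors (or gene names); each
#'   group gets one dedicated leaf term shared by all its members.
#' @param seed integer seed.
#' @param terms_per_gene random direct annotations per gene (default 3).
#' @param namespace namespace tag for every term (default \code{"BP"}).
#' @param gene_names optional explicit gene names (length \code{n_genes}),
#'   e.g. to align with a planted interaction matrix.
#' @return list with \code{graph} (an [OntologyGraph-class]), \code{direct}
#'   (gene -> direct terms), \code{group_terms} (dedicated term per group)
#'   and \code{genes}.
#' @export
toyOntology <- function(n_terms, depth, n_genes, coherent_groups = list(),
                        seed = 1, terms_per_gene = 3, namespace = "BP",
                        gene_names = NULL) {
    stopifnot(n_terms >= depth, depth >= 1, n_genes >= 1)
    rng <- .seededRNG(seed)
    ids <- sprintf("%s:%04d", namespace, seq_len(n_terms))
    parents <- stats::setNames(vector("list", n_terms), ids)
    level <- integer(n_terms)
    level[1] <- 1L
    if (depth > 1)
        for (i in 2:depth) {
            parents[[ids[i]]] <- ids[i - 1L]
            level[i] <- i
        }
    if (n_terms > depth)
        for (i in (depth + 1L):n_terms) {
            eligible <- which(level[seq_len(i - 1L)] < depth)
            p <- eligible[.rngSampleInt(rng, length(eligible), 1L)]
            parents[[ids[i]]] <- ids[p]
            level[i] <- level[p] + 1L
        }
    if (is.null(gene_names))
        gene_names <- sprintf("GENE%04d", seq_len(n_genes))
    stopifnot(length(gene_names) == n_genes)
    ## dedicated leaf terms for coherent groups, attached as deep as possible
    group_terms <- character(length(coherent_groups))
    if (length(coherent_groups)) {
        deep <- which(level == max(level))
        for (gi in seq_along(coherent_groups)) {
            tid <- sprintf("%s:G%03d", namespace, gi)
            p <- deep[.rngSampleInt(rng, length(deep), 1L)]
            parents[[tid]] <- ids[p]
            ids <- c(ids, tid)
            level <- c(level, level[p] + 1L)
            group_terms[gi] <- tid
        }
    }
    direct <- stats::setNames(vector("list", n_genes), gene_names)
    tree_terms <- sprintf("%s:%04d", namespace, seq_len(n_terms))
    for (g in seq_len(n_genes))
        direct[[g]] <- unique(tree_terms[
            .rngSampleInt(rng, n_terms, min(terms_per_gene, n_terms),
                          replace = FALSE)])
    for (gi in seq_along(coherent_groups)) {
        grp <- coherent_groups[[gi]]
        members <- if (is.character(grp)) grp else gene_names[grp]
        for (g in members)
            direct[[g]] <- unique(c(direct[[g]], group_terms[gi]))
    }
    graph <- methods::new(
        "OntologyGraph", terms = ids, parents = parents,
        namespace = stats::setNames(rep(namespace, length(ids)), ids))
    list(graph = graph, direct = direct, group_terms = group_terms,
         genes = gene_names)
}

#' Write an ontology graph as an OBO 1.2 file
#'
#' @param graph an [OntologyGraph-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeOBO <- function(graph, path) {
    rev_ns <- stats::setNames(names(.NS_MAP), .NS_MAP)
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines("format-version: 1.2", con)
    for (t in graph@terms) {
        writeLines(c("", "[Term]", paste0("id: ", t)), con)
        ns <- graph@namespace[t]
        if (!is.na(ns)) {
            long <- rev_ns[ns]
            writeLines(paste0("namespace: ",
                              if (is.na(long)) ns else long), con)
        }
        for (p in graph@parents[[t]])
            writeLines(paste0("is_a: ", p), con)
    }
    invisible(path)
}

#' Write direct annotations as a minimal GAF 2.2 file
#'
#' @param direct named list: gene -> direct term ids.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGAF <- function(direct, path) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines("!gaf-version: 2.2", con)
    for (g in names(direct))
        for (t in direct[[g]])
            writeLines(paste(c("MGRNET", g, g, "", t, "PMID:0", "IEA", "",
                               "P", "", "", "protein", "taxon:9606",
                               "20260101", "MGRNET", "", ""),
                             collapse = "\t"), con)
    invisible(path)
}
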