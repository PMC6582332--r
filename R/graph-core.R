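# Co-expression graph container and the clique-based bicluster machinery.
#
# A tuba_graph stores edges as a canonical data.frame (gene1 < gene2, rows
# sorted) plus a parallel list of shared-sample sets, so that every
# transformation (pruning, trimming) is deterministic and the graph can be
# rebuilt bit-identically from the same inputs.

new_tuba_graph <- function(edges, shared, meta = list()) {
  stopifnot(is.data.frame(edges), length(shared) == nrow(edges))
  structure(
    list(edges = edges, shared = shared,
         genes = sort(unique(c(edges$gene1, edges$gene2))), meta = meta),
    class = "tuba_graph"
  )
}

#' Construct a co-expression graph from a plain edge list
#'
#' Generic ingestion path: any simple undirected edge list over gene
#' identifiers (for example, a thresholded correlation network built outside
#' this package) can be fed to the clique machinery. Self-loops are an error;
#' duplicate edges are collapsed.
#'
#' @param edges Data frame whose first two columns are gene identifiers;
#'   optional columns `m`, `p_raw`, `p_adj` are carried along.
#' @param shared Optional list (one element per edge row) of shared-sample
#'   character vectors; defaults to empty sets.
#' @param meta Optional provenance list.
#' @return A `"tuba_graph"`.
#' @export
as_tuba_graph <- function(edges, shared = NULL, meta = list()) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  g1 <- as.character(edges[[1]]); g2 <- as.character(edges[[2]])
  if (any(g1 == g2)) stop("self-loops are not allowed")
  flip <- g1 > g2
  tmp <- g1[flip]; g1[flip] <- g2[flip]; g2[flip] <- tmp
  grab <- function(col, na) if (col %in% names(edges)) edges[[col]] else rep(na, length(g1))
  e <- data.frame(gene1 = g1, gene2 = g2,
                  m = grab("m", NA_integer_),
                  p_raw = grab("p_raw", NA_real_),
                  p_adj = grab("p_adj", NA_real_),
                  stringsAsFactors = FALSE)
  if (is.null(shared)) shared <- rep(list(character(0)), nrow(e))
  dup <- duplicated(paste(e$gene1, e$gene2, sep = "\r"))
  e <- e[!dup, , drop = FALSE]
  shared <- shared[!dup]
  ord <- order(e$gene1, e$gene2)
  e <- e[ord, , drop = FALSE]
  rownames(e) <- NULL
  new_tuba_graph(e, shared[ord], meta)
}

#' @export
print.tuba_graph <- function(x, ...) {
  cat(sprintf("Co-expression graph: %d genes, %d edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

subset_graph <- function(graph, keep_rows) {
  new_tuba_graph(
    {e <- graph$edges[keep_rows, , drop = FALSE]; rownames(e) <- NULL; e},
    graph$shared[keep_rows], graph$meta)
}

# igraph view of a tuba_graph (vertex names = gene ids)
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges[, c("gene1", "gene2")],
                                directed = FALSE)
}

#' Prune a graph to its triangle-supported core
#'
#' Iteratively removes every edge that is part of no triangle (3-clique) until
#' a fixed point is reached, then drops isolated nodes. The result is the
#' maximal subgraph in which every edge lies in at least one triangle -- the
#' graph whose elementary units are triangles, which is the precondition for
#' seed discovery.
#'
#' @param graph A `"tuba_graph"`.
#' @return A `"tuba_graph"` (possibly with zero edges).
#' @export
prune_to_triangles <- function(graph) {
  stopifnot(inherits(graph, "tuba_graph"))
  repeat {
    e <- graph$edges
    if (!nrow(e)) return(graph)
    genes <- graph$genes
    i <- match(e$gene1, genes); j <- match(e$gene2, genes)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(length(genes), length(genes)))
    P <- A %*% A  # P[u,v] = number of common neighbours of u and v
    in_tri <- P[cbind(i, j)] > 0
    if (all(in_tri)) return(graph)
    graph <- subset_graph(graph, in_tri)
  }
}

#' All maximum cliques of the graph
#'
#' Enumerates every clique of maximum size using the Bron-Kerbosch algorithm
#' (via igraph). Cliques are returned as sorted character vectors in
#' lexicographic order, so the result is canonical.
#'
#' @param graph A `"tuba_graph"`.
#' @return List of character vectors (possibly empty).
#' @export
find_maximum_cliques <- function(graph) {
  stopifnot(inherits(graph, "tuba_graph"))
  if (!nrow(graph$edges)) return(list())
  cl <- igraph::largest_cliques(as_igraph(graph))
  cl <- lapply(cl, function(v) sort(names(v)))
  cl[order(vapply(cl, paste, "", collapse = "\r"))]
}

#' Form a seed from the maximum cliques
#'
#' When the maximum clique is not unique, all equally large cliques with a
#' non-zero intersection of their nodes are merged: cliques are nodes of an
#' overlap graph (adjacent iff they share a gene), and the seed is the union
#' of the genes in the connected component containing the canonically smallest
#' gene identifier. Remaining components surface as seeds in later
#' iterations.
#'
#' @param max_cliques Non-empty list of equal-size cliques (character vectors).
#' @return A `"tuba_seed"`: list with `genes` (sorted), `member_cliques`,
#'   `discovery_index` (NA until assigned by [extract_seeds()]).
#' @export
form_seed <- function(max_cliques) {
  stopifnot(length(max_cliques) >= 1)
  sizes <- lengths(max_cliques)
  stopifnot(length(unique(sizes)) == 1L)
  nc <- length(max_cliques)
  # connected components of the clique-overlap graph (union-find)
  parent <- seq_len(nc)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nc > 1) {
    for (a in seq_len(nc - 1)) for (b in seq((a + 1), nc)) {
      if (length(intersect(max_cliques[[a]], max_cliques[[b]]))) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  comp <- vapply(seq_len(nc), find, 0L)
  smallest <- min(unlist(max_cliques))
  has_smallest <- which(vapply(max_cliques,
                               function(cl) smallest %in% cl, TRUE))[1]
  sel <- comp == comp[has_smallest]
  structure(
    list(genes = sort(unique(unlist(max_cliques[sel]))),
         member_cliques = max_cliques[sel],
         discovery_index = NA_integer_),
    class = "tuba_seed"
  )
}

#' Trim the graph after a seed is extracted
#'
#' Removes every edge incident to a seed gene, then re-applies
#' [prune_to_triangles()] so the remaining graph again has triangles as its
#' elementary units before the next seed is sought.
#'
#' @param graph A `"tuba_graph"`.
#' @param seed A `"tuba_seed"` (or character vector of genes).
#' @return A `"tuba_graph"`.
#' @export
trim_graph <- function(graph, seed) {
  genes <- if (inherits(seed, "tuba_seed")) seed$genes else as.character(seed)
  keep <- !(graph$edges$gene1 %in% genes | graph$edges$gene2 %in% genes)
  prune_to_triangles(subset_graph(graph, keep))
}

#' Iteratively extract all seeds from a pruned graph
#'
#' Alternates maximum-clique discovery, seed formation and trimming until the
#' graph has no edges left. Seeds carry their discovery order and are pairwise
#' disjoint in genes.
#'
#' @param graph A triangle-pruned `"tuba_graph"`.
#' @return List of `"tuba_seed"` objects in discovery order.
#' @export
extract_seeds <- function(graph) {
  stopifnot(inherits(graph, "tuba_graph"))
  seeds <- list()
  i <- 0L
  while (nrow(graph$edges) > 0) {
    s <- form_seed(find_maximum_cliques(graph))
    i <- i + 1L
    s$discovery_index <- i
    seeds[[i]] <- s
    n_before <- nrow(graph$edges)
    graph <- trim_graph(graph, s)
    stopifnot(nrow(graph$edges) < n_before)  # termination guarantee
  }
  seeds
}

#' Expand a seed into a bicluster
#'
#' Reintroduces the seed into the original triangle-pruned graph and adds, in
#' a single pass, every node that shares edges with at least two seed genes.
#' The bicluster's edges are the pruned graph's induced edges on the final
#' gene set, its samples the union of the edges' shared-sample sets, and each
#' gene's degree its edge count within the induced subgraph.
#'
#' @param seed A `"tuba_seed"`.
#' @param pruned_graph The triangle-pruned graph before any trimming.
#' @return A `"tuba_bicluster"`: list with `genes`, `seed_genes`,
#'   `samples`, `edges`, `shared`, `degrees`, `discovery_index`.
#' @export
expand_seed <- function(seed, pruned_graph) {
  stopifnot(inherits(seed, "tuba_seed"), inherits(pruned_graph, "tuba_graph"))
  e <- pruned_graph$edges
  sg <- seed$genes
  touch1 <- e$gene1 %in% sg
  touch2 <- e$gene2 %in% sg
  outside <- c(e$gene2[touch1 & !touch2], e$gene1[touch2 & !touch1])
  added <- names(which(table(outside) >= 2))
  genes <- sort(unique(c(sg, added)))
  keep <- e$gene1 %in% genes & e$gene2 %in% genes
  edges <- e[keep, , drop = FALSE]
  rownames(edges) <- NULL
  shared <- pruned_graph$shared[keep]
  samp <- unique(unlist(shared, use.names = FALSE))
  deg <- table(factor(c(edges$gene1, edges$gene2), levels = genes))
  structure(
    list(genes = genes, seed_genes = sg, samples = sort(samp),
         edges = edges, shared = shared,
         degrees = stats::setNames(as.integer(deg), genes),
         discovery_index = seed$discovery_index),
    class = "tuba_bicluster"
  )
}

#' @export
print.tuba_bicluster <- function(x, ...) {
  cat(sprintf("Bicluster %s: %d genes (%d seed), %d samples, %d edges\n",
              if (is.na(x$discovery_index)) "?" else x$discovery_index,
              length(x$genes), length(x$seed_genes), length(x$samples),
              nrow(x$edges)))
  invisible(x)
}

#' Run the full biclustering pipeline
#'
#' Composes the pipeline: extremal-set computation, significance-filtered
#' graph construction, triangle pruning, iterative seed extraction, seed
#' expansion, and extremal-set enrichment scoring. Deterministic given the
#' input matrix and configuration.
#'
#' @param mat Numeric gene-by-sample matrix (see [read_expression()]).
#' @param config A `"tuba_config"`.
#' @param score If `TRUE` (default) attach per-gene/per-sample enrichment
#'   FDRs and the quality index Q to the collection.
#' @return A `"tuba_biclusters"` collection: list with `biclusters`,
#'   `config`, `gene_ids`, `sample_ids`, and (if scored) `gene_scores`,
#'   `sample_scores`, `quality`.
#' @export
#' @examples
#' sim <- default_benchmark(seed = 42, n_genes = 120, n_samples = 60,
#'                          n_implants = 1)
#' res <- run_tuba(sim$matrix, tuba_config(percentile = 0.1, cutoff = 1e-4))
run_tuba <- function(mat, config = tuba_config(), score = TRUE) {
  stopifnot(inherits(config, "tuba_config"))
  validate_expression(mat)
  sets <- compute_extremal_sets(mat, config$percentile, config$direction,
                                min_distinct = config$min_distinct)
  graph <- build_graph(sets, config$cutoff, config$cutoff_mode)
  pruned <- prune_to_triangles(graph)
  seeds <- extract_seeds(pruned)
  bics <- lapply(seeds, expand_seed, pruned_graph = pruned)
  coll <- structure(
    list(biclusters = bics, config = config,
         gene_ids = rownames(mat), sample_ids = colnames(mat),
         n_samples = ncol(mat)),
    class = "tuba_biclusters"
  )
  if (!length(bics)) {
    warning("no biclusters found at the configured cut-off")
    return(coll)
  }
  if (score) coll <- score_collection(coll, mat) else coll
}

#' @export
print.tuba_biclusters <- function(x, ...) {
  cat(sprintf("Bicluster collection: %d biclusters over %d genes x %d samples\n",
              length(x$biclusters), length(x$gene_ids), length(x$sample_ids)))
  if (length(x$biclusters)) {
    ng <- vapply(x$biclusters, function(b) length(b$genes), 0L)
    ns <- vapply(x$biclusters, function(b) length(b$samples), 0L)
    cat(sprintf("  gene-set sizes  : %s\n", paste(range(ng), collapse = "-")))
    cat(sprintf("  sample-set sizes: %s\n", paste(range(ns), collapse = "-")))
    if (!is.null(x$quality)) {
      cat(sprintf("  quality Q       : %s\n",
                  paste(format(range(x$quality), digits = 3), collapse = "-")))
    }
  }
  invisible(x)
}
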