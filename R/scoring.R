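# Enrichment scoring of bicluster genes and samples.
#
# Membership is never altered by scoring; the scores quantify how strongly
# each gene (sample) is tied to its bicluster through the extremal sets.

#' Score bicluster genes by extremal-set enrichment
#'
#' For a bicluster with sample set `S_B` of size `m`, each member gene's
#' top-m (or bottom-m, matching the run direction) sample set is tested for
#' enrichment in `S_B`: the raw p-value is the hypergeometric upper tail for
#' the overlap between the two m-sized sets drawn from the N samples.
#' Returned p-values are raw; family-wise BH adjustment across all
#' (gene, bicluster) pairs of a run is performed by [score_collection()].
#'
#' @param bicluster A `"tuba_bicluster"`.
#' @param rank_mat Extremality rank matrix from [extremal_rank_matrix()]
#'   (rows must cover the bicluster genes).
#' @return Data frame: `gene`, `overlap`, `p_raw`.
#' @export
score_genes <- function(bicluster, rank_mat) {
  m <- length(bicluster$samples)
  stopifnot(m >= 1)
  N <- ncol(rank_mat)
  sub <- rank_mat[bicluster$genes, bicluster$samples, drop = FALSE]
  x <- rowSums(sub <= m)
  data.frame(gene = bicluster$genes, overlap = as.integer(x),
             p_raw = overlap_pvalue(x, m, m, N),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score bicluster samples by gene-set enrichment
#'
#' For each sample `s` in a bicluster with `m` samples, let `G_s` be the set
#' of all genes in the dataset having `s` among their top-m (bottom-m)
#' samples. The raw p-value is the hypergeometric upper tail for the overlap
#' between `G_s` and the bicluster's gene set, in the universe of all genes.
#' An empty `G_s` yields p = 1. BH adjustment across all (sample, bicluster)
#' pairs is performed by [score_collection()].
#'
#' @param bicluster A `"tuba_bicluster"`.
#' @param rank_mat Extremality rank matrix over the full dataset.
#' @return Data frame: `sample`, `n_genes_with_sample`, `overlap`, `p_raw`.
#' @export
score_samples <- function(bicluster, rank_mat) {
  m <- length(bicluster$samples)
  stopifnot(m >= 1)
  G <- nrow(rank_mat)
  K <- length(bicluster$genes)
  topm <- rank_mat[, bicluster$samples, drop = FALSE] <= m
  draws <- colSums(topm)
  x <- colSums(topm[bicluster$genes, , drop = FALSE])
  data.frame(sample = bicluster$samples,
             n_genes_with_sample = as.integer(draws),
             overlap = as.integer(x),
             p_raw = overlap_pvalue(x, pmin(K, draws),
                                    pmax(K, draws), G),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Attach enrichment scores and quality indices to a collection
#'
#' Computes [score_genes()] and [score_samples()] for every bicluster,
#' BH-adjusts the gene tests pooled across all biclusters of the run (and the
#' sample tests likewise), and derives each bicluster's quality index Q.
#' Pooling makes scores comparable across biclusters.
#'
#' @param collection A `"tuba_biclusters"` collection.
#' @param mat The expression matrix the collection was derived from.
#' @return The collection with `gene_scores`, `sample_scores` (long-format
#'   data frames with `fdr` columns) and `quality` (named numeric) attached.
#' @export
score_collection <- function(collection, mat) {
  stopifnot(inherits(collection, "tuba_biclusters"))
  direction <- collection$config$direction
  rank_mat <- extremal_rank_matrix(mat, direction)
  gs <- list(); ss <- list()
  for (i in seq_along(collection$biclusters)) {
    b <- collection$biclusters[[i]]
    g <- score_genes(b, rank_mat)
    g$bicluster <- i
    g$is_seed <- g$gene %in% b$seed_genes
    g$degree <- b$degrees[g$gene]
    s <- score_samples(b, rank_mat)
    s$bicluster <- i
    gs[[i]] <- g; ss[[i]] <- s
  }
  gene_scores <- do.call(rbind, gs)
  sample_scores <- do.call(rbind, ss)
  gene_scores$fdr <- stats::p.adjust(gene_scores$p_raw, method = "BH")
  sample_scores$fdr <- stats::p.adjust(sample_scores$p_raw, method = "BH")
  thr <- collection$config$fdr_threshold
  q <- vapply(seq_along(collection$biclusters), function(i) {
    quality(gene_scores$fdr[gene_scores$bicluster == i],
            sample_scores$fdr[sample_scores$bicluster == i], thr)
  }, 0)
  collection$gene_scores <- gene_scores[, c("bicluster", "gene", "degree",
                                            "is_seed", "overlap", "p_raw",
                                            "fdr")]
  collection$sample_scores <- sample_scores[, c("bicluster", "sample",
                                                "n_genes_with_sample",
                                                "overlap", "p_raw", "fdr")]
  collection$quality <- q
  collection
}

#' Bicluster quality index Q
#'
#' Q is the minimum of the fraction of the bicluster's genes with enrichment
#' FDR below the threshold and the fraction of its samples with FDR below the
#' threshold. Values near 1 indicate a bicluster whose genes and samples are
#' all strongly tied to it; values near 0 a weak association.
#'
#' @param gene_fdr Numeric vector of per-gene FDRs.
#' @param sample_fdr Numeric vector of per-sample FDRs.
#' @param threshold FDR threshold (default 0.05).
#' @return A number in \[0, 1\].
#' @export
quality <- function(gene_fdr, sample_fdr, threshold = 0.05) {
  stopifnot(length(gene_fdr) >= 1, length(sample_fdr) >= 1)
  min(mean(gene_fdr < threshold), mean(sample_fdr < threshold))
}

#' Rank a bicluster's genes by degree
#'
#' Genes with higher degree are co-expressed with other bicluster genes in a
#' greater proportion of the bicluster's samples and are candidate drivers of
#' the shared signature. Ties are broken by gene identifier.
#'
#' @param bicluster A `"tuba_bicluster"`.
#' @return Data frame `gene`, `degree`, `candidate_driver` (flags the genes
#'   attaining the maximum degree), in descending degree order.
#' @export
rank_genes_by_degree <- function(bicluster) {
  stopifnot(inherits(bicluster, "tuba_bicluster"))
  d <- bicluster$degrees
  ord <- order(-d, names(d))
  data.frame(gene = names(d)[ord], degree = as.integer(d[ord]),
             candidate_driver = d[ord] == max(d),
             stringsAsFactors = FALSE, row.names = NULL)
}
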