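# Downstream analyses on finished bicluster collections: cross-run matching,
# categorical (subtype/grade) enrichment, copy-number enrichment combined by
# Fisher's method, proximal-locus classification, and Hamming clustering of
# the bicluster-sample membership matrix.

gene_sets_of <- function(x) {
  if (inherits(x, "tuba_biclusters")) {
    lapply(x$biclusters, function(b) b$genes)
  } else if (is.list(x)) {
    if (!is.null(x$gene_sets)) x$gene_sets else x
  } else stop("cannot extract gene sets from this object")
}

#' Match two bicluster collections by gene-set overlap
#'
#' Every pair (one bicluster from each collection) is tested for gene-set
#' overlap with the hypergeometric upper tail over a shared gene universe;
#' BH adjustment is applied over all pairs. A bicluster "matches" if it is
#' enriched (FDR below `fdr`) in at least one bicluster of the other
#' collection; the fractions of matching biclusters are reported in both
#' directions.
#'
#' @param collA,collB `"tuba_biclusters"` collections, outputs of
#'   [read_bicluster_collection()], or plain lists of gene-id vectors.
#' @param universe_size Number of genes in the shared universe.
#' @param fdr Matching threshold on adjusted p-values (default 0.001).
#' @return List with `pairs` (data frame: `a`, `b`, `overlap`, `p_raw`,
#'   `fdr`), `frac_a_matched`, `frac_b_matched`, and the FDR family size.
#' @export
compare_collections <- function(collA, collB, universe_size, fdr = 0.001) {
  A <- gene_sets_of(collA); B <- gene_sets_of(collB)
  if (!length(A) || !length(B)) {
    return(list(pairs = data.frame(), frac_a_matched = 0,
                frac_b_matched = 0, n_tests = 0L))
  }
  stopifnot(universe_size >= max(c(lengths(A), lengths(B))))
  pairs <- expand.grid(a = seq_along(A), b = seq_along(B))
  ov <- mapply(function(i, j) length(intersect(A[[i]], B[[j]])),
               pairs$a, pairs$b)
  ka <- lengths(A)[pairs$a]; kb <- lengths(B)[pairs$b]
  pairs$overlap <- as.integer(ov)
  pairs$p_raw <- overlap_pvalue(ov, pmin(ka, kb), pmax(ka, kb), universe_size)
  pairs$fdr <- stats::p.adjust(pairs$p_raw, method = "BH")
  hit <- pairs$fdr < fdr
  list(pairs = pairs,
       frac_a_matched = mean(seq_along(A) %in% pairs$a[hit]),
       frac_b_matched = mean(seq_along(B) %in% pairs$b[hit]),
       n_tests = nrow(pairs))
}

#' Categorical enrichment of bicluster samples
#'
#' For each bicluster and each value of a categorical sample annotation
#' (subtype, grade, node status, ...), performs the one-sided Fisher's exact
#' test on the 2x2 table classifying labeled samples by bicluster membership
#' and by category, and BH-adjusts across all bicluster-category tests of
#' the column. Samples without a label are excluded with a logged count.
#'
#' @param collection A `"tuba_biclusters"` collection.
#' @param labels A sample label table ([read_sample_labels()]).
#' @param column Name of the categorical column to test.
#' @return Data frame: `bicluster`, `category`, `n_bicluster`, `n_category`,
#'   `overlap`, `p_raw`, `fdr`.
#' @export
categorical_enrichment <- function(collection, labels, column) {
  stopifnot(inherits(collection, "tuba_biclusters"),
            column %in% names(labels))
  labeled <- labels[!is.na(labels[[column]]), , drop = FALSE]
  labeled <- labeled[labeled$sample_id %in% collection$sample_ids, ]
  n_excluded <- length(collection$sample_ids) - nrow(labeled)
  if (n_excluded > 0) {
    message(n_excluded, " sample(s) without a '", column,
            "' label excluded from the enrichment tables")
  }
  N <- nrow(labeled)
  cats <- sort(unique(as.character(labeled[[column]])))
  rows <- list()
  for (i in seq_along(collection$biclusters)) {
    sb <- intersect(collection$biclusters[[i]]$samples, labeled$sample_id)
    for (cc in cats) {
      in_cat <- labeled$sample_id[labeled[[column]] == cc]
      m <- length(intersect(sb, in_cat))
      rows[[length(rows) + 1L]] <- data.frame(
        bicluster = i, category = cc,
        n_bicluster = length(sb), n_category = length(in_cat),
        overlap = m,
        p_raw = overlap_pvalue(m, min(length(sb), length(in_cat)),
                               max(length(sb), length(in_cat)), N),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Combine independent p-values by Fisher's method
#'
#' The statistic is `chi2 = -2 * sum(log(p))`, chi-square distributed with
#' `2k` degrees of freedom under the joint null of `k` independent uniform
#' p-values; the combined p-value is its upper tail.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return List with `chisq`, `df`, `p_value`.
#' @export
#' @examples
#' fishers_method(c(0.05, 0.05))
fishers_method <- function(p) {
  stopifnot(length(p) >= 1, all(p > 0), all(p <= 1))
  chisq <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Copy-number enrichment of a bicluster
#'
#' For each bicluster gene covered by the copy-number call matrix, tests
#' whether the samples carrying a gain (or loss) call for that gene are
#' over-represented inside the bicluster: the hypergeometric upper tail for
#' the in-bicluster count of call-positive samples, given the gene's
#' cohort-wide positive count. The per-gene p-values are combined with
#' Fisher's method into a single bicluster-level p-value.
#'
#' @param bicluster A `"tuba_bicluster"`.
#' @param cna Integer gene-by-sample call matrix ([read_cna_matrix()]).
#' @param direction `"gain"` (call >= `call_threshold`) or `"loss"`
#'   (call <= `-call_threshold`).
#' @param call_threshold Positivity threshold on the calls (default 1).
#' @return List with `per_gene` (data frame: `gene`, `n_positive_cohort`,
#'   `n_positive_bicluster`, `p_raw`), `chisq`, `df`, `p_combined`, and
#'   `skipped` (genes absent from the call matrix). `NULL` if no bicluster
#'   gene is covered.
#' @export
cna_enrichment <- function(bicluster, cna, direction = c("gain", "loss"),
                           call_threshold = 1) {
  direction <- match.arg(direction)
  stopifnot(inherits(bicluster, "tuba_bicluster"))
  genes <- intersect(bicluster$genes, rownames(cna))
  skipped <- setdiff(bicluster$genes, genes)
  if (length(skipped)) {
    warning(length(skipped), " bicluster gene(s) absent from the CNA matrix")
  }
  if (!length(genes)) return(NULL)
  pos <- if (direction == "gain") cna >= call_threshold else cna <= -call_threshold
  N <- ncol(cna)
  sb <- intersect(bicluster$samples, colnames(cna))
  draws <- length(sb)
  K <- rowSums(pos[genes, , drop = FALSE])
  x <- rowSums(pos[genes, sb, drop = FALSE])
  p <- overlap_pvalue(x, pmin(K, draws), pmax(K, draws), N)
  fm <- fishers_method(p)
  list(per_gene = data.frame(gene = genes, n_positive_cohort = as.integer(K),
                             n_positive_bicluster = as.integer(x), p_raw = p,
                             stringsAsFactors = FALSE, row.names = NULL),
       chisq = fm$chisq, df = fm$df, p_combined = fm$p_value,
       skipped = skipped)
}

#' Copy-number enrichment across a collection
#'
#' Runs [cna_enrichment()] on every bicluster and BH-adjusts the combined
#' p-values across biclusters.
#'
#' @inheritParams cna_enrichment
#' @param collection A `"tuba_biclusters"` collection.
#' @return Data frame: `bicluster`, `n_genes_tested`, `chisq`, `df`,
#'   `p_combined`, `fdr` (biclusters with no covered gene are dropped).
#' @export
cna_enrichment_collection <- function(collection, cna,
                                      direction = c("gain", "loss"),
                                      call_threshold = 1) {
  direction <- match.arg(direction)
  res <- lapply(seq_along(collection$biclusters), function(i) {
    r <- suppressWarnings(
      cna_enrichment(collection$biclusters[[i]], cna, direction,
                     call_threshold))
    if (is.null(r)) return(NULL)
    data.frame(bicluster = i, n_genes_tested = nrow(r$per_gene),
               chisq = r$chisq, df = r$df, p_combined = r$p_combined)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame())
  out$fdr <- stats::p.adjust(out$p_combined, method = "BH")
  out
}

#' Classify a bicluster as proximal or distributed on the genome
#'
#' A bicluster is called proximal when at least `min_fraction` of its
#' annotated genes lie on one chromosome within a window spanning at most
#' `max_span_bp`. This operationalizes the visual judgment of amplicon-like
#' biclusters; both knobs are reported alongside the call.
#'
#' @param bicluster A `"tuba_bicluster"`.
#' @param loci Gene-locus table ([read_gene_loci()]).
#' @param min_fraction Minimum fraction of annotated genes inside the window
#'   (default 0.8).
#' @param max_span_bp Maximum window span in bp (default 25e6).
#' @return List with `classification` (`"proximal"`, `"distributed"` or
#'   `"unannotated"`), `chromosome`, `fraction`, `window`, `n_annotated`,
#'   and the parameters used.
#' @export
classify_proximal <- function(bicluster, loci, min_fraction = 0.8,
                              max_span_bp = 25e6) {
  stopifnot(inherits(bicluster, "tuba_bicluster"))
  ann <- loci[loci$gene %in% bicluster$genes, , drop = FALSE]
  params <- list(min_fraction = min_fraction, max_span_bp = max_span_bp)
  if (!nrow(ann)) {
    return(list(classification = "unannotated", chromosome = NA_character_,
                fraction = NA_real_, window = c(NA_real_, NA_real_),
                n_annotated = 0L, params = params))
  }
  best <- list(count = 0L, chrom = NA_character_, win = c(NA_real_, NA_real_))
  for (chrom in unique(ann$chromosome)) {
    pos <- sort((ann$start[ann$chromosome == chrom] +
                   ann$end[ann$chromosome == chrom]) / 2)
    j <- 1L
    for (i in seq_along(pos)) {
      while (pos[i] - pos[j] > max_span_bp) j <- j + 1L
      cnt <- i - j + 1L
      if (cnt > best$count) {
        best <- list(count = cnt, chrom = chrom, win = c(pos[j], pos[i]))
      }
    }
  }
  frac <- best$count / nrow(ann)
  list(classification = if (frac >= min_fraction) "proximal" else "distributed",
       chromosome = best$chrom, fraction = frac, window = best$win,
       n_annotated = nrow(ann), params = params)
}

#' Bicluster-by-sample binary membership matrix
#'
#' @param collection A `"tuba_biclusters"` collection.
#' @param sample_ids Sample universe (defaults to the collection's samples).
#' @return Binary integer matrix, biclusters in rows; row sums equal the
#'   bicluster sample counts.
#' @export
membership_matrix <- function(collection, sample_ids = NULL) {
  stopifnot(inherits(collection, "tuba_biclusters"))
  if (is.null(sample_ids)) sample_ids <- collection$sample_ids
  bics <- collection$biclusters
  m <- matrix(0L, length(bics), length(sample_ids),
              dimnames = list(paste0("bicluster_", seq_along(bics)),
                              sample_ids))
  for (i in seq_along(bics)) m[i, bics[[i]]$samples] <- 1L
  m
}

#' Hamming-distance hierarchical clustering of bicluster membership
#'
#' Clusters biclusters (or samples) by the Hamming distance between their
#' binary membership vectors -- the count of positions at which two vectors
#' differ -- using agglomerative clustering with the configured linkage. The
#' merge tree is also rendered in Newick format.
#'
#' @param membership Binary matrix from [membership_matrix()].
#' @param axis `"biclusters"` (rows, default) or `"samples"` (columns).
#' @param linkage Linkage method for `stats::hclust` (default `"average"`).
#' @return List with `matrix` (as clustered), `dist` (Hamming distances),
#'   `tree` (an `hclust`, or `NULL` if fewer than 2 rows), `newick`, and
#'   `linkage`.
#' @export
membership_and_hamming_clustering <- function(membership,
                                              axis = c("biclusters", "samples"),
                                              linkage = "average") {
  axis <- match.arg(axis)
  m <- if (axis == "samples") t(membership) else membership
  if (nrow(m) < 2) {
    return(list(matrix = m, dist = NULL, tree = NULL, newick = NULL,
                linkage = linkage))
  }
  d <- stats::dist(m, method = "manhattan")  # = Hamming on binary vectors
  tree <- stats::hclust(d, method = linkage)
  newick <- ape::write.tree(ape::as.phylo(tree))
  list(matrix = m, dist = d, tree = tree, newick = newick, linkage = linkage)
}
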