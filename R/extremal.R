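#' Per-gene extremal sample sets
#'
#' For every gene, identifies the `k` samples with the highest (or lowest)
#' expression, where `k = round(percentile * N)` with half-up rounding. These
#' percentile sets are the raw material of the pairwise proximity measure: two
#' genes are close when their extremal sets share more samples than chance
#' allows.
#'
#' Ties at the percentile boundary are broken deterministically: samples are
#' ordered by expression (descending for `"high"`, ascending for `"low"`) with
#' ties resolved by canonical sample order, i.e. column order of the input
#' matrix. For a gene with all-equal values the set is therefore the first `k`
#' samples in column order.
#'
#' @param mat Numeric gene-by-sample matrix with unique row and column names.
#' @param percentile Fraction in (0, 0.5].
#' @param direction `"high"` or `"low"`.
#' @param min_distinct Optional integer; genes whose boundary tie group pushes
#'   the number of samples attaining the boundary value past `k + min_distinct`
#'   are dropped (with a message). `NULL` disables the filter.
#'
#' @return An object of class `"tuba_extremal_sets"`: a list with elements
#'   `sets` (named list, gene -> character vector of `k` sample ids),
#'   `k`, `n_samples`, `percentile`, `direction`, `gene_ids`, `sample_ids`.
#' @export
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' compute_extremal_sets(m, percentile = 0.2)
compute_extremal_sets <- function(mat, percentile,
                                  direction = c("high", "low"),
                                  min_distinct = NULL) {
  direction <- match.arg(direction)
  validate_expression(mat)
  stopifnot(percentile > 0, percentile <= 0.5)
  n <- ncol(mat)
  k <- floor(percentile * n + 0.5)  # round half-up
  if (k < 2) {
    stop("extremal set size k = round(percentile * N) = ", k,
         " is below 2; increase the percentile or use a larger cohort")
  }
  samples <- colnames(mat)
  idx <- seq_len(n)
  sets <- vector("list", nrow(mat))
  keep <- rep(TRUE, nrow(mat))
  for (g in seq_len(nrow(mat))) {
    v <- mat[g, ]
    ord <- if (direction == "high") order(-v, idx) else order(v, idx)
    if (!is.null(min_distinct)) {
      boundary <- v[ord[k]]
      n_at_or_beyond <- if (direction == "high") sum(v >= boundary) else sum(v <= boundary)
      if (n_at_or_beyond > k + min_distinct) {
        keep[g] <- FALSE
        next
      }
    }
    sets[[g]] <- samples[ord[seq_len(k)]]
  }
  if (!all(keep)) {
    message(sum(!keep), " gene(s) dropped by the boundary-tie filter")
  }
  names(sets) <- rownames(mat)
  sets <- sets[keep]
  structure(
    list(sets = sets, k = k, n_samples = n, percentile = percentile,
         direction = direction, gene_ids = names(sets), sample_ids = samples),
    class = "tuba_extremal_sets"
  )
}

#' @export
print.tuba_extremal_sets <- function(x, ...) {
  cat(sprintf("Extremal sets: %d genes, %s %g%% of %d samples (k = %d)\n",
              length(x$sets), if (x$direction == "high") "top" else "bottom",
              100 * x$percentile, x$n_samples, x$k))
  invisible(x)
}

#' Extremality rank matrix
#'
#' For each gene, ranks all samples from most to least extreme using the same
#' deterministic tie-break as [compute_extremal_sets()]; rank 1 is the most
#' extreme sample. `rank <= m` then selects each gene's top-m (or bottom-m)
#' set, which the bicluster scoring routines need for varying m.
#'
#' @param mat Numeric gene-by-sample matrix.
#' @param direction `"high"` or `"low"`.
#' @return Integer matrix, same dimnames as `mat`.
#' @export
extremal_rank_matrix <- function(mat, direction = c("high", "low")) {
  direction <- match.arg(direction)
  idx <- seq_len(ncol(mat))
  r <- matrix(0L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (g in seq_len(nrow(mat))) {
    v <- mat[g, ]
    ord <- if (direction == "high") order(-v, idx) else order(v, idx)
    r[g, ord] <- idx
  }
  r
}

#' Significance of the overlap of two extremal sets
#'
#' Upper-tail probability `P(X >= m)` for a hypergeometric variable `X` with
#' population size `N`, `k1` successes and `k2` draws -- equivalently the
#' one-sided Fisher's exact test on the 2x2 contingency table classifying the
#' `N` samples by membership in each gene's extremal set. This is the pairwise
#' proximity measure between genes: the smaller the value, the less plausible
#' that the two sets share `m` samples by chance.
#'
#' The tail is evaluated in log space by `stats::phyper(log.p = TRUE)`, so
#' values far below double underflow thresholds of naive summation (for
#' example 1e-165) are returned accurately. The function is symmetric in
#' `(k1, k2)` and vectorised over its arguments.
#'
#' @param m Observed overlap, `0 <= m <= min(k1, k2)`.
#' @param k1,k2 Sizes of the two extremal sets.
#' @param N Total number of samples.
#' @param log_p If `TRUE`, return the natural log of the p-value.
#' @return Numeric vector of p-values in (0, 1] (or their logs).
#' @export
#' @examples
#' overlap_pvalue(10, 10, 10, 200)  # complete overlap of two top-5% sets
overlap_pvalue <- function(m, k1, k2, N, log_p = FALSE) {
  n <- max(length(m), length(k1), length(k2), length(N))
  m <- rep_len(as.numeric(m), n); k1 <- rep_len(as.numeric(k1), n)
  k2 <- rep_len(as.numeric(k2), n); N <- rep_len(as.numeric(N), n)
  if (any(m < 0) || any(m > pmin(k1, k2)) || any(pmax(k1, k2) > N)) {
    stop("require 0 <= m <= min(k1, k2) and max(k1, k2) <= N")
  }
  lp <- stats::phyper(m - 1, k1, N - k1, k2, lower.tail = FALSE, log.p = TRUE)
  if (log_p) lp else exp(lp)
}

# All-pairs overlap counts from an extremal-set collection.
# Returns a data.frame (i, j, m) for pairs with m >= 1, i < j in gene order,
# computed with a sparse incidence crossproduct.
all_pair_overlaps <- function(sets) {
  genes <- sets$gene_ids
  g_idx <- rep(seq_along(genes), each = sets$k)
  s_idx <- match(unlist(sets$sets, use.names = FALSE), sets$sample_ids)
  inc <- Matrix::sparseMatrix(i = g_idx, j = s_idx, x = 1,
                              dims = c(length(genes), sets$n_samples))
  ov <- Matrix::tcrossprod(inc)
  tri <- Matrix::summary(ov)
  tri <- tri[tri$i < tri$j, , drop = FALSE]
  data.frame(i = tri$i, j = tri$j, m = as.integer(tri$x))
}

#' Build the significance-filtered co-expression graph
#'
#' Tests every unordered gene pair for extremal-set overlap with
#' [overlap_pvalue()] and keeps the pairs passing the configured cut-off as
#' edges. Benjamini-Hochberg adjustment is performed over the full family of
#' `G(G-1)/2` pairwise tests: pairs with zero overlap enter the family with a
#' raw p of 1, so the adjustment does not depend on sparsity shortcuts.
#' Each retained edge stores the shared samples (the intersection of the two
#' genes' extremal sets).
#'
#' @param sets A `"tuba_extremal_sets"` object.
#' @param cutoff Significance cut-off in (0, 1); edges satisfy
#'   `p <= cutoff` where `p` is raw or adjusted according to `cutoff_mode`.
#' @param cutoff_mode `"fdr"` (adjusted p, the default) or `"raw"`.
#' @return An object of class `"tuba_graph"`: list with `edges` (data.frame
#'   `gene1`, `gene2`, `m`, `p_raw`, `p_adj`), `shared` (list of character
#'   vectors parallel to the edge rows), `genes` (nodes incident to at least
#'   one edge) and `meta`.
#' @export
build_graph <- function(sets, cutoff, cutoff_mode = c("fdr", "raw")) {
  cutoff_mode <- match.arg(cutoff_mode)
  stopifnot(inherits(sets, "tuba_extremal_sets"), cutoff > 0, cutoff < 1)
  genes <- sets$gene_ids
  G <- length(genes)
  n_family <- G * (G - 1) / 2
  ov <- all_pair_overlaps(sets)
  # k is constant across genes, so p depends only on m: use a lookup table.
  p_by_m <- overlap_pvalue(seq_len(sets$k), sets$k, sets$k, sets$n_samples)
  p_raw <- p_by_m[ov$m]
  # BH over the full family; untested (m = 0) pairs all sit at p = 1 and
  # occupy the top ranks, which p.adjust(n = n_family) reproduces exactly.
  p_adj <- stats::p.adjust(p_raw, method = "BH", n = n_family)
  keep <- if (cutoff_mode == "fdr") p_adj <= cutoff else p_raw <= cutoff
  ov <- ov[keep, , drop = FALSE]
  p_raw <- p_raw[keep]; p_adj <- p_adj[keep]
  edges <- data.frame(gene1 = genes[ov$i], gene2 = genes[ov$j],
                      m = ov$m, p_raw = p_raw, p_adj = p_adj,
                      stringsAsFactors = FALSE)
  # canonical storage: gene1 < gene2 lexicographically, rows sorted
  flip <- edges$gene1 > edges$gene2
  if (any(flip)) {
    tmp <- edges$gene1[flip]
    edges$gene1[flip] <- edges$gene2[flip]
    edges$gene2[flip] <- tmp
  }
  ord <- order(edges$gene1, edges$gene2)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  shared <- vector("list", nrow(edges))
  canon <- sets$sample_ids
  for (e in seq_len(nrow(edges))) {
    s <- intersect(sets$sets[[edges$gene1[e]]], sets$sets[[edges$gene2[e]]])
    shared[[e]] <- canon[sort(match(s, canon))]
  }
  g <- new_tuba_graph(edges, shared,
                      meta = list(n_samples = sets$n_samples,
                                  n_genes_tested = G,
                                  percentile = sets$percentile,
                                  direction = sets$direction,
                                  cutoff = cutoff, cutoff_mode = cutoff_mode))
  if (length(g$genes) < 3) {
    warning("fewer than 3 genes pass the cut-off; ",
            "downstream steps will produce no biclusters")
  }
  g
}

#' Tuning curve over a grid of significance cut-offs
#'
#' For each cut-off, counts the edges, the genes incident to at least one
#' edge, and the distinct samples appearing on at least one edge's shared-set.
#' These are the diagnostics used to pick the overlap significance cut-off:
#' as the cut-off is relaxed, edges eventually flood in without a
#' proportional gain in genes or samples.
#'
#' @param sets A `"tuba_extremal_sets"` object.
#' @param cutoff_grid Numeric vector of cut-offs in (0, 1); internally sorted
#'   from stringent (small) to lenient (large).
#' @param cutoff_mode `"fdr"` or `"raw"`.
#' @return Data frame of class `"tuba_tuning_curve"` with columns `cutoff`,
#'   `n_edges`, `n_genes_in_graph`, `n_samples_on_edges`; all three counts are
#'   non-decreasing with leniency.
#' @export
tuning_curve <- function(sets, cutoff_grid, cutoff_mode = c("fdr", "raw")) {
  cutoff_mode <- match.arg(cutoff_mode)
  stopifnot(inherits(sets, "tuba_extremal_sets"),
            all(cutoff_grid > 0), all(cutoff_grid < 1))
  grid <- sort(unique(cutoff_grid))
  genes <- sets$gene_ids
  G <- length(genes)
  ov <- all_pair_overlaps(sets)
  p_by_m <- overlap_pvalue(seq_len(sets$k), sets$k, sets$k, sets$n_samples)
  p_raw <- p_by_m[ov$m]
  p <- if (cutoff_mode == "fdr") {
    stats::p.adjust(p_raw, method = "BH", n = G * (G - 1) / 2)
  } else p_raw
  rows <- lapply(grid, function(cc) {
    sel <- which(p <= cc)
    n_edges <- length(sel)
    n_genes <- length(unique(c(ov$i[sel], ov$j[sel])))
    smp <- character(0)
    if (n_edges) {
      smp <- unique(unlist(lapply(sel, function(e) {
        intersect(sets$sets[[ov$i[e]]], sets$sets[[ov$j[e]]])
      }), use.names = FALSE))
    }
    data.frame(cutoff = cc, n_edges = n_edges, n_genes_in_graph = n_genes,
               n_samples_on_edges = length(smp))
  })
  out <- do.call(rbind, rows)
  stopifnot(!is.unsorted(out$n_edges), !is.unsorted(out$n_genes_in_graph),
            !is.unsorted(out$n_samples_on_edges))
  class(out) <- c("tuba_tuning_curve", "data.frame")
  out
}

#' Suggest an overlap significance cut-off from a tuning curve
#'
#' Implements the edge-growth heuristic: pick the least stringent cut-off `c`
#' on a decade-spaced grid such that relaxing by one further decade grows the
#' edge count by 40-60%. If no cut-off qualifies, the one whose growth ratio
#' is closest to 1.5 is returned and flagged as approximate.
#'
#' @param curve A `"tuba_tuning_curve"` with at least 2 rows on a
#'   decade-spaced grid.
#' @return List with `cutoff`, `approximate` flag, and `diagnostics` (the
#'   curve augmented with the next-decade growth ratio).
#' @export
suggest_cutoff <- function(curve) {
  stopifnot(inherits(curve, "data.frame"), nrow(curve) >= 2)
  if (all(curve$n_edges == 0)) {
    stop("all edge counts are zero; the grid is entirely too stringent")
  }
  n <- nrow(curve)
  ratio <- c(curve$n_edges[-1] / curve$n_edges[-n], NA_real_)
  diag <- cbind(curve, growth_ratio = ratio)
  ok <- which(!is.na(ratio) & is.finite(ratio) &
                ratio >= 1.4 & ratio <= 1.6)
  if (length(ok)) {
    pick <- max(ok)  # least stringent qualifying cut-off
    approximate <- FALSE
  } else {
    cand <- which(!is.na(ratio) & is.finite(ratio))
    if (!length(cand)) stop("no finite growth ratios on the grid")
    pick <- cand[which.min(abs(ratio[cand] - 1.5))]
    approximate <- TRUE
  }
  list(cutoff = curve$cutoff[pick], approximate = approximate,
       diagnostics = diag)
}

#' Permutation null for the pairwise overlap test
#'
#' For each iteration, independently permutes the sample labels of every gene,
#' recomputes the extremal sets and all pairwise overlap p-values, and
#' summarises them: a histogram of raw and BH-adjusted p-values and the count
#' of adjusted p-values below `alpha`. Under the null of no co-expression
#' structure the adjusted counts should essentially always be zero at
#' stringent `alpha`.
#'
#' @param mat Numeric gene-by-sample matrix.
#' @param percentile Fraction in (0, 0.5].
#' @param n_iter Number of permutation iterations (>= 1).
#' @param rng_seed Integer seed; the run is reproducible given the seed.
#' @param direction `"high"` or `"low"`.
#' @param alpha Threshold reported on the adjusted p-values.
#' @param breaks Histogram breaks on (0, 1].
#' @return List with `summary` (data.frame: `iteration`, `n_pairs_overlap`,
#'   `min_p_raw`, `n_raw_below_alpha`, `n_adj_below_alpha`) and `histograms`
#'   (per iteration, counts of raw and adjusted p in `breaks`).
#' @export
permutation_null <- function(mat, percentile, n_iter, rng_seed,
                             direction = "high", alpha = 1e-8,
                             breaks = seq(0, 1, by = 0.05)) {
  stopifnot(n_iter >= 1)
  set.seed(as.integer(rng_seed))
  G <- nrow(mat)
  n_family <- G * (G - 1) / 2
  rows <- vector("list", n_iter)
  hists <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    perm <- mat
    for (g in seq_len(G)) perm[g, ] <- perm[g, sample.int(ncol(mat))]
    sets <- compute_extremal_sets(perm, percentile, direction)
    ov <- all_pair_overlaps(sets)
    p_by_m <- overlap_pvalue(seq_len(sets$k), sets$k, sets$k, sets$n_samples)
    p_raw <- p_by_m[ov$m]
    p_adj <- stats::p.adjust(p_raw, method = "BH", n = n_family)
    rows[[it]] <- data.frame(
      iteration = it,
      n_pairs_overlap = length(p_raw),
      min_p_raw = if (length(p_raw)) min(p_raw) else 1,
      n_raw_below_alpha = sum(p_raw < alpha),
      n_adj_below_alpha = sum(p_adj < alpha))
    hists[[it]] <- list(
      raw = graphics::hist(p_raw, breaks = breaks, plot = FALSE)$counts,
      adjusted = graphics::hist(p_adj, breaks = breaks, plot = FALSE)$counts)
  }
  list(summary = do.call(rbind, rows), histograms = hists,
       alpha = alpha, breaks = breaks)
}
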