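# Extremal sets, the pairwise overlap test, graph construction, and tuning.

test_that("extremal set size follows round-half-up of percentile * N", {
  m <- matrix(rnorm(5 * 200), 5, 200,
              dimnames = list(paste0("g", 1:5), sprintf("s%03d", 1:200)))
  sets <- compute_extremal_sets(m, 0.05, "high")
  expect_equal(sets$k, 10)
  expect_true(all(lengths(sets$sets) == 10))

  # half-up: 0.05 * 50 = 2.5 -> 3
  m2 <- m[, 1:50]
  expect_equal(compute_extremal_sets(m2, 0.05)$k, 3)

  m3 <- m[, 1:20]  # k would be 1
  expect_error(compute_extremal_sets(m3, 0.05), "below 2")
})

test_that("extremal membership and tie-breaks are deterministic", {
  m <- matrix(0, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  m[1, ] <- c(1, 2, 3, 4)
  m[2, ] <- c(4, 3, 2, 1)
  sets <- compute_extremal_sets(m, 0.5, "high")
  expect_setequal(sets$sets$g1, c("s3", "s4"))
  expect_setequal(sets$sets$g2, c("s1", "s2"))
  low <- compute_extremal_sets(m, 0.5, "low")
  expect_setequal(low$sets$g1, c("s1", "s2"))

  # all-equal gene: the k samples earliest in canonical (column) order
  m[1, ] <- 5
  m <- cbind(m, m, m[, 1:2])  # 10 samples
  colnames(m) <- paste0("s", 1:10)
  sets <- compute_extremal_sets(m[, 1:10], 0.3, "high")
  expect_identical(sets$sets$g1, c("s1", "s2", "s3"))
})

test_that("overlap_pvalue reproduces the worked examples", {
  # complete overlap of two 10-sets in a 200-sample cohort
  expect_equal(overlap_pvalue(10, 10, 10, 200), 4.45e-17, tolerance = 5e-3)
  expect_equal(overlap_pvalue(10, 10, 10, 200), 1 / choose(200, 10))
  # 10-of-20 overlap sits between 1e-10 and 1e-5
  p <- overlap_pvalue(10, 20, 20, 200)
  expect_gt(p, 1e-10)
  expect_lt(p, 1e-5)
  expect_equal(p, oracle_tail(10, 20, 20, 200), tolerance = 1e-12)
  # degenerate and closed-form cases
  expect_equal(overlap_pvalue(0, 7, 9, 50), 1)
  expect_equal(overlap_pvalue(5, 5, 5, 20), 1 / choose(20, 5))
  expect_error(overlap_pvalue(6, 5, 5, 20), "require")
})

test_that("overlap_pvalue is symmetric, monotone in m, and matches the tail-sum oracle", {
  set.seed(11)
  for (i in 1:200) {
    N <- sample(5:60, 1)
    k1 <- sample(seq_len(N), 1)
    k2 <- sample(seq_len(N), 1)
    m <- sample(0:min(k1, k2), 1)
    p <- overlap_pvalue(m, k1, k2, N)
    expect_equal(p, oracle_tail(m, k1, k2, N), tolerance = 1e-12)
    expect_equal(p, overlap_pvalue(m, k2, k1, N), tolerance = 1e-12)
  }
  ms <- 0:10
  ps <- overlap_pvalue(ms, 10, 10, 200)
  expect_true(all(diff(ps) < 0))
  # log-space path agrees with the linear one
  expect_equal(exp(overlap_pvalue(10, 10, 10, 200, log_p = TRUE)),
               overlap_pvalue(10, 10, 10, 200))
})

make_sets <- function(sets, sample_ids, percentile = 0.05) {
  structure(list(sets = sets, k = length(sets[[1]]),
                 n_samples = length(sample_ids),
                 percentile = percentile, direction = "high",
                 gene_ids = names(sets), sample_ids = sample_ids),
            class = "tuba_extremal_sets")
}

test_that("build_graph keeps identical-set triangles and drops disjoint sets", {
  samp <- sprintf("s%03d", 1:200)
  common <- samp[1:10]
  sets <- make_sets(list(gA = common, gB = common, gC = common), samp)
  g <- build_graph(sets, 1e-8, "fdr")
  expect_equal(nrow(g$edges), 3)
  expect_true(all(vapply(g$shared, function(s) identical(sort(s), sort(common)),
                         TRUE)))

  disj <- make_sets(list(gA = samp[1:10], gB = samp[11:20], gC = samp[21:30]),
                    samp)
  expect_warning(g0 <- build_graph(disj, 1e-8, "fdr"), "fewer than 3")
  expect_equal(nrow(g0$edges), 0)
})

test_that("build_graph equals a brute-force all-pairs scan", {
  set.seed(23)
  samp <- sprintf("s%03d", 1:100)
  sets <- lapply(1:10, function(i) sample(samp, 8))
  # force some strong overlaps
  sets[[2]] <- sets[[1]]
  sets[[3]][1:6] <- sets[[1]][1:6]
  names(sets) <- sprintf("g%02d", 1:10)
  sc <- make_sets(sets, samp, percentile = 0.08)
  cutoff <- 1e-4
  g <- build_graph(sc, cutoff, "fdr")

  # oracle: plain double loop + explicit tail sums + BH over all 45 pairs
  pairs <- t(combn(names(sets), 2))
  p <- apply(pairs, 1, function(pr) {
    m <- length(intersect(sets[[pr[1]]], sets[[pr[2]]]))
    oracle_tail(m, 8, 8, 100)
  })
  adj <- stats::p.adjust(p, "BH")
  want <- pairs[adj <= cutoff, , drop = FALSE]
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(nrow(g$edges), nrow(want))
  expect_equal(g$edges$gene1, want[, 1])
  expect_equal(g$edges$gene2, want[, 2])
})

test_that("graph edges are invariant to gene order and consistent sample relabeling", {
  sim <- coextremal_fixture(n_genes = 40, n_samples = 80, block_genes = 4,
                            block_samples = 8, seed = 3)
  mat <- sim$matrix
  cfg_p <- 0.1
  g1 <- build_graph(compute_extremal_sets(mat, cfg_p), 1e-6)
  g2 <- build_graph(compute_extremal_sets(mat[rev(seq_len(nrow(mat))), ], cfg_p),
                    1e-6)
  key <- function(g) sort(paste(g$edges$gene1, g$edges$gene2))
  expect_identical(key(g1), key(g2))

  relab <- mat
  colnames(relab) <- paste0("x_", colnames(mat))
  g3 <- build_graph(compute_extremal_sets(relab, cfg_p), 1e-6)
  expect_identical(key(g1), key(g3))
})

test_that("tuning curve is monotone and consistent with build_graph", {
  sim <- coextremal_fixture(n_genes = 30, n_samples = 100, block_genes = 4,
                            block_samples = 5, seed = 9)
  sets <- compute_extremal_sets(sim$matrix, 0.05)
  grid <- 10^seq(-12, -2, by = 2)
  curve <- tuning_curve(sets, grid)
  expect_equal(nrow(curve), length(grid))
  expect_true(!is.unsorted(curve$n_edges))
  expect_true(!is.unsorted(curve$n_genes_in_graph))
  expect_true(!is.unsorted(curve$n_samples_on_edges))

  for (r in c(1, nrow(curve))) {
    g <- suppressWarnings(build_graph(sets, curve$cutoff[r], "fdr"))
    expect_equal(curve$n_edges[r], nrow(g$edges))
    expect_equal(curve$n_genes_in_graph[r], length(g$genes))
    expect_equal(curve$n_samples_on_edges[r],
                 length(unique(unlist(g$shared))))
  }
})

test_that("suggest_cutoff applies the 40-60% edge-growth heuristic", {
  curve <- data.frame(cutoff = 10^c(-12, -10, -8, -6),
                      n_edges = c(10, 12, 18, 54),
                      n_genes_in_graph = c(5, 6, 7, 9),
                      n_samples_on_edges = c(20, 22, 25, 30))
  # decade growth ratios: 1.2, 1.5, 3.0 -> the 1.5 cut-off wins
  out <- suggest_cutoff(curve)
  expect_equal(out$cutoff, 1e-10)
  expect_false(out$approximate)

  # two qualifying cut-offs: the less stringent one is returned
  curve2 <- curve
  curve2$n_edges <- c(10, 15, 22, 220)
  expect_equal(suggest_cutoff(curve2)$cutoff, 1e-10)

  # nothing in [1.4, 1.6]: nearest-to-1.5 with the approximate flag
  curve3 <- curve
  curve3$n_edges <- c(1, 10, 100, 1000)
  out3 <- suggest_cutoff(curve3)
  expect_true(out3$approximate)

  curve0 <- curve
  curve0$n_edges <- 0
  expect_error(suggest_cutoff(curve0), "zero")
})

test_that("permutation null is seed-deterministic and finds nothing on noise", {
  set.seed(5)
  m <- matrix(rlnorm(60 * 80), 60, 80,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:80)))
  a <- permutation_null(m, 0.1, n_iter = 2, rng_seed = 31)
  b <- permutation_null(m, 0.1, n_iter = 2, rng_seed = 31)
  expect_identical(a$summary, b$summary)
  expect_identical(a$histograms, b$histograms)
  expect_true(all(a$summary$n_adj_below_alpha == 0))
  # raw p-values are broadly spread over (0, 1], not piled near 0
  h <- a$histograms[[1]]$raw
  expect_lt(h[1] / sum(h), 0.2)
})
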