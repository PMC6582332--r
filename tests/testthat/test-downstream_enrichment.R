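# Collection comparison, categorical and copy-number enrichment, proximal
# classification, and Hamming clustering of membership.

test_that("identical collections match fully; disjoint ones not at all", {
  A <- list(letters[1:10], letters[11:20])
  full <- compare_collections(A, A, universe_size = 1000)
  expect_equal(full$frac_a_matched, 1)
  expect_equal(full$frac_b_matched, 1)

  B <- list(LETTERS[1:10])
  none <- compare_collections(A, B, universe_size = 1000)
  expect_equal(none$frac_a_matched, 0)
  expect_equal(none$frac_b_matched, 0)

  empty <- compare_collections(list(), A, universe_size = 1000)
  expect_equal(empty$n_tests, 0L)
})

test_that("split-half runs of one dataset yield matched biclusters that are larger", {
  sim <- default_benchmark(seed = 20, n_genes = 400, n_samples = 160,
                           n_implants = 3, genes_per = 10, samples_per = 16)
  # implant samples interleaved across the halves so both halves see them
  half1 <- seq(1, 160, by = 2); half2 <- seq(2, 160, by = 2)
  cfg <- tuba_config(percentile = 0.1, cutoff = 1e-6)
  rA <- run_tuba(sim$matrix[, half1], cfg, score = FALSE)
  rB <- run_tuba(sim$matrix[, half2], cfg, score = FALSE)
  cmp <- compare_collections(rA, rB, universe_size = 400)
  expect_gt(cmp$frac_a_matched, 0)
  matched_a <- unique(cmp$pairs$a[cmp$pairs$fdr < 0.001])
  sizes <- lengths(gene_sets <- lapply(rA$biclusters, `[[`, "genes"))
  expect_gte(min(sizes[matched_a]), 3)
})

test_that("categorical enrichment matches the closed-form tail and stays null under proportionality", {
  sim <- default_benchmark(seed = 4, n_genes = 200, n_samples = 100,
                           n_implants = 1, genes_per = 6, samples_per = 10,
                           effect_sd = 8)
  res <- run_tuba(sim$matrix, tuba_config(percentile = 0.1, cutoff = 1e-6),
                  score = FALSE)
  rec <- score_recovery(res, sim$truth)
  expect_true(rec$recovered[1])

  enr <- categorical_enrichment(res, sim$labels, "subtype")
  hit <- enr[enr$bicluster == rec$best_bicluster[1] &
               enr$category == "implant_1", ]
  expect_lt(hit$fdr, 0.05)
  # oracle check of the raw p on the same 2x2 margins
  expect_equal(hit$p_raw,
               oracle_tail(hit$overlap, min(hit$n_bicluster, hit$n_category),
                           max(hit$n_bicluster, hit$n_category), 100),
               tolerance = 1e-12)
  # the background category is not enriched in the implant bicluster
  null_row <- enr[enr$bicluster == rec$best_bicluster[1] &
                    enr$category == "background", ]
  expect_gt(null_row$p_raw, 0.5)
})

test_that("Fisher's method matches the chi-square closed form", {
  both_null <- fishers_method(c(1, 1))
  expect_equal(both_null$chisq, 0)
  expect_equal(both_null$p_value, 1)

  fm <- fishers_method(c(0.05, 0.05))
  expect_equal(fm$chisq, -2 * log(0.05) * 2, tolerance = 1e-10)
  expect_equal(fm$df, 4)
  expect_equal(fm$p_value, oracle_chisq4_upper(fm$chisq), tolerance = 1e-6)
  expect_equal(fm$p_value, 0.0175, tolerance = 2e-3)

  # under the joint null, combined p is uniform (simulation cross-check)
  set.seed(8)
  sim_p <- replicate(2000, fishers_method(runif(3))$p_value)
  expect_gt(suppressWarnings(ks.test(sim_p, "punif"))$p.value, 0.01)
})

test_that("copy-number enrichment flags implanted amplicons", {
  sim <- default_benchmark(seed = 13, n_genes = 200, n_samples = 100,
                           n_implants = 2, genes_per = 6, samples_per = 10,
                           effect_sd = 8)
  res <- run_tuba(sim$matrix, tuba_config(percentile = 0.1, cutoff = 1e-6),
                  score = FALSE)
  rec <- score_recovery(res, sim$truth)
  expect_true(all(rec$recovered))
  tab <- cna_enrichment_collection(res, sim$cna, direction = "gain")
  expect_true(all(tab$fdr[tab$bicluster %in% rec$best_bicluster] < 1e-3))

  # per-gene p of 1 combine to a combined p of 1
  b <- res$biclusters[[rec$best_bicluster[1]]]
  null_cna <- sim$cna; null_cna[] <- 0L
  r <- cna_enrichment(b, null_cna, "gain")
  expect_equal(r$chisq, 0)
  expect_equal(r$p_combined, 1)

  # genes absent from the call matrix are skipped with a warning
  expect_warning(r2 <- cna_enrichment(b, sim$cna[-(1:3), ], "gain"),
                 "absent")
  expect_equal(sort(r2$skipped), sort(intersect(b$genes, rownames(sim$cna)[1:3])))
})

test_that("proximal classification follows the window rule", {
  loci <- data.frame(
    gene = paste0("g", 1:10),
    chromosome = c(rep("chr8", 9), "chr1"),
    start = c(seq(1e6, 9e6, by = 1e6), 5e7),
    end = c(seq(1e6, 9e6, by = 1e6) + 1e4, 5e7 + 1e4))
  b5 <- structure(list(genes = paste0("g", 1:5), samples = "s1"),
                  class = "tuba_bicluster")
  expect_equal(classify_proximal(b5, loci)$classification, "proximal")

  spread <- loci; spread$chromosome <- rep(paste0("chr", 1:4), length.out = 10)
  expect_equal(classify_proximal(b5, spread)$classification, "distributed")

  # 9 of 10 genes inside one 10 Mb window on chr8: proximal at defaults
  b10 <- structure(list(genes = paste0("g", 1:10), samples = "s1"),
                   class = "tuba_bicluster")
  out <- classify_proximal(b10, loci, max_span_bp = 10e6)
  expect_equal(out$classification, "proximal")
  expect_equal(out$fraction, 0.9)

  none <- structure(list(genes = "unknown_gene", samples = "s1"),
                    class = "tuba_bicluster")
  expect_equal(classify_proximal(none, loci)$classification, "unannotated")
})

test_that("membership matrix and Hamming clustering behave on edge cases", {
  b1 <- structure(list(genes = letters[1:3], samples = paste0("s", 1:5)),
                  class = "tuba_bicluster")
  b2 <- structure(list(genes = letters[4:6], samples = paste0("s", 1:5)),
                  class = "tuba_bicluster")
  b3 <- structure(list(genes = letters[7:9], samples = paste0("s", 6:10)),
                  class = "tuba_bicluster")
  coll <- structure(list(biclusters = list(b1, b2, b3),
                         sample_ids = paste0("s", 1:10),
                         gene_ids = letters[1:9],
                         config = tuba_config()),
                    class = "tuba_biclusters")
  mm <- membership_matrix(coll)
  expect_equal(dim(mm), c(3L, 10L))
  expect_equal(unname(rowSums(mm)), c(5, 5, 5))

  cl <- membership_and_hamming_clustering(mm)
  d <- as.matrix(cl$dist)
  expect_equal(d["bicluster_1", "bicluster_2"], 0)   # identical membership
  expect_equal(d["bicluster_1", "bicluster_3"], 10)  # complementary rows
  expect_s3_class(cl$tree, "hclust")
  expect_match(cl$newick, "bicluster_1")
  # identical biclusters merge before unrelated ones
  merge_height <- cl$tree$height[1]
  expect_equal(merge_height, 0)

  single <- membership_and_hamming_clustering(mm[1, , drop = FALSE])
  expect_null(single$tree)

  by_sample <- membership_and_hamming_clustering(mm, axis = "samples")
  expect_equal(nrow(by_sample$matrix), 10)
})
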