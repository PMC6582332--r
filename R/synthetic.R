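# Synthetic expression matrices with implanted extremal biclusters, plus the
# recovery scoring used to benchmark the pipeline without external data.

#' Generate a background expression matrix
#'
#' Draws i.i.d. per-gene baselines with gene-specific means: either
#' log-normal intensities (`meanlog` per gene drawn from a normal) or
#' negative-binomial counts transformed to `log2(x + 1)`. Deterministic under
#' the seed.
#'
#' @param n_genes,n_samples Dimensions (>= 1).
#' @param rng_seed Integer seed.
#' @param family `"lognormal"` or `"negative_binomial"`.
#' @param meanlog_mean,meanlog_sd Hyperparameters of the per-gene mean
#'   (log scale).
#' @param sdlog Within-gene spread for the lognormal family.
#' @param nb_size Dispersion (size) for the negative-binomial family.
#' @return Numeric matrix with gene/sample identifiers.
#' @export
generate_background <- function(n_genes, n_samples, rng_seed,
                                family = c("lognormal", "negative_binomial"),
                                meanlog_mean = 2, meanlog_sd = 1,
                                sdlog = 0.5, nb_size = 5) {
  family <- match.arg(family)
  stopifnot(n_genes >= 1, n_samples >= 1)
  set.seed(as.integer(rng_seed))
  mu <- stats::rnorm(n_genes, meanlog_mean, meanlog_sd)
  # column-major fill + meanlog recycling give element (g, s) mean mu[g]
  vals <- switch(family,
    lognormal = matrix(stats::rlnorm(n_genes * n_samples, meanlog = mu,
                                     sdlog = sdlog), nrow = n_genes),
    negative_binomial = log2(1 + matrix(
      stats::rnbinom(n_genes * n_samples, mu = exp(mu), size = nb_size),
      nrow = n_genes)))
  dimnames(vals) <- list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("s%04d", seq_len(n_samples)))
  vals
}

#' Specify an implanted bicluster
#'
#' @param genes,samples Gene and sample identifiers (or indices) of the
#'   block; at least 3 genes are needed for the block to be recoverable.
#' @param effect Non-zero additive shift: in expression units
#'   (`effect_scale = "units"`) or in multiples of each implanted gene's
#'   background standard deviation (`effect_scale = "gene_sd"`). Positive for
#'   high-direction implants, negative for low.
#' @param effect_scale `"units"` or `"gene_sd"`.
#' @param cna_linked If `TRUE`, downstream simulators emit matching
#'   copy-number calls for the block.
#' @param label Optional subtype label attached to the implant samples.
#' @return An `"implant_spec"` list.
#' @export
implant_spec <- function(genes, samples, effect, effect_scale = c("units", "gene_sd"),
                         cna_linked = FALSE, label = NULL) {
  effect_scale <- match.arg(effect_scale)
  if (!is.numeric(effect) || any(effect == 0)) stop("`effect` must be non-zero")
  structure(list(genes = genes, samples = samples, effect = effect,
                 effect_scale = effect_scale, cna_linked = cna_linked,
                 label = label),
            class = "implant_spec")
}

#' Implant a co-extremal block into an expression matrix
#'
#' Adds the specified effect to the gene-by-sample block. With a large
#' effect, each implanted gene's extremal set becomes exactly the implant
#' sample set; smaller effects give partial overlap.
#'
#' @param mat Numeric gene-by-sample matrix.
#' @param spec An [implant_spec()].
#' @return The matrix with the block shifted.
#' @export
implant <- function(mat, spec) {
  stopifnot(inherits(spec, "implant_spec"))
  g <- spec$genes; s <- spec$samples
  if (is.numeric(g)) g <- rownames(mat)[g]
  if (is.numeric(s)) s <- colnames(mat)[s]
  stopifnot(all(g %in% rownames(mat)), all(s %in% colnames(mat)))
  shift <- if (spec$effect_scale == "gene_sd") {
    spec$effect * apply(mat[g, , drop = FALSE], 1, stats::sd)
  } else {
    rep_len(spec$effect, length(g))
  }
  mat[g, s] <- mat[g, s] + shift  # column-major recycling: per-gene shift
  mat
}

#' Simulate a dataset with implanted biclusters and its truth table
#'
#' Generates a background matrix and applies the implants in order (effects
#' on the `gene_sd` scale are computed on the pre-implant background).
#' Overlapping implants are allowed but flagged in the truth table.
#'
#' @param n_genes,n_samples Dimensions.
#' @param implants List of [implant_spec()]s.
#' @param rng_seed Integer seed.
#' @param family,... Passed to [generate_background()].
#' @return List with `matrix` and `truth` (list: `implants`, `rng_seed`,
#'   `family`, `overlapping` flag).
#' @export
simulate_dataset <- function(n_genes, n_samples, implants, rng_seed,
                             family = "lognormal", ...) {
  bg <- generate_background(n_genes, n_samples, rng_seed, family, ...)
  resolve <- function(x, nm) if (is.numeric(x)) nm[x] else x
  implants <- lapply(implants, function(sp) {
    sp$genes <- resolve(sp$genes, rownames(bg))
    sp$samples <- resolve(sp$samples, colnames(bg))
    sp
  })
  mat <- bg
  for (sp in implants) {
    sp_units <- sp
    if (sp$effect_scale == "gene_sd") {
      sp_units$effect <- sp$effect *
        apply(bg[sp$genes, , drop = FALSE], 1, stats::sd)
      sp_units$effect_scale <- "units"
    }
    mat <- implant(mat, sp_units)
  }
  all_genes <- unlist(lapply(implants, `[[`, "genes"))
  overlapping <- anyDuplicated(all_genes) > 0
  if (overlapping) message("implants overlap in genes; flagged in the truth table")
  list(matrix = mat,
       truth = list(implants = implants, rng_seed = rng_seed,
                    family = family, overlapping = overlapping))
}

#' The default synthetic benchmark
#'
#' A lognormal background of 1,000 genes by 200 samples with 3 disjoint
#' implants of 20 genes by 10 samples each at effect +6 background standard
#' deviations -- strong, clean blocks sized for seconds-scale runs. Matching
#' copy-number calls (gain in exactly the implant samples) and a subtype
#' label per implant are emitted for the enrichment analyses.
#'
#' @param seed Integer seed (default 42).
#' @param n_genes,n_samples,n_implants,genes_per,samples_per,effect_sd
#'   Benchmark geometry; defaults as above.
#' @return List with `matrix`, `truth`, `cna` (call matrix), `labels`
#'   (sample label table with a `subtype` column).
#' @export
default_benchmark <- function(seed = 42, n_genes = 1000, n_samples = 200,
                              n_implants = 3, genes_per = 20,
                              samples_per = 10, effect_sd = 6) {
  stopifnot(n_implants * genes_per <= n_genes,
            n_implants * samples_per <= n_samples)
  implants <- lapply(seq_len(n_implants), function(i) {
    implant_spec(genes = (i - 1) * genes_per + seq_len(genes_per),
                 samples = (i - 1) * samples_per + seq_len(samples_per),
                 effect = effect_sd, effect_scale = "gene_sd",
                 cna_linked = TRUE, label = paste0("implant_", i))
  })
  sim <- simulate_dataset(n_genes, n_samples, implants, rng_seed = seed)
  cna <- matrix(0L, n_genes, n_samples, dimnames = dimnames(sim$matrix))
  subtype <- rep("background", n_samples)
  names(subtype) <- colnames(sim$matrix)
  for (sp in sim$truth$implants) {
    if (isTRUE(sp$cna_linked)) cna[sp$genes, sp$samples] <- 2L
    if (!is.null(sp$label)) subtype[sp$samples] <- sp$label
  }
  labels <- data.frame(sample_id = colnames(sim$matrix), subtype = subtype,
                       stringsAsFactors = FALSE, row.names = NULL)
  c(sim, list(cna = cna, labels = labels))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Score recovery of implanted biclusters
#'
#' For each implant, finds the bicluster maximizing the gene-set Jaccard
#' index and reports both the gene and sample Jaccard; an implant counts as
#' recovered when both are at least `threshold`.
#'
#' @param collection A `"tuba_biclusters"` collection (may be empty).
#' @param truth Truth table from [simulate_dataset()].
#' @param threshold Jaccard threshold (default 0.8).
#' @return Data frame: `implant`, `best_bicluster`, `gene_jaccard`,
#'   `sample_jaccard`, `recovered`.
#' @export
score_recovery <- function(collection, truth, threshold = 0.8) {
  implants <- truth$implants
  bics <- if (inherits(collection, "tuba_biclusters")) {
    collection$biclusters
  } else collection
  rows <- lapply(seq_along(implants), function(i) {
    sp <- implants[[i]]
    if (!length(bics)) {
      return(data.frame(implant = i, best_bicluster = NA_integer_,
                        gene_jaccard = 0, sample_jaccard = 0,
                        recovered = FALSE))
    }
    gj <- vapply(bics, function(b) jaccard(b$genes, sp$genes), 0)
    best <- which.max(gj)
    sj <- jaccard(bics[[best]]$samples, sp$samples)
    data.frame(implant = i, best_bicluster = best, gene_jaccard = gj[best],
               sample_jaccard = sj,
               recovered = gj[best] >= threshold & sj >= threshold)
  })
  do.call(rbind, rows)
}
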