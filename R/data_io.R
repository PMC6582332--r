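# Reading and writing the external formats: expression matrices, gene loci,
# copy-number calls, sample labels, and the bicluster output bundle.

validate_expression <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  dup_g <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup_g)) stop("duplicate gene identifier(s): ",
                          paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dup_s)) stop("duplicate sample identifier(s): ",
                          paste(unique(dup_s), collapse = ", "))
  invisible(mat)
}

#' Apply the load-time filters to an expression matrix
#'
#' Drops samples (columns) containing any missing value, then genes (rows)
#' with zero expression in every remaining sample. The filters are
#' idempotent. A load report (counts dropped) is emitted as a message.
#'
#' @param mat Numeric gene-by-sample matrix.
#' @return The filtered matrix.
#' @export
filter_expression <- function(mat) {
  na_sample <- apply(mat, 2, anyNA)
  mat <- mat[, !na_sample, drop = FALSE]
  zero_gene <- rowSums(mat != 0) == 0
  mat <- mat[!zero_gene, , drop = FALSE]
  message(sprintf("load filter: dropped %d sample(s) with NAs, %d all-zero gene(s); %d genes x %d samples retained",
                  sum(na_sample), sum(zero_gene), nrow(mat), ncol(mat)))
  mat
}

#' Read a gene-by-sample expression matrix
#'
#' Expects a delimited text file whose first row holds sample identifiers and
#' first column gene identifiers; values are normalized expression on
#' whatever scale the upstream pipeline produced (the algorithm only uses
#' within-gene ranks). Load-time filters drop samples with any missing value
#' and genes with zero expression in all samples.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter; `"auto"` (default) lets the reader
#'   detect it.
#' @param transpose If `TRUE`, the file is samples-in-rows and is transposed
#'   after reading.
#' @param filter Apply [filter_expression()] (default `TRUE`).
#' @return Numeric matrix, genes in rows.
#' @export
read_expression <- function(path, delimiter = "auto", transpose = FALSE,
                            filter = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          data.table = FALSE, na.strings = c("NA", ""))
  ids <- as.character(dt[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate gene identifier(s) in ", path, ": ",
                        paste(unique(dup), collapse = ", "))
  body <- dt[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at row %d (gene %s), column %d (%s)",
                     col[bad[1]], bad[1], ids[bad[1]], j + 1L,
                     names(body)[j]))
      }
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  if (transpose) mat <- t(mat)
  validate_expression(mat)
  if (filter) filter_expression(mat) else mat
}

#' Read a gene-locus annotation table
#'
#' @param path TSV with columns `gene`, `chromosome`, `start`, `end`
#'   (1-based, inclusive).
#' @return Data frame with those columns; one row per gene.
#' @export
read_gene_loci <- function(path) {
  loci <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("gene", "chromosome", "start", "end")
  if (!all(need %in% names(loci))) {
    stop("locus table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(loci$gene)) stop("duplicate gene(s) in locus table")
  if (any(loci$start > loci$end)) stop("locus with start > end")
  loci[, need]
}

#' Read a gene-by-sample copy-number call matrix
#'
#' Integer calls in the GISTIC2 style (typically -2..2); layout as in
#' [read_expression()] (genes in rows).
#'
#' @param path TSV/CSV matrix file.
#' @return Integer matrix.
#' @export
read_cna_matrix <- function(path) {
  mat <- read_expression(path, filter = FALSE)
  if (any(mat != round(mat), na.rm = TRUE)) {
    stop("copy-number calls must be integer-valued")
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Read a sample label table
#'
#' @param path TSV with a `sample_id` column plus one or more categorical
#'   columns (subtype, grade, ...).
#' @return Data frame.
#' @export
read_sample_labels <- function(path) {
  lab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!"sample_id" %in% names(lab)) stop("label table needs a sample_id column")
  if (anyDuplicated(lab$sample_id)) stop("duplicate sample_id(s) in label table")
  lab
}

# 6 significant digits, scientific notation, for serialized p-values
fmt_p <- function(p) {
  out <- formatC(p, format = "e", digits = 5)
  out[is.na(p)] <- "NA"
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write a bicluster collection to a directory
#'
#' Emits a long-format gene table, a long-format sample table, a
#' per-bicluster summary, one GraphML file per bicluster (shared samples as a
#' semicolon-joined edge attribute, for Cytoscape-style inspection), and a
#' JSON run manifest embedding the run configuration. All tables are
#' tab-separated with header rows; p-values are serialized in scientific
#' notation with 6 significant digits. Output is byte-identical across runs
#' with the same inputs and configuration.
#'
#' @param collection A `"tuba_biclusters"` collection (scored or not).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bicluster_collection <- function(collection, out_dir) {
  stopifnot(inherits(collection, "tuba_biclusters"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", out_dir)
  }
  bics <- collection$biclusters
  scored <- !is.null(collection$gene_scores)

  gene_tab <- if (length(bics)) {
    if (scored) {
      g <- collection$gene_scores
      data.frame(bicluster = g$bicluster, gene = g$gene, degree = g$degree,
                 is_seed = g$is_seed, gene_fdr = fmt_p(g$fdr),
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(seq_along(bics), function(i) {
        b <- bics[[i]]
        data.frame(bicluster = i, gene = b$genes,
                   degree = as.integer(b$degrees[b$genes]),
                   is_seed = b$genes %in% b$seed_genes, gene_fdr = "NA",
                   stringsAsFactors = FALSE)
      }))
    }
  } else {
    data.frame(bicluster = integer(0), gene = character(0),
               degree = integer(0), is_seed = logical(0),
               gene_fdr = character(0))
  }
  sample_tab <- if (length(bics)) {
    if (scored) {
      s <- collection$sample_scores
      data.frame(bicluster = s$bicluster, sample = s$sample,
                 sample_fdr = fmt_p(s$fdr), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(seq_along(bics), function(i) {
        data.frame(bicluster = i, sample = bics[[i]]$samples,
                   sample_fdr = "NA", stringsAsFactors = FALSE)
      }))
    }
  } else {
    data.frame(bicluster = integer(0), sample = character(0),
               sample_fdr = character(0))
  }
  summary_tab <- if (length(bics)) {
    data.frame(
      bicluster = seq_along(bics),
      n_genes = vapply(bics, function(b) length(b$genes), 0L),
      n_samples = vapply(bics, function(b) length(b$samples), 0L),
      n_seed_genes = vapply(bics, function(b) length(b$seed_genes), 0L),
      Q = if (!is.null(collection$quality)) collection$quality else NA_real_)
  } else {
    data.frame(bicluster = integer(0), n_genes = integer(0),
               n_samples = integer(0), n_seed_genes = integer(0),
               Q = numeric(0))
  }

  paths <- file.path(out_dir, c("bicluster_genes.tsv", "bicluster_samples.tsv",
                                "bicluster_summary.tsv", "manifest.json"))
  write_tsv(gene_tab, paths[1])
  write_tsv(sample_tab, paths[2])
  write_tsv(summary_tab, paths[3])
  gml <- character(0)
  for (i in seq_along(bics)) {
    b <- bics[[i]]
    ig <- igraph::graph_from_data_frame(
      b$edges[, c("gene1", "gene2")], directed = FALSE,
      vertices = data.frame(name = b$genes,
                            degree = as.integer(b$degrees[b$genes]),
                            is_seed = b$genes %in% b$seed_genes))
    igraph::E(ig)$shared_samples <-
      vapply(b$shared, paste, "", collapse = ";")
    igraph::E(ig)$overlap <- b$edges$m
    f <- file.path(out_dir, sprintf("bicluster_%03d.graphml", i))
    igraph::write_graph(ig, f, format = "graphml")
    gml <- c(gml, f)
  }
  manifest <- list(
    config = unclass(collection$config),
    n_biclusters = length(bics),
    n_genes = length(collection$gene_ids),
    n_samples = length(collection$sample_ids),
    files = basename(c(paths[1:3], gml)))
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(paths, gml))
}

#' Read bicluster membership back from an output directory
#'
#' Reconstructs the gene and sample membership sets written by
#' [write_bicluster_collection()]; used for round-trip checks and for feeding
#' exported runs into the comparison utilities.
#'
#' @param dir Directory written by [write_bicluster_collection()].
#' @return List with `gene_sets`, `sample_sets` (lists of character vectors,
#'   one per bicluster) and `summary` (data frame).
#' @export
read_bicluster_collection <- function(dir) {
  g <- utils::read.delim(file.path(dir, "bicluster_genes.tsv"),
                         stringsAsFactors = FALSE)
  s <- utils::read.delim(file.path(dir, "bicluster_samples.tsv"),
                         stringsAsFactors = FALSE)
  summ <- utils::read.delim(file.path(dir, "bicluster_summary.tsv"),
                            stringsAsFactors = FALSE)
  ids <- summ$bicluster
  list(gene_sets = lapply(ids, function(i) sort(g$gene[g$bicluster == i])),
       sample_sets = lapply(ids, function(i) sort(s$sample[s$bicluster == i])),
       summary = summ)
}
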