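# Independent oracles and fixture builders used across the suite.
# All oracles avoid the code paths they check: explicit binomial-coefficient
# tail sums instead of phyper, plain recursion instead of igraph cliques,
# naive fixed-point filtering instead of the sparse-matrix pruner.

# Hypergeometric upper tail P(X >= m) by explicit tail summation.
oracle_tail <- function(m, k1, k2, N) {
  mn <- min(k1, k2)
  if (m > mn) return(0)
  j <- m:mn
  sum(choose(k1, j) * choose(N - k1, k2 - j)) / choose(N, k2)
}

# Enumerate every clique (complete subgraph) of an adjacency matrix by
# recursive extension in index order; return the maximum-size ones as
# sorted name vectors in lexicographic order.
oracle_max_cliques <- function(adj, names = rownames(adj)) {
  n <- nrow(adj)
  cliques <- list()
  rec <- function(cur, cand) {
    if (length(cur) >= 2) cliques[[length(cliques) + 1L]] <<- cur
    for (v in cand) {
      rec(c(cur, v), cand[cand > v & adj[v, cand]])
    }
  }
  rec(integer(0), seq_len(n))
  if (!length(cliques)) return(list())
  sz <- lengths(cliques)
  mx <- cliques[sz == max(sz)]
  mx <- lapply(mx, function(ix) sort(names[ix]))
  unique(mx[order(vapply(mx, paste, "", collapse = "\r"))])
}

# Fixed-point edge filter: repeatedly drop edges whose endpoints have no
# common neighbour, by direct scanning.
oracle_prune <- function(edges) {  # edges: 2-column character matrix
  repeat {
    if (!nrow(edges)) return(edges)
    nbr <- function(v) {
      unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
    }
    keep <- vapply(seq_len(nrow(edges)), function(e) {
      length(intersect(nbr(edges[e, 1]), nbr(edges[e, 2]))) > 0
    }, TRUE)
    if (all(keep)) return(edges)
    edges <- edges[keep, , drop = FALSE]
  }
}

# Closed-form chi-square survival function for df = 4.
oracle_chisq4_upper <- function(x) exp(-x / 2) * (1 + x / 2)

# Random Erdos-Renyi graph as a tuba_graph (and its adjacency matrix).
random_graph <- function(n, p, seed) {
  set.seed(seed)
  nm <- sprintf("v%02d", seq_len(n))
  adj <- matrix(FALSE, n, n, dimnames = list(nm, nm))
  up <- which(upper.tri(adj))
  adj[up] <- stats::runif(length(up)) < p
  adj <- adj | t(adj)
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- data.frame(gene1 = nm[idx[, 1]], gene2 = nm[idx[, 2]],
                      stringsAsFactors = FALSE)
  list(graph = as_tuba_graph(edges), adj = adj, edges = edges)
}

# Expression fixture in which `block_genes` share an identical extremal
# sample set (huge shift) on top of an i.i.d. background.
coextremal_fixture <- function(n_genes = 100, n_samples = 200, block_genes = 3,
                               block_samples = 10, seed = 7) {
  sim <- simulate_dataset(
    n_genes, n_samples,
    implants = list(implant_spec(seq_len(block_genes),
                                 seq_len(block_samples),
                                 effect = 50, effect_scale = "gene_sd")),
    rng_seed = seed)
  sim
}
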