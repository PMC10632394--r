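# Shared fixture builders; everything is generated in code at test time.

# Two-gene system with one directed edge g1 -> g2 (effect 0.5, 1 IV/gene).
two_gene_truth <- function() {
  simulate_network(p = 2,
                   edges = data.frame(regulator = 1, target = 2,
                                      effect = 0.5),
                   ivs_per_gene = 1, seed = 7)
}

# Benchmark recovery fixture: 30 genes, 90 variants (3 IVs/gene), 25 true
# edges including 2 reciprocal pairs, cis effects in [0.7, 1.2], regulatory
# effects in [0.4, 0.8], n samples at noise sd 1.
benchmark_truth <- function(seed) {
  simulate_network(p = 30, n_edges = 25, reciprocal_pairs = 2,
                   effect_range = c(0.4, 0.8), cis_range = c(0.7, 1.2),
                   ivs_per_gene = 3, noise_sd = 1, seed = seed)
}

benchmark_dataset <- function(seed, n = 500) {
  truth <- benchmark_truth(seed)
  data <- simulate_dataset(n = n, truth = truth, maf = 0.3,
                           seed = seed + 100)
  list(truth = truth, data = data,
       dataset = preprocess_data(data))
}

# Build a grn_graph directly from an edge data frame.
graph_fixture <- function(edges, cutoff = 0.5) {
  edges <- tibble::as_tibble(edges)
  if (!"frequency" %in% names(edges)) edges$frequency <- 1
  structure(list(edges = edges,
                 genes = sort(unique(c(edges$regulator, edges$target))),
                 cutoff = cutoff, n_edges = nrow(edges)),
            class = "grn_graph")
}

# Directed one-way cycle over the given node names.
cycle_edges <- function(nodes) {
  tibble::tibble(regulator = nodes,
                 target = nodes[c(seq_along(nodes)[-1], 1)])
}

# Exhaustive set-partition generator (for brute-force modularity oracles).
all_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  rest <- all_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(items[1], q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(items[1]), p)
  }
  out
}

# Brute-force modularity from the printed formula, over all ordered pairs.
brute_modularity <- function(network, assignment) {
  genes <- network$genes
  p <- length(genes)
  E <- matrix(0, p, p, dimnames = list(genes, genes))
  E[cbind(match(network$edges$target, genes),
          match(network$edges$regulator, genes))] <- 1
  N <- sum(E)
  d <- vapply(seq_len(p), function(i) sum(E[i, -i] + E[-i, i]), numeric(1))
  comm <- assignment[genes]
  q <- 0
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (comm[i] == comm[j]) {
        q <- q + (E[i, j] + E[j, i]) - d[i] * d[j] / (2 * N)
      }
    }
  }
  q / (2 * N)
}
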