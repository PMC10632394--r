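test_that("total degree counts in- and out-edges, reciprocal pairs twice", {
  nw <- graph_fixture(tibble::tibble(
    regulator = c("a", "b", "c", "d"),
    target = c("b", "a", "a", "e")))
  expect_equal(total_degree(nw, "a"), 3)   # a<->b reciprocal (2) + c->a (1)
  expect_equal(total_degree(nw, "b"), 2)
  expect_equal(total_degree(nw, "e"), 1)
  d <- total_degree(nw)
  expect_equal(sum(d$degree), 2 * nw$n_edges)   # degree-sum identity
  expect_error(total_degree(nw, "zz"), "unknown")
})

test_that("single-community modularity is exactly zero", {
  set.seed(60)
  for (i in 1:100) {
    p <- sample(3:10, 1)
    genes <- paste0("g", seq_len(p))
    pairs <- expand.grid(regulator = genes, target = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$regulator != pairs$target, ]
    edges <- pairs[runif(nrow(pairs)) < 0.3, ]
    if (nrow(edges) == 0) next
    nw <- graph_fixture(edges)
    one <- setNames(rep(1, length(nw$genes)), nw$genes)
    expect_lt(abs(network_modularity(nw, one)), 1e-12)
  }
})

test_that("two directed triangles split as themselves score Q = 0.5", {
  nw <- graph_fixture(rbind(cycle_edges(c("a", "b", "c")),
                            cycle_edges(c("x", "y", "z"))))
  split <- setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "x", "y", "z"))
  expect_equal(network_modularity(nw, split), 0.5)
})

test_that("modularity equals brute force over every partition of small graphs", {
  set.seed(61)
  for (rep in 1:3) {
    genes <- paste0("g", 1:6)
    pairs <- expand.grid(regulator = genes, target = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$regulator != pairs$target, ]
    edges <- pairs[runif(nrow(pairs)) < 0.25, ]
    if (nrow(edges) == 0) next
    nw <- graph_fixture(edges)
    parts <- all_partitions(nw$genes)
    for (p in parts[seq(1, length(parts), by = 7)]) {
      assignment <- unlist(lapply(seq_along(p), function(i) {
        setNames(rep(i, length(p[[i]])), p[[i]])
      }))
      expect_equal(network_modularity(nw, assignment),
                   brute_modularity(nw, assignment), tolerance = 1e-12)
    }
  }
})

test_that("greedy partition recovers a planted two-clique structure", {
  clique <- function(nodes) {
    pairs <- expand.grid(regulator = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs[pairs$regulator < pairs$target, ]  # one direction per pair
  }
  edges <- rbind(clique(paste0("a", 1:4)), clique(paste0("b", 1:4)),
                 data.frame(regulator = "a1", target = "b1"))
  nw <- graph_fixture(edges)
  part <- greedy_partition(nw)
  tt <- tidy(part)
  expect_equal(length(unique(tt$community[startsWith(tt$gene, "a")])), 1)
  expect_equal(length(unique(tt$community[startsWith(tt$gene, "b")])), 1)
  expect_equal(dplyr::n_distinct(tt$community), 2)
  # exhaustive oracle: greedy Q matches the best partition over all 4140
  parts <- all_partitions(nw$genes)
  qs <- vapply(parts, function(p) {
    assignment <- unlist(lapply(seq_along(p), function(i) {
      setNames(rep(i, length(p[[i]])), p[[i]])
    }))
    network_modularity(nw, assignment)
  }, numeric(1))
  expect_equal(part$modularity, max(qs), tolerance = 1e-10)
  # self-consistency: stored Q equals independent recomputation
  expect_equal(part$modularity,
               network_modularity(nw, part$assignment), tolerance = 1e-12)
  expect_gte(part$modularity, 0)
})

test_that("greedy partition agrees with the reference fast-greedy method", {
  set.seed(62)
  genes <- paste0("g", 1:12)
  pairs <- expand.grid(regulator = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  edges <- pairs[runif(nrow(pairs)) < 0.2, ]
  nw <- graph_fixture(edges)
  part <- greedy_partition(nw)
  E <- grniv:::graph_matrix(nw); W <- E + t(E)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  ig <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  # same objective scale; our Q must be at least as good up to tie-breaks
  expect_gte(part$modularity + 1e-9,
             igraph::modularity(g, igraph::membership(ig),
                                weights = igraph::E(g)$weight))
})

test_that("subnetwork extraction matches a union-find oracle", {
  set.seed(63)
  genes <- paste0("g", 1:25)
  edges <- tibble::tibble(regulator = sample(genes, 18, TRUE),
                          target = sample(genes, 18, TRUE))
  edges <- dplyr::distinct(edges[edges$regulator != edges$target, ])
  nw <- graph_fixture(edges)
  subs <- extract_subnetworks(nw)
  # independent union-find
  parent <- seq_along(nw$genes); names(parent) <- nw$genes
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(edges))) {
    a <- find(match(edges$regulator[r], nw$genes))
    b <- find(match(edges$target[r], nw$genes))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(parent), find, numeric(1))
  expect_equal(length(subs), dplyr::n_distinct(roots))
  # sorted by size, and sizes match
  sizes <- sort(table(roots), decreasing = TRUE)
  expect_equal(vapply(subs, function(s) length(s$genes), integer(1)),
               as.integer(sizes))
})

test_that("trivial component cases behave", {
  two <- graph_fixture(tibble::tibble(regulator = c("a", "c"),
                                      target = c("b", "d")))
  subs <- extract_subnetworks(two)
  expect_length(subs, 2)
  expect_equal(vapply(subs, function(s) length(s$genes), integer(1)),
               c(2L, 2L))
  chain <- graph_fixture(tibble::tibble(regulator = c("a", "b"),
                                        target = c("b", "c")))
  expect_length(extract_subnetworks(chain), 1)
  # TF flags propagate
  subs_tf <- extract_subnetworks(chain, tf_list = c("b", "zz"))
  expect_equal(subs_tf[[1]]$tf, "b")
})
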