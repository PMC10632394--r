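# Dense binary edge matrix (rows = regulator -> column? No: E[i, j] = 1 when
# j regulates i, matching the coefficient-matrix orientation) plus node ids.
graph_matrix <- function(network) {
  genes <- network$genes
  p <- length(genes)
  E <- matrix(0, p, p, dimnames = list(genes, genes))
  if (nrow(network$edges) > 0) {
    E[cbind(match(network$edges$target, genes),
            match(network$edges$regulator, genes))] <- 1
  }
  E
}

#' Total degree of network genes
#'
#' `d(i) = sum_{j != i} (E_ij + E_ji)`: the number of genes regulating or
#' regulated by gene i, with a reciprocal pair contributing 2.
#'
#' @param network a `grn_graph`.
#' @param gene optional single gene id; returns its degree as a scalar.
#' @return Tibble (gene, degree), or a scalar when `gene` is given.
#' @export
total_degree <- function(network, gene = NULL) {
  E <- graph_matrix(network)
  d <- rowSums(E) + colSums(E)
  if (!is.null(gene)) {
    abort_if(!gene %in% network$genes, paste("unknown gene:", gene))
    return(unname(d[gene]))
  }
  tibble::tibble(gene = network$genes, degree = unname(d))
}

#' Modularity of a partition of a directed regulation network
#'
#' Evaluates
#' \deqn{Q(D) = \frac{1}{2N} \sum_{(i,j)}
#'   \Big((E_{ij} + E_{ji}) - \frac{d(i) d(j)}{2N}\Big)\,\delta_D(i,j),}
#' summing over all ordered gene pairs (self-edges are structurally zero,
#' and the i = j null term is retained so the single-community partition
#' scores exactly zero), with `N` the total number of directed regulations.
#'
#' @param network a `grn_graph` with at least one edge.
#' @param assignment named vector or tibble (gene, community) covering every
#'   network gene.
#' @return Modularity in `[-1, 1]`.
#' @export
network_modularity <- function(network, assignment) {
  abort_if(network$n_edges < 1, "modularity needs a nonempty edge set")
  comm <- normalize_assignment(network, assignment)
  E <- graph_matrix(network)
  W <- E + t(E)
  d <- rowSums(W)
  N <- sum(E)
  same <- outer(comm, comm, `==`)
  sum((W - outer(d, d) / (2 * N)) * same) / (2 * N)
}

normalize_assignment <- function(network, assignment) {
  if (is.data.frame(assignment)) {
    assignment <- setNames(assignment$community, assignment$gene)
  }
  abort_if(!all(network$genes %in% names(assignment)),
           "assignment must cover every network gene")
  assignment[network$genes]
}

#' Fast greedy modularity partition
#'
#' Agglomerative community detection on the symmetrized weights
#' `E_ij + E_ji`: starting from singleton communities, repeatedly merges the
#' community pair with the largest modularity increase (ties resolved toward
#' the lowest community-id pair), stopping when no merge increases Q, and
#' returns the best-scoring partition encountered. Run independently on each
#' weakly connected component (cross-component merges can never raise Q).
#'
#' @param network a `grn_graph` with a nonempty edge set.
#' @return Object of class `grn_partition`: `assignment` tibble (gene,
#'   community), `modularity`, `sizes`, `degrees`.
#' @export
greedy_partition <- function(network) {
  abort_if(network$n_edges < 1, "partitioning needs a nonempty edge set")
  E <- graph_matrix(network)
  W <- E + t(E)
  N <- sum(E)
  comp <- weak_components(W)
  comm <- integer(length(network$genes))
  offset <- 0L
  for (cid in sort(unique(comp))) {
    nodes <- which(comp == cid)
    labels <- greedy_merge(W[nodes, nodes, drop = FALSE], N)
    comm[nodes] <- labels + offset
    offset <- offset + max(labels)
  }
  assignment <- tibble::tibble(gene = network$genes,
                               community = match(comm, sort(unique(comm))))
  q <- network_modularity(network, assignment)
  structure(list(assignment = assignment, modularity = q,
                 sizes = dplyr::count(assignment, .data$community,
                                      name = "size"),
                 degrees = total_degree(network), network = network),
            class = "grn_partition")
}

# Agglomerative merging on one component's symmetric weight matrix.
# 2N is the whole graph's edge count, so Q gains match global modularity.
greedy_merge <- function(W, N) {
  m <- nrow(W)
  if (m == 1) return(1L)
  two_n <- 2 * N
  # e[r, s]: weight between communities r, s (halved on the diagonal terms
  # convention: use full symmetric weights; q = sum_r (e_rr - a_r^2))
  e <- W / two_n
  a <- rowSums(W) / two_n
  labels <- seq_len(m)
  active <- rep(TRUE, m)
  best_labels <- labels
  q <- sum(diag(e)) - sum(a^2)
  best_q <- q
  repeat {
    ids <- which(active)
    if (length(ids) < 2) break
    best_gain <- 0; best_pair <- NULL
    for (ri in seq_along(ids)) {
      for (si in seq_len(ri - 1)) {
        r <- ids[si]; s <- ids[ri]   # r < s
        gain <- 2 * (e[r, s] - a[r] * a[s])
        if (gain > best_gain + 1e-15) {
          best_gain <- gain; best_pair <- c(r, s)
        }
      }
    }
    if (is.null(best_pair)) break
    r <- best_pair[1]; s <- best_pair[2]
    e[r, ] <- e[r, ] + e[s, ]
    e[, r] <- e[, r] + e[, s]
    a[r] <- a[r] + a[s]
    active[s] <- FALSE
    labels[labels == s] <- r
    q <- q + best_gain
    if (q > best_q) {
      best_q <- q
      best_labels <- labels
    }
  }
  match(best_labels, sort(unique(best_labels)))
}

# Weakly connected component labels from a symmetric adjacency matrix.
weak_components <- function(W) {
  m <- nrow(W)
  comp <- integer(m)
  cid <- 0L
  for (v in seq_len(m)) {
    if (comp[v] != 0) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(W[u, ] != 0 & comp == 0)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Weakly connected subnetworks
#'
#' Decomposes the directed network into weakly connected components, sorted
#' by node count in decreasing order, optionally flagging transcription
#' factors.
#'
#' @param network a `grn_graph`.
#' @param tf_list optional character vector of transcription-factor gene
#'   ids.
#' @return List of `grn_graph` objects (largest first), each carrying its
#'   node list; the summary tibble is attached as attribute `"summary"`.
#' @export
extract_subnetworks <- function(network, tf_list = NULL) {
  if (length(network$genes) == 0) return(list())
  W <- graph_matrix(network)
  W <- W + t(W)
  comp <- weak_components(W)
  ord <- order(-tabulate(comp)[comp], network$genes)
  sizes <- sort(tabulate(comp), decreasing = TRUE)
  comp_ids <- unique(comp[ord])
  subs <- lapply(comp_ids, function(cid) {
    nodes <- network$genes[comp == cid]
    edges <- dplyr::filter(network$edges, .data$regulator %in% nodes |
                             .data$target %in% nodes)
    g <- structure(list(edges = edges, genes = nodes,
                        cutoff = network$cutoff, n_edges = nrow(edges)),
                   class = "grn_graph")
    if (!is.null(tf_list)) g$tf <- intersect(nodes, tf_list)
    g
  })
  attr(subs, "summary") <- tibble::tibble(
    subnetwork = seq_along(subs),
    n_genes = vapply(subs, function(g) length(g$genes), integer(1)),
    n_edges = vapply(subs, function(g) g$n_edges, integer(1)),
    n_tf = if (is.null(tf_list)) NA_integer_ else
      vapply(subs, function(g) length(g$tf), integer(1)))
  subs
}

#' @export
print.grn_partition <- function(x, ...) {
  cat(sprintf("<grn_partition> %d communities, Q = %.4f\n",
              nrow(x$sizes), x$modularity))
  invisible(x)
}

#' Community assignment of a partition
#'
#' @param x a `grn_partition`.
#' @param ... unused.
#' @return Tibble (gene, community, degree).
#' @method tidy grn_partition
#' @export
tidy.grn_partition <- function(x, ...) {
  dplyr::left_join(x$assignment, x$degrees, by = "gene")
}

#' One-row summary of a partition
#'
#' @param x a `grn_partition`.
#' @param ... unused.
#' @return Tibble (n_communities, modularity, largest_size).
#' @method glance grn_partition
#' @export
glance.grn_partition <- function(x, ...) {
  tibble::tibble(n_communities = nrow(x$sizes), modularity = x$modularity,
                 largest_size = max(x$sizes$size))
}

#' Edge list of a thresholded network
#'
#' @param x a `grn_graph`.
#' @param ... unused.
#' @return The edge tibble (regulator, target, frequency).
#' @method tidy grn_graph
#' @export
tidy.grn_graph <- function(x, ...) x$edges

#' One-row summary of a thresholded network
#'
#' @param x a `grn_graph`.
#' @param ... unused.
#' @return Tibble (n_genes, n_edges, cutoff, n_subnetworks).
#' @method glance grn_graph
#' @export
glance.grn_graph <- function(x, ...) {
  nsub <- if (length(x$genes) > 0) {
    W <- graph_matrix(x); max(weak_components(W + t(W)))
  } else 0L
  tibble::tibble(n_genes = length(x$genes), n_edges = x$n_edges,
                 cutoff = x$cutoff, n_subnetworks = nsub)
}

#' Degree-distribution plot of a network
#'
#' @param object a `grn_graph`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot grn_graph
#' @export
autoplot.grn_graph <- function(object, ...) {
  total_degree(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "total degree d(i)", y = "genes",
                  title = sprintf("Degree distribution (cutoff %.2f)",
                                  object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Community-size plot of a partition
#'
#' @param object a `grn_partition`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot grn_partition
#' @export
autoplot.grn_partition <- function(object, ...) {
  object$sizes |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$community),
                                 y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "community", y = "genes",
                  title = sprintf("Community sizes (Q = %.3f)",
                                  object$modularity)) +
    ggplot2::theme_minimal()
}
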