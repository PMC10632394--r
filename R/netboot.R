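#' Bootstrap the sample and aggregate edge indicators
#'
#' Resamples the `n` samples with replacement, re-runs the full two-stage
#' fit (including instrument re-discovery by default) on each replicate,
#' binarizes each replicate's coefficient matrix into an adjacency indicator
#' `A[i, j] = 1` iff the effect of gene j on gene i is nonzero, and averages
#' the indicators across replicates into the edge-confidence frequency
#' matrix `Abar = (1/B) sum_b A_b`.
#'
#' Replicate seeds are derived from `(seed, b)` by a counter scheme, so any
#' subset of replicates is reproducible independently of execution order,
#' and an interrupted run resumed from a `cache_dir` yields the same result
#' as an uninterrupted one.
#'
#' @param dataset a [regulatory_dataset()].
#' @param config a [twostage_config()].
#' @param B number of bootstrap replicates (>= 1).
#' @param seed master seed.
#' @param refit_ivs re-run instrument discovery on every replicate (default)
#'   or reuse the instrument definitions in `ivmap`, resampling their
#'   columns.
#' @param ivmap instrument map; required when `refit_ivs = FALSE`, and used
#'   for discovery parameters otherwise.
#' @param iv_args list of arguments for [discover_ivs()] on each replicate.
#' @param cache_dir optional directory for per-replicate edge caches
#'   (plain TSV; completed replicates are reloaded rather than refit).
#' @param max_retries bounded retries for failed replicates, each with a
#'   fresh derived seed.
#' @return Object of class `bootstrap_ensemble`: `B`, `frequency` (sparse
#'   p x p), `adjacency_sum`, `replicate_seeds`, `genes`.
#' @export
bootstrap_networks <- function(dataset, config = twostage_config(), B = 100,
                               seed = 1, refit_ivs = TRUE, ivmap = NULL,
                               iv_args = list(), cache_dir = NULL,
                               max_retries = 3) {
  abort_if(B < 1, "B must be >= 1")
  abort_if(!refit_ivs && is.null(ivmap),
           "ivmap is required when refit_ivs = FALSE")
  n <- nrow(dataset$expression_net)
  p <- ncol(dataset$expression_net)
  genes <- colnames(dataset$expression_net) %||% paste0("g", seq_len(p))
  run_replicate <- function(b) {
    if (!is.null(cache_dir)) {
      f <- file.path(cache_dir, sprintf("replicate_%04d.tsv", b))
      if (file.exists(f)) {
        el <- read.delim(f, stringsAsFactors = FALSE)
        return(list(edges = el, seed = derive_seed(seed, b)))
      }
    }
    attempt <- 0
    repeat {
      rep_seed <- derive_seed(seed, b + attempt * 100003)
      res <- tryCatch({
        idx <- with_seed(rep_seed, sample.int(n, n, replace = TRUE))
        boot <- resample_dataset(dataset, idx)
        im <- if (refit_ivs) {
          do.call(discover_ivs,
                  c(list(dataset = boot, seed = derive_seed(rep_seed, 7)),
                    iv_args))
        } else {
          resample_ivmap(ivmap, idx)
        }
        cfg <- config
        cfg$seed <- derive_seed(rep_seed, 11)
        fit <- fit_network(boot, im, cfg)
        s <- Matrix::summary(fit$coefficients)
        s <- s[s$x != 0, , drop = FALSE]
        list(edges = data.frame(target = s$i, regulator = s$j),
             seed = rep_seed)
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      attempt <- attempt + 1
      if (attempt > max_retries) {
        stop("bootstrap replicate ", b, " failed after retries: ",
             conditionMessage(res), call. = FALSE)
      }
      warning("replicate ", b, " failed (", conditionMessage(res),
              "); redrawing with a fresh seed")
    }
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      write.table(res$edges,
                  file.path(cache_dir, sprintf("replicate_%04d.tsv", b)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res
  }
  reps <- run_parallel(seq_len(B), run_replicate,
                       config$workers %||% 1)
  acc <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(p, p))
  for (r in reps) {
    if (nrow(r$edges) > 0) {
      acc <- acc + Matrix::sparseMatrix(i = r$edges$target,
                                        j = r$edges$regulator,
                                        x = 1, dims = c(p, p))
    }
  }
  dimnames(acc) <- list(genes, genes)
  structure(list(B = B, adjacency_sum = acc, frequency = acc / B,
                 replicate_seeds = vapply(reps, `[[`, numeric(1), "seed"),
                 genes = genes),
            class = "bootstrap_ensemble")
}

# Row-resample every aligned component of a regulatory dataset.
resample_dataset <- function(dataset, idx) {
  regulatory_dataset(dataset$expression_net[idx, , drop = FALSE],
                     dataset$expression_iv[idx, , drop = FALSE],
                     dataset$genotypes[idx, , drop = FALSE],
                     dataset$gene_annotation, dataset$variant_annotation,
                     sample_ids = dataset$sample_ids[idx],
                     qc_log = dataset$qc_log)
}

# Reuse frozen instrument definitions on a resampled dataset.
resample_ivmap <- function(ivmap, idx) {
  out <- ivmap
  out$entries <- lapply(ivmap$entries, function(e) {
    if (!is.null(e$columns)) e$columns <- e$columns[idx, , drop = FALSE]
    e
  })
  out
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("<bootstrap_ensemble> B = %d, %d gene pairs ever selected\n",
              x$B, sum(x$adjacency_sum > 0)))
  invisible(x)
}

#' Componentwise mean of binary adjacency matrices
#'
#' @param adjacencies nonempty list of equally shaped binary matrices.
#' @return The elementwise mean matrix.
#' @export
aggregate_adjacency <- function(adjacencies) {
  abort_if(length(adjacencies) == 0, "need at least one adjacency matrix")
  dims <- lapply(adjacencies, dim)
  abort_if(!all(vapply(dims, identical, logical(1), dims[[1]])),
           "adjacency matrices must share a common shape")
  Reduce(`+`, adjacencies) / length(adjacencies)
}

#' Threshold a bootstrap frequency matrix into a directed network
#'
#' Declares a directed edge j -> i wherever the bootstrap frequency
#' `Abar[i, j]` is at least `cutoff`. Zero-frequency pairs are never
#' materialized, so `cutoff = 0` returns exactly the pairs selected in at
#' least one replicate. Nodes are the genes incident to at least one edge.
#'
#' @param x a `bootstrap_ensemble`, or a frequency matrix (rows = targets).
#' @param cutoff frequency threshold in `[0, 1]` (`>=` keeps).
#' @return Object of class `grn_graph`: `edges` tibble (regulator, target,
#'   frequency), `genes` (incident nodes), `cutoff`, `n_edges`.
#' @export
threshold_network <- function(x, cutoff = 0.95) {
  abort_if(cutoff < 0 || cutoff > 1, "cutoff must be in [0, 1]")
  freq <- if (inherits(x, "bootstrap_ensemble")) x$frequency else
    methods::as(as_matrix(x, "frequency"), "sparseMatrix")
  genes <- rownames(freq) %||% paste0("g", seq_len(nrow(freq)))
  s <- Matrix::summary(methods::as(freq, "TsparseMatrix"))
  s <- s[s$x >= cutoff & s$x > 0, , drop = FALSE]
  edges <- tibble::tibble(regulator = genes[s$j], target = genes[s$i],
                          frequency = s$x) |>
    dplyr::arrange(.data$regulator, .data$target)
  structure(list(edges = edges,
                 genes = sort(unique(c(edges$regulator, edges$target))),
                 cutoff = cutoff, n_edges = nrow(edges)),
            class = "grn_graph")
}

#' @export
print.grn_graph <- function(x, ...) {
  cat(sprintf("<grn_graph> %d regulations among %d genes (cutoff %.2f)\n",
              x$n_edges, length(x$genes), x$cutoff))
  invisible(x)
}

#' Edge frequencies of a bootstrap ensemble
#'
#' @param x a `bootstrap_ensemble`.
#' @param ... unused.
#' @return Tibble with `target`, `regulator`, `frequency` for every pair
#'   selected at least once.
#' @method tidy bootstrap_ensemble
#' @export
tidy.bootstrap_ensemble <- function(x, ...) {
  s <- Matrix::summary(methods::as(x$frequency, "TsparseMatrix"))
  s <- s[s$x > 0, , drop = FALSE]
  tibble::tibble(target = x$genes[s$i], regulator = x$genes[s$j],
                 frequency = s$x) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$target)
}

#' One-row summary of a bootstrap ensemble
#'
#' @param x a `bootstrap_ensemble`.
#' @param ... unused.
#' @return Tibble with `B`, pairs ever selected, and edge counts at the
#'   1.0 and 0.95 cutoffs.
#' @method glance bootstrap_ensemble
#' @export
glance.bootstrap_ensemble <- function(x, ...) {
  tibble::tibble(B = x$B, n_pairs = sum(x$adjacency_sum > 0),
                 n_edges_100 = threshold_network(x, 1)$n_edges,
                 n_edges_95 = threshold_network(x, 0.95)$n_edges)
}

#' Edge-frequency histogram of a bootstrap ensemble
#'
#' @param object a `bootstrap_ensemble`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot bootstrap_ensemble
#' @export
autoplot.bootstrap_ensemble <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$frequency)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", colour = "grey20") +
    ggplot2::labs(x = "bootstrap frequency", y = "gene pairs",
                  title = "Edge-confidence distribution") +
    ggplot2::theme_minimal()
}
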