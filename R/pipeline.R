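#' Assemble and validate a pipeline run configuration
#'
#' Every tunable of every stage appears here with its default; unknown keys
#' are rejected, and a configuration survives a JSON round trip unchanged.
#'
#' @param ... overrides of the defaults listed below.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    # simulation (used by the packaged synthetic fixture)
    p = 30, n = 500, n_edges = 25, reciprocal_pairs = 2, ivs_per_gene = 3,
    effect_range = c(0.4, 0.8), cis_range = c(0.7, 1.2), maf = 0.3,
    noise_sd = 1,
    # preprocessing
    n_pcs = 3, sample_missing_cut = 0.1, variant_missing_cut = 0.1,
    mac_cut = 5, hwe_alpha = 1e-4,
    # IV discovery
    flank = 1000, iv_alpha = 0.05, asum_alpha0 = 0.1, asum_perms = 1000,
    max_ivs = 3, cor_cut = 0.3,
    # two-stage fit
    isis_target_size = NULL, lasso_folds = 10, lasso_rule = "1se",
    require_iv = TRUE,
    # bootstrap + reporting
    B = 100, refit_ivs = TRUE, cutoffs = c(1.0, 0.95),
    # execution
    seed = 1, workers = 1, output_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  abort_if(length(unknown) > 0,
           paste("unknown config keys:", paste(unknown, collapse = ", ")))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

config_to_twostage <- function(cfg) {
  twostage_config(isis_target_size = cfg$isis_target_size,
                  lasso_folds = cfg$lasso_folds,
                  lasso_rule = cfg$lasso_rule,
                  require_iv = cfg$require_iv, workers = cfg$workers,
                  seed = cfg$seed)
}

#' Pilot-timed batch plan for parallel execution
#'
#' Times a stage on a pilot subset of genes, records the maximum per-gene
#' wall time, and sizes batches so each task's predicted time fits the
#' per-task budget. The returned plan partitions all genes exactly once.
#'
#' @param dataset a [regulatory_dataset()].
#' @param stage `"stage1"` or `"stage2"`.
#' @param ivmap instrument map for the timed stage.
#' @param pilot_genes pilot sample size (default 10, capped at the gene
#'   count).
#' @param budget_secs per-task wall-time budget in seconds.
#' @param config a [twostage_config()].
#' @param seed seed for the pilot gene draw.
#' @return Tibble with one row per task (`task`, `genes` list-column) and
#'   attributes `batch_size`, `max_gene_secs`.
#' @export
estimate_batching <- function(dataset, stage = c("stage1", "stage2"),
                              ivmap, pilot_genes = 10, budget_secs = 60,
                              config = twostage_config(), seed = 1) {
  stage <- match.arg(stage)
  p <- ncol(dataset$expression_net)
  pilot <- with_seed(seed, sample.int(p, min(pilot_genes, p)))
  config <- resolve_config(config, nrow(dataset$expression_net))
  stage1 <- if (stage == "stage2") stage1_predict(dataset, ivmap, config)
  times <- vapply(pilot, function(k) {
    t0 <- proc.time()[["elapsed"]]
    if (stage == "stage1") {
      pool <- iv_pool(ivmap)
      keep <- isis_screen(dataset$expression_net[, k], pool$matrix,
                          target_size = config$isis_target_size)
      if (length(keep) > 0) {
        ridge_gcv(dataset$expression_net[, k],
                  pool$matrix[, keep, drop = FALSE])
      }
    } else {
      fit_gene(k, dataset, stage1, ivmap, config)
    }
    proc.time()[["elapsed"]] - t0
  }, numeric(1))
  max_t <- max(times, 1e-4)
  batch_size <- max(1L, min(p, floor(budget_secs / max_t)))
  starts <- seq(1, p, by = batch_size)
  plan <- tibble::tibble(
    task = seq_along(starts),
    genes = lapply(starts, function(s) seq(s, min(s + batch_size - 1, p))))
  attr(plan, "batch_size") <- batch_size
  attr(plan, "max_gene_secs") <- max_t
  plan
}

#' Run the full inference pipeline
#'
#' Executes, in order: synthetic-data generation (when no dataset is
#' supplied), preprocessing, instrument discovery, the two-stage network
#' fit, bootstrap aggregation, frequency thresholding, and modularity
#' partitioning. When `config$output_dir` is set, each stage's tables are
#' written as TSV plus a JSON manifest listing every output file with its
#' content hash.
#'
#' @param config a [run_config()].
#' @param data optional `synthetic_dataset`-like input; simulated from the
#'   config otherwise.
#' @return List of class `pipeline_result` with `dataset`, `ivmap`, `fit`,
#'   `ensemble`, `networks` (one `grn_graph` per cutoff), `partition` (on
#'   the lowest cutoff's network), `manifest`.
#' @export
run_pipeline <- function(config = run_config(), data = NULL) {
  if (is.null(data)) {
    truth <- simulate_network(p = config$p, n_edges = config$n_edges,
                              reciprocal_pairs = config$reciprocal_pairs,
                              effect_range = config$effect_range,
                              cis_range = config$cis_range,
                              ivs_per_gene = config$ivs_per_gene,
                              noise_sd = config$noise_sd,
                              seed = derive_seed(config$seed, 1))
    data <- simulate_dataset(config$n, truth = truth, maf = config$maf,
                             seed = derive_seed(config$seed, 2))
  }
  dataset <- preprocess_data(data, n_pcs = config$n_pcs,
                             sample_missing_cut = config$sample_missing_cut,
                             variant_missing_cut = config$variant_missing_cut,
                             mac_cut = config$mac_cut,
                             hwe_alpha = config$hwe_alpha)
  iv_args <- list(flank = config$flank, alpha = config$iv_alpha,
                  alpha0 = config$asum_alpha0, n_perm = config$asum_perms,
                  max_ivs = config$max_ivs, cor_cut = config$cor_cut)
  ivmap <- do.call(discover_ivs,
                   c(list(dataset = dataset,
                          seed = derive_seed(config$seed, 3)), iv_args))
  ts_cfg <- config_to_twostage(config)
  fit <- fit_network(dataset, ivmap, ts_cfg)
  ensemble <- bootstrap_networks(dataset, ts_cfg, B = config$B,
                                 seed = derive_seed(config$seed, 4),
                                 refit_ivs = config$refit_ivs,
                                 ivmap = ivmap, iv_args = iv_args)
  networks <- lapply(config$cutoffs, function(ct) {
    threshold_network(ensemble, ct)
  })
  names(networks) <- sprintf("cutoff_%g", config$cutoffs)
  low <- networks[[which.min(config$cutoffs)]]
  partition <- if (low$n_edges > 0) greedy_partition(low) else NULL
  manifest <- list(config = unclass(config),
                   n_genes = ncol(dataset$expression_net),
                   n_variants = ncol(dataset$genotypes),
                   n_instrument_genes = sum(vapply(
                     ivmap$entries,
                     function(e) !is.null(e$columns), logical(1))),
                   qc_log = dataset$qc_log)
  res <- structure(list(dataset = dataset, ivmap = ivmap, fit = fit,
                        ensemble = ensemble, networks = networks,
                        partition = partition, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) {
    res$manifest$files <- write_pipeline_outputs(res, config$output_dir)
  }
  res
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(dir, name)
    write.table(as.data.frame(df), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <<- c(files, f)
  }
  wr(tidy(res$fit), "network_edges.tsv")
  wr(tidy(res$ensemble), "bootstrap_frequency.tsv")
  wr(tidy(res$ivmap), "instruments.tsv")
  for (nm in names(res$networks)) {
    wr(res$networks[[nm]]$edges, paste0(nm, "_edges.tsv"))
  }
  if (!is.null(res$partition)) wr(tidy(res$partition), "communities.tsv")
  manifest <- res$manifest
  manifest$files <- tibble::tibble(
    file = basename(files), md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$files
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$fit)
  print(x$ensemble)
  for (nw in x$networks) print(nw)
  if (!is.null(x$partition)) print(x$partition)
  invisible(x)
}

#' Compare an estimated edge set with a known truth
#'
#' Precision, recall and F1 of directed edge recovery against the nonzero
#' support of a true regulation matrix.
#'
#' @param fit a `grn_fit`, `grn_graph`, or edge tibble with `regulator` and
#'   `target` columns.
#' @param truth a `sem_parameters` object (or edge tibble).
#' @return Tibble (n_true, n_est, tp, precision, recall, f1).
#' @export
edge_metrics <- function(fit, truth) {
  est <- if (inherits(fit, "grn_fit")) tidy(fit)
  else if (inherits(fit, "grn_graph")) fit$edges
  else fit
  tr <- if (inherits(truth, "sem_parameters")) tidy(truth) else truth
  key <- function(d) paste(d$regulator, d$target)
  tp <- length(intersect(key(est), key(tr)))
  precision <- if (nrow(est) == 0) NA_real_ else tp / nrow(est)
  recall <- if (nrow(tr) == 0) NA_real_ else tp / nrow(tr)
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(n_true = nrow(tr), n_est = nrow(est), tp = tp,
                 precision = precision, recall = recall, f1 = f1)
}
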