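#' Expression-level gene filter in the GTEx style
#'
#' Keeps genes expressed at TPM > `tpm_cut` in at least `frac` of samples AND
#' with at least `read_cut` reads in at least `frac` of samples.
#'
#' @param counts `n x p` raw count matrix (samples x genes).
#' @param tpm `n x p` TPM matrix, same shape and gene order.
#' @param tpm_cut TPM threshold (default 0.1, strict `>`).
#' @param frac required fraction of samples (default 0.2, `>=`).
#' @param read_cut read threshold (default 6, `>=`).
#' @return Integer vector of kept gene (column) indices with a `qc_log`
#'   attribute (tibble of counts removed).
#' @export
filter_genes_gtex <- function(counts, tpm, tpm_cut = 0.1, frac = 0.2,
                              read_cut = 6) {
  counts <- as_matrix(counts, "counts"); tpm <- as_matrix(tpm, "tpm")
  abort_if(!identical(dim(counts), dim(tpm)),
           "counts and tpm must share shape and gene order")
  keep <- colMeans(tpm > tpm_cut) >= frac & colMeans(counts >= read_cut) >= frac
  idx <- which(keep)
  attr(idx, "qc_log") <- qc_entry("filter_genes_gtex", ncol(counts), length(idx))
  idx
}

#' Expression-level gene filter in the TCGA style
#'
#' Removes genes with total count across samples below `total_cut` or with
#' zero/missing entries in more than `missing_frac` of samples (zero counts
#' are treated as missing for this rule).
#'
#' @param counts `n x p` raw count matrix (samples x genes); `NA` allowed.
#' @param total_cut total-count threshold (default 2.5e6; strict `<` removes).
#' @param missing_frac missingness threshold (default 0.8; strict `>` removes).
#' @return Kept gene indices with a `qc_log` attribute.
#' @export
filter_genes_tcga <- function(counts, total_cut = 2.5e6, missing_frac = 0.8) {
  counts <- as_matrix(counts, "counts")
  abort_if(any(counts < 0, na.rm = TRUE), "counts must be nonnegative")
  totals <- colSums(counts, na.rm = TRUE)
  miss <- colMeans(is.na(counts) | counts == 0)
  idx <- which(!(totals < total_cut | miss > missing_frac))
  attr(idx, "qc_log") <- qc_entry("filter_genes_tcga", ncol(counts), length(idx))
  idx
}

qc_entry <- function(step, n_in, n_out) {
  tibble::tibble(step = step, n_in = n_in, removed = n_in - n_out,
                 n_out = n_out)
}

#' Trimmed-mean-of-M-values (TMM) normalization
#'
#' Computes per-sample TMM scaling factors from their published definition:
#' the reference library is the one whose upper-quartile (of counts scaled by
#' library size) is closest to the mean upper-quartile; each sample's factor
#' is `2^f` with `f` the inverse-asymptotic-variance-weighted mean of gene-wise
#' log2 ratios (M-values), after trimming the most extreme 30% of M-values and
#' 5% of A-values; factors are renormalized to geometric mean 1. The
#' normalized output is `log2(count / (lib.size * factor) * mean(lib.size)
#' + 0.5)`.
#'
#' @param counts `n x p` nonnegative count matrix (samples x genes).
#' @param logratio_trim,sum_trim trim fractions for M and A values.
#' @return List with `factors` (length n), `log2` (`n x p` matrix) and `ref`
#'   (reference sample index).
#' @export
tmm_normalize <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as_matrix(counts, "counts")
  abort_if(nrow(counts) < 2, "TMM needs at least 2 samples")
  abort_if(any(counts < 0), "counts must be nonnegative")
  lib <- rowSums(counts)
  abort_if(any(lib == 0), "all-zero library encountered")
  f75 <- apply(counts / lib, 1, quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(nrow(counts)), function(i) {
    tmm_pair_factor(counts[i, ], counts[ref, ], lib[i], lib[ref],
                    logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  norm <- log2(counts / (lib * f) * mean(lib) + 0.5)
  list(factors = f, log2 = norm, ref = ref)
}

# One sample's TMM factor against the reference library.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  f <- sum(M[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Median-of-ratios size factors with log2 output
#'
#' Variance-stabilizing substitute for count normalization: size factors are
#' the per-sample median ratio to the gene-wise geometric-mean reference
#' (computed over genes with all-positive counts), and the output is
#' `log2(count / size_factor + 1)`.
#'
#' @param counts `n x p` nonnegative count matrix (samples x genes).
#' @return List with `size_factors` (length n) and `log2` matrix.
#' @export
vst_substitute <- function(counts) {
  counts <- as_matrix(counts, "counts")
  abort_if(any(counts < 0), "counts must be nonnegative")
  pos <- colSums(counts > 0) == nrow(counts)
  abort_if(!any(pos),
           "no gene with all-positive counts: size factors undefined")
  ref <- exp(colMeans(log(counts[, pos, drop = FALSE])))
  sf <- apply(counts[, pos, drop = FALSE], 1, function(r) median(r / ref))
  list(size_factors = sf, log2 = log2(counts / sf + 1))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the allele counts, the p-value is the total
#' probability of heterozygote counts whose conditional probability under
#' Hardy-Weinberg equilibrium does not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (nonnegative integers, total >= 1).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  abort_if(any(c(n_AA, n_Aa, n_aa) < 0) || n_AA + n_Aa + n_aa < 1,
           "genotype counts must be nonnegative with total >= 1")
  n <- n_AA + n_Aa + n_aa
  rare <- 2 * min(n_AA, n_aa) + n_Aa          # minor allele count
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  # log conditional probability of each heterozygote count, up to a constant
  lp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_com <- n - h - hom_rare
    h * log(2) - lgamma(hom_rare + 1) - lgamma(h + 1) - lgamma(hom_com + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  p <- sum(pr[pr <= pr[match(n_Aa, hets)] * (1 + 1e-12)])
  min(1, p)
}

#' Impute missing genotype calls with the major allele
#'
#' Replaces each variant's missing entries with the dosage of its homozygous
#' major genotype (2 when the counted allele is the major allele, 0
#' otherwise).
#'
#' @param genotypes dosage matrix in {0, 1, 2, NA}.
#' @return Complete dosage matrix (no `NA`).
#' @export
impute_major_allele <- function(genotypes) {
  X <- as_matrix(genotypes, "genotypes")
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (!any(miss)) next
    abort_if(all(miss), sprintf("variant %d has no observed call", j))
    fill <- if (mean(X[!miss, j]) / 2 > 0.5) 2 else 0
    X[miss, j] <- fill
  }
  X
}

#' Genotype quality-control filters
#'
#' Applies, in order: (1) drop samples with genotype missing rate >
#' `sample_missing_cut`; (2) drop variants with missing rate >
#' `variant_missing_cut` across remaining samples; (3) drop variants whose
#' Hardy-Weinberg exact-test p-value falls below `hwe_alpha`; (4) drop
#' variants with minor-allele count below `mac_cut`. Missing calls are then
#' imputed with the major allele.
#'
#' @param genotypes dosage matrix in {0, 1, 2, NA} (samples x variants).
#' @param sample_missing_cut,variant_missing_cut missing-rate cutoffs
#'   (default 0.1; strict `>` removes).
#' @param hwe_alpha HWE p-value cutoff (default 1e-4; strict `<` removes).
#' @param mac_cut minimum minor-allele count (default 5; `<` removes).
#' @param impute impute residual missingness with the major allele.
#' @return List with `genotypes` (filtered, imputed), `kept_samples`,
#'   `kept_variants` (indices into the input) and `qc_log` tibble.
#' @export
filter_variants <- function(genotypes, sample_missing_cut = 0.1,
                            variant_missing_cut = 0.1, mac_cut = 5,
                            hwe_alpha = 1e-4, impute = TRUE) {
  X <- as_matrix(genotypes, "genotypes")
  log <- list()
  samp_keep <- which(rowMeans(is.na(X)) <= sample_missing_cut)
  log[[1]] <- qc_entry("sample_missing", nrow(X), length(samp_keep))
  X <- X[samp_keep, , drop = FALSE]
  var_keep <- which(colMeans(is.na(X)) <= variant_missing_cut)
  log[[2]] <- qc_entry("variant_missing", ncol(X), length(var_keep))
  X <- X[, var_keep, drop = FALSE]
  hwe_p <- apply(X, 2, function(g) {
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  hwe_keep <- which(hwe_p >= hwe_alpha)
  log[[3]] <- qc_entry("hwe", ncol(X), length(hwe_keep))
  X <- X[, hwe_keep, drop = FALSE]
  mac <- apply(X, 2, function(g) {
    g <- g[!is.na(g)]
    ac <- sum(g)
    min(ac, 2 * length(g) - ac)
  })
  mac_keep <- which(mac >= mac_cut)
  log[[4]] <- qc_entry("mac", ncol(X), length(mac_keep))
  X <- X[, mac_keep, drop = FALSE]
  abort_if(ncol(X) == 0 || nrow(X) == 0,
           "no samples or variants survive genotype QC")
  if (impute && anyNA(X)) X <- impute_major_allele(X)
  list(genotypes = X, kept_samples = samp_keep,
       kept_variants = var_keep[hwe_keep][mac_keep],
       qc_log = dplyr::bind_rows(log))
}

#' Principal components of the genotype matrix
#'
#' Top-k principal-component scores of the column-standardized dosage matrix,
#' used to adjust expression for population stratification before local
#' association scans. Signs are fixed by making each component's
#' largest-magnitude loading positive, so scores are deterministic.
#'
#' @param genotypes complete dosage matrix.
#' @param k number of components (default 3).
#' @return `n x k` score matrix.
#' @export
genotype_pca <- function(genotypes, k = 3) {
  X <- as_matrix(genotypes, "genotypes")
  abort_if(anyNA(X), "genotypes must be complete (impute first)")
  keep <- apply(X, 2, sd) > 0
  Xs <- scale(X[, keep, drop = FALSE])
  abort_if(k > min(nrow(Xs) - 1, ncol(Xs)),
           "k exceeds the rank of the genotype matrix")
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- pc$x[, seq_len(k), drop = FALSE] %*% diag(flip, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Remove confounder effects from expression by linear regression
#'
#' Per gene, returns the ordinary-least-squares residuals of expression on
#' an intercept, the one-hot-encoded covariates, and (optionally) genotype
#' principal components. Collinear design columns are dropped with a warning.
#'
#' @param expression `n x p` matrix.
#' @param covariates data frame of per-sample covariates (may be `NULL`).
#' @param genotype_pcs optional `n x k` PC score matrix to include.
#' @return Residual expression matrix, same shape, orthogonal to the design.
#' @export
adjust_confounders <- function(expression, covariates = NULL,
                               genotype_pcs = NULL) {
  Y <- as_matrix(expression, "expression")
  D <- matrix(1, nrow(Y), 1)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    cv <- as.data.frame(covariates)
    cv <- cv[, !vapply(cv, function(x) length(unique(x)) <= 1, logical(1)),
             drop = FALSE]
    if (ncol(cv) > 0) {
      D <- cbind(D, stats::model.matrix(~ ., data = cv)[, -1, drop = FALSE])
    }
  }
  if (!is.null(genotype_pcs)) D <- cbind(D, as_matrix(genotype_pcs, "pcs"))
  abort_if(nrow(D) != nrow(Y), "covariates must be row-aligned with expression")
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    warning("dropping ", ncol(D) - qd$rank, " collinear design column(s)")
  }
  resid <- Y - qr.fitted(qd, Y)
  dimnames(resid) <- dimnames(Y)
  resid
}

#' Assemble an aligned dataset for network inference
#'
#' Bundles covariate-adjusted expression (`expression_net`, used for the
#' transcriptome-wide stages), additionally PC-adjusted expression
#' (`expression_iv`, used only for instrument discovery), complete genotypes
#' and annotations into the common currency passed between pipeline stages.
#'
#' @param expression_net,expression_iv `n x p` matrices, identical shape and
#'   gene order.
#' @param genotypes complete `n x q` dosage matrix.
#' @param gene_annotation,variant_annotation annotation tibbles (1-based,
#'   inclusive coordinates).
#' @param sample_ids character sample identifiers.
#' @param qc_log tibble of applied filters.
#' @return An object of class `regulatory_dataset`.
#' @export
regulatory_dataset <- function(expression_net, expression_iv, genotypes,
                               gene_annotation, variant_annotation,
                               sample_ids = NULL, qc_log = NULL) {
  en <- as_matrix(expression_net, "expression_net")
  ei <- as_matrix(expression_iv, "expression_iv")
  X <- as_matrix(genotypes, "genotypes")
  abort_if(!identical(dim(en), dim(ei)),
           "expression matrices must have identical shape")
  abort_if(nrow(en) != nrow(X), "expression and genotypes must be row-aligned")
  abort_if(anyNA(X), "genotypes must be complete")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(en)))
  abort_if(length(sample_ids) != nrow(en), "sample_ids length mismatch")
  structure(list(expression_net = en, expression_iv = ei, genotypes = X,
                 gene_annotation = gene_annotation,
                 variant_annotation = variant_annotation,
                 sample_ids = sample_ids,
                 qc_log = qc_log %||% tibble::tibble()),
            class = "regulatory_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.regulatory_dataset <- function(x, ...) {
  cat(sprintf("<regulatory_dataset> %d samples, %d genes, %d variants\n",
              nrow(x$expression_net), ncol(x$expression_net),
              ncol(x$genotypes)))
  invisible(x)
}

#' Preprocess a synthetic dataset into inference-ready form
#'
#' Applies genotype QC (missingness, Hardy-Weinberg, minor-allele count) with
#' major-allele imputation, then builds the two adjusted expression versions:
#' `expression_net` (covariates regressed out) and `expression_iv`
#' (covariates plus top genotype principal components regressed out).
#'
#' @param data a `synthetic_dataset` (or compatible list).
#' @param n_pcs number of genotype PCs to remove for IV discovery (default 3).
#' @param ... passed to [filter_variants()].
#' @return A [regulatory_dataset()].
#' @export
preprocess_data <- function(data, n_pcs = 3, ...) {
  fv <- filter_variants(data$genotypes, ...)
  Y <- data$expression[fv$kept_samples, , drop = FALSE]
  covs <- data$covariates
  if (!is.null(covs)) {
    covs <- as.data.frame(covs)[fv$kept_samples,
                                setdiff(names(covs), "sample_id"),
                                drop = FALSE]
  }
  k_max <- min(sum(apply(fv$genotypes, 2, sd) > 0),
               nrow(fv$genotypes) - 1)
  pcs <- if (n_pcs > 0) genotype_pca(fv$genotypes, k = min(n_pcs, k_max))
  else NULL
  en <- adjust_confounders(Y, covs)
  ei <- adjust_confounders(Y, covs, genotype_pcs = pcs)
  va <- data$variant_annotation[fv$kept_variants, , drop = FALSE]
  sample_ids <- if (!is.null(rownames(Y))) rownames(Y) else
    paste0("s", fv$kept_samples)
  regulatory_dataset(en, ei, fv$genotypes, data$gene_annotation, va,
                     sample_ids = sample_ids, qc_log = fv$qc_log)
}
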