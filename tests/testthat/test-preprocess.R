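test_that("GTEx-style gene filter applies both boundary rules", {
  n <- 100
  # gene 1: TPM > 0.1 in only 19% of samples -> removed
  tpm1 <- c(rep(1, 19), rep(0.05, 81))
  # gene 2: all counts exactly 6, all TPM 1 -> kept (boundaries satisfied)
  # gene 3: enough TPM but too few reads -> removed
  counts <- cbind(rep(100, n), rep(6, n), c(rep(6, 19), rep(0, 81)))
  tpm <- cbind(tpm1, rep(1, n), rep(1, n))
  kept <- filter_genes_gtex(counts, tpm)
  expect_equal(as.integer(kept), 2L)
  qc <- attr(kept, "qc_log")
  expect_equal(qc$n_in - qc$removed, qc$n_out)
})

test_that("GTEx filter kept set matches hand enumeration on a toy matrix", {
  set.seed(40)
  n <- 50
  counts <- matrix(rpois(n * 10, 8), n, 10)
  tpm <- matrix(runif(n * 10, 0, 0.4), n, 10)
  kept <- filter_genes_gtex(counts, tpm)
  manual <- which(vapply(1:10, function(j) {
    mean(tpm[, j] > 0.1) >= 0.2 && mean(counts[, j] >= 6) >= 0.2
  }, logical(1)))
  expect_equal(as.integer(kept), manual)
})

test_that("TCGA-style filter applies the total-count and missingness rules", {
  n <- 10
  counts <- cbind(rep(249999.9, n),          # total 2,499,999 -> removed
                  rep(250000, n),            # total 2,500,000 -> kept
                  c(rep(0, 9), 5e6))         # 90% zero -> removed
  kept <- filter_genes_tcga(counts)
  expect_equal(as.integer(kept), 2L)
  expect_error(filter_genes_tcga(matrix(-1, 2, 2)), "nonnegative")
})

test_that("TMM factors are 1 for identical and scaled libraries", {
  set.seed(7)
  base <- rpois(300, 50) + 1
  same <- rbind(base, base, base)
  expect_equal(tmm_normalize(same)$factors, rep(1, 3))
  scaled <- rbind(base, 3 * base)   # identical composition, 3x library
  expect_equal(tmm_normalize(scaled)$factors, rep(1, 2))
})

test_that("TMM matches the reference implementation and renormalizes", {
  set.seed(8)
  cnt <- matrix(rnbinom(6 * 500, mu = 60 * exp(rnorm(3000, 0, 0.7)),
                        size = 4), nrow = 6)
  res <- tmm_normalize(cnt)
  ref <- edgeR::calcNormFactors(t(cnt), method = "TMM")
  expect_equal(res$factors, unname(ref), tolerance = 1e-10)
  expect_equal(exp(mean(log(res$factors))), 1, tolerance = 1e-12)
  expect_error(tmm_normalize(rbind(c(0, 0), c(1, 2))), "all-zero")
})

test_that("median-of-ratios size factors behave on constructed tables", {
  base <- c(10, 40, 25, 100, 7)
  two <- rbind(base, base)
  r <- vst_substitute(two)
  expect_equal(unname(r$size_factors), c(1, 1))
  expect_equal(r$log2[1, ], r$log2[2, ])
  dbl <- rbind(base, 2 * base)
  expect_equal(unname(vst_substitute(dbl)$size_factors), c(sqrt(1/2), sqrt(2)),
               tolerance = 1e-12)
  # toy 5x4 table against a scratch median-of-ratios computation
  set.seed(9)
  cnt <- matrix(rpois(20, 30) + 1, 5, 4)
  sf <- vst_substitute(cnt)$size_factors
  ref <- exp(colMeans(log(cnt)))   # per-gene geometric mean across samples
  manual <- apply(cnt, 1, function(r) median(r / ref))
  expect_equal(unname(sf), unname(manual))
  expect_error(vst_substitute(matrix(c(0, 1, 1, 0), 2, 2)), "undefined")
})

test_that("Hardy-Weinberg exact test matches a brute-force enumeration oracle", {
  # independent oracle: direct conditional probability via choose()
  oracle <- function(aa, ab, bb) {
    n <- aa + ab + bb
    r <- 2 * min(aa, bb) + ab
    hets <- seq(r %% 2, min(r, 2 * n - r), by = 2)
    pr <- vapply(hets, function(h) {
      nr <- (r - h) / 2
      choose(n, nr) * choose(n - nr, h) * 2^h / choose(2 * n, r)
    }, numeric(1))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(ab, hets)] * (1 + 1e-9)])
  }
  expect_equal(hwe_exact_test(1, 0, 0), 1)
  expect_equal(hwe_exact_test(57, 14, 50), oracle(57, 14, 50))
  set.seed(10)
  for (i in 1:40) {
    n <- sample(3:200, 1)
    aa <- sample(0:n, 1); ab <- sample(0:(n - aa), 1); bb <- n - aa - ab
    p <- hwe_exact_test(aa, ab, bb)
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(p, oracle(aa, ab, bb), tolerance = 1e-9)
  }
})

test_that("major-allele imputation fills by the dominant allele", {
  X <- cbind(c(0, 0, 1, NA), c(2, 2, 1, NA), c(1, 1, NA, NA))
  out <- impute_major_allele(X)
  expect_equal(out[4, 1], 0)
  expect_equal(out[4, 2], 2)
  expect_false(anyNA(out))
  expect_error(impute_major_allele(cbind(c(NA_real_, NA_real_))),
               "observed")
})

test_that("variant QC applies missing, HWE and MAC rules in order", {
  set.seed(11)
  n <- 1000
  good <- simulate_genotypes(n, 0.3, variants = 3, seed = 1)
  mono <- matrix(0, n, 1)                       # MAC 0 -> removed
  mac4 <- matrix(c(rep(1, 4), rep(0, n - 4)), n, 1)   # MAC 4 -> removed
  mac5 <- matrix(c(rep(1, 5), rep(0, n - 5)), n, 1)   # MAC 5 -> kept
  hwe_bad <- matrix(c(rep(0, 900), rep(1, 50), rep(2, 50)), n, 1)
  X <- cbind(good, mono, mac4, mac5, hwe_bad)
  res <- filter_variants(X)
  expect_equal(unname(res$kept_variants), c(1:3, 6))
  expect_false(anyNA(res$genotypes))
  # hwe oracle agrees that (900, 50, 50) is discordant at alpha 1e-4
  expect_lt(hwe_exact_test(900, 50, 50), 1e-4)
  # idempotence: filtering a clean matrix changes nothing
  res2 <- filter_variants(res$genotypes)
  expect_identical(res2$genotypes, res$genotypes)
  # qc_log is internally consistent
  expect_true(all(res$qc_log$n_in - res$qc_log$removed == res$qc_log$n_out))
})

test_that("missing-rate cuts act at the 10% boundary", {
  n <- 20
  X <- simulate_genotypes(n, 0.4, variants = 10, seed = 3)
  X[1, 1:3] <- NA                      # sample 1: 30% missing -> dropped
  res <- filter_variants(X, mac_cut = 0, hwe_alpha = 0)
  expect_false(1 %in% res$kept_samples)
  X2 <- simulate_genotypes(50, 0.4, variants = 20, seed = 4)
  X2[1:6, 1] <- NA                     # variant 1: 12% missing -> dropped
  X2[7:11, 2] <- NA                    # variant 2: exactly 10% -> kept
  # every sample has at most 1 of 20 variants missing (5%), so none drops
  res2 <- filter_variants(X2, mac_cut = 0, hwe_alpha = 0)
  expect_false(1 %in% res2$kept_variants)
  expect_true(2 %in% res2$kept_variants)
})

test_that("confounder adjustment returns residuals orthogonal to the design", {
  set.seed(12)
  n <- 80
  covs <- data.frame(sex = sample(c("F", "M"), n, TRUE),
                     age = rnorm(n))
  Y <- matrix(rnorm(n * 5), n, 5)
  resid <- adjust_confounders(Y, covs)
  D <- model.matrix(~ sex + age, covs)
  expect_lt(max(abs(crossprod(D, resid))), 1e-8)
  # intercept-only: column centering
  expect_equal(adjust_confounders(Y, NULL),
               scale(Y, scale = FALSE), ignore_attr = TRUE)
  # perfect linear dependence gives ~zero residuals
  Y2 <- outer(covs$age, c(1, -2))
  expect_lt(max(abs(adjust_confounders(Y2, covs))), 1e-8)
})

test_that("genotype PCA separates synthetic subpopulations deterministically", {
  set.seed(13)
  X <- rbind(simulate_genotypes(60, maf = rep(c(0.05, 0.4), 10), seed = 1),
             simulate_genotypes(60, maf = rep(c(0.4, 0.05), 10), seed = 2))
  pcs <- genotype_pca(X, k = 3)
  grp <- rep(1:2, each = 60)
  expect_gt(abs(mean(pcs[grp == 1, 1]) - mean(pcs[grp == 2, 1])),
            2 * (sd(pcs[grp == 1, 1]) + sd(pcs[grp == 2, 1])) / 2)
  expect_identical(pcs, genotype_pca(X, k = 3))  # sign-fixed, deterministic
  expect_error(genotype_pca(X[1:3, ], k = 3), "rank")
})

test_that("net and IV expression differ only by the genotype-PC projection", {
  d <- simulate_dataset(n = 150, p = 6, n_edges = 4, ivs_per_gene = 3,
                        seed = 14)
  ds <- preprocess_data(d, n_pcs = 3)
  pcs <- genotype_pca(ds$genotypes, k = 3)
  gap <- ds$expression_net - ds$expression_iv
  # the gap lies in the span of [covariate design | PCs]; projecting the gap
  # onto PCs plus covariates reproduces it
  covs <- as.data.frame(d$covariates[, c("sex", "batch")])
  D <- cbind(model.matrix(~ sex + batch, covs), pcs)
  fitted <- D %*% qr.coef(qr(D), gap)
  expect_lt(max(abs(gap - fitted)), 1e-8)
})
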