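#' Variants inside a gene's cis window
#'
#' Returns the indices of variants lying within the gene body extended by
#' `flank` base pairs on each side (clamped at position 1), on the gene's
#' chromosome. Coordinates are 1-based inclusive.
#'
#' @param gene one-row data frame with `chrom`, `start`, `end`.
#' @param variants data frame with `chrom`, `pos` (row order = column order
#'   of the genotype matrix).
#' @param flank window extension in base pairs (default 1000).
#' @return Integer vector of variant indices (possibly empty).
#' @export
cis_window <- function(gene, variants, flank = 1000) {
  if (!gene$chrom %in% variants$chrom) {
    warning("chromosome ", gene$chrom, " absent from variant annotation")
    return(integer(0))
  }
  lo <- max(1, gene$start - flank)
  hi <- gene$end + flank
  which(variants$chrom == gene$chrom & variants$pos >= lo &
          variants$pos <= hi)
}

#' Minor-allele-frequency stratum of a variant
#'
#' MAF is `min(mean(dosage)/2, 1 - mean(dosage)/2)`. Strata: `common` when
#' MAF >= 0.05, `low` when 0.01 <= MAF < 0.05, `rare` when MAF < 0.01.
#'
#' @param dosages complete dosage vector in {0, 1, 2} (or a precomputed MAF
#'   when `is_maf = TRUE`).
#' @param is_maf interpret `dosages` as MAF values directly.
#' @return Character vector of stratum labels.
#' @export
categorize_maf <- function(dosages, is_maf = FALSE) {
  maf <- if (is_maf) dosages else {
    m <- mean(dosages) / 2
    min(m, 1 - m)
  }
  dplyr::case_when(maf >= 0.05 ~ "common", maf >= 0.01 ~ "low",
                   TRUE ~ "rare")
}

#' Marginal association scan of one variant
#'
#' Simple linear regression of expression on dosage: slope and two-sided
#' t-test p-value.
#'
#' @param expression gene expression vector (PC-adjusted version).
#' @param dosages aligned dosage vector; must not be constant.
#' @return List with `effect` and `p_value`.
#' @export
marginal_iv_test <- function(expression, dosages) {
  abort_if(length(expression) != length(dosages), "length mismatch")
  abort_if(sd(dosages) == 0, "constant dosage vector")
  n <- length(expression)
  gc <- dosages - mean(dosages); yc <- expression - mean(expression)
  ssg <- sum(gc^2)
  slope <- sum(gc * yc) / ssg
  rss <- sum((yc - slope * gc)^2)
  se <- sqrt(rss / (n - 2) / ssg)
  t <- slope / se
  list(effect = slope, p_value = 2 * pt(-abs(t), df = n - 2))
}

# Vectorized |t| statistics of y on each column of the centered matrix Gc.
marginal_t <- function(Gc, yc, ssg, n) {
  slopes <- as.numeric(crossprod(Gc, yc)) / ssg
  rss <- sum(yc^2) - slopes^2 * ssg
  rss[rss < 0] <- 0
  se <- sqrt(rss / (n - 2) / ssg)
  list(slope = slopes, t = slopes / se)
}

#' Data-adaptive burden (aSum) permutation test
#'
#' Aggregates low-MAF/rare variants in a gene's window into a single burden
#' score while guarding against power loss from opposite-direction effects:
#' variants whose marginal effect is negative with marginal p < `alpha0` have
#' their centered dosage negated before summation. Significance of the
#' burden-score association is assessed by permuting the phenotype and
#' re-running the full adaptive procedure on each permutation, with add-one
#' smoothing `(r + 1) / (n_perm + 1)`.
#'
#' @param expression gene expression vector.
#' @param rare_dosages `n x m` dosage matrix of the window's low-MAF/rare
#'   variants (m >= 1).
#' @param alpha0 flip threshold on the marginal p-value (default 0.1).
#' @param n_perm number of phenotype permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return List with `score` (the adaptive burden vector on the observed
#'   data), `flips` (logical), `statistic` (|t| of the burden association)
#'   and `p_value`.
#' @export
asum_test <- function(expression, rare_dosages, alpha0 = 0.1, n_perm = 1000,
                      seed = 1) {
  G <- as_matrix(rare_dosages, "rare_dosages")
  abort_if(ncol(G) < 1, "aSum needs at least one variant")
  abort_if(nrow(G) != length(expression), "sample mismatch")
  n <- nrow(G); m <- ncol(G)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  ssg <- colSums(Gc^2)
  abort_if(any(ssg == 0), "constant variant column in aSum input")
  t_crit <- -stats::qt(alpha0 / 2, df = n - 2)
  run_one <- function(yc) {
    mt <- marginal_t(Gc, yc, ssg, n)
    flips <- mt$slope < 0 & abs(mt$t) > t_crit
    s <- ifelse(flips, -1, 1)
    burden <- as.numeric(Gc %*% s)
    ssb <- sum(burden^2)
    slope <- sum(burden * yc) / ssb
    rss <- sum(yc^2) - slope^2 * ssb
    stat <- abs(slope) / sqrt(max(rss, 0) / (n - 2) / ssb)
    list(stat = stat, flips = flips, burden = burden)
  }
  yc <- expression - mean(expression)
  obs <- run_one(yc)
  r <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      run_one(yc[sample.int(n)])$stat >= obs$stat
    }, logical(1)))
  })
  list(score = obs$burden, flips = obs$flips, statistic = obs$stat,
       p_value = (r + 1) / (n_perm + 1))
}

#' Greedy decorrelated selection of instrumental variables
#'
#' Keeps candidates significant at `alpha`, sorts them by ascending p-value
#' (ties broken by genomic position, then by index), and greedily accepts a
#' candidate only if its absolute Pearson correlation with every
#' already-accepted instrument column stays below `cor_cut`, stopping at
#' `max_ivs`.
#'
#' @param candidates tibble with columns `id`, `p_value`, optionally
#'   `position` and `stratum`, and a list-column `column` holding each
#'   candidate's n-vector (dosages, or an aggregated burden score).
#' @param alpha significance gate (default 0.05, strict `<`).
#' @param max_ivs maximum instruments per gene (default 3).
#' @param cor_cut pairwise absolute-correlation bound (default 0.3,
#'   strict `<`).
#' @return The accepted rows of `candidates`, in acceptance order.
#' @export
select_ivs <- function(candidates, alpha = 0.05, max_ivs = 3, cor_cut = 0.3) {
  if (nrow(candidates) == 0) return(candidates)
  sig <- candidates[candidates$p_value < alpha, , drop = FALSE]
  if (nrow(sig) == 0) return(sig)
  pos <- if ("position" %in% names(sig)) sig$position else seq_len(nrow(sig))
  sig <- sig[order(sig$p_value, pos, seq_len(nrow(sig))), , drop = FALSE]
  taken <- integer(0)
  for (i in seq_len(nrow(sig))) {
    if (length(taken) >= max_ivs) break
    cand <- sig$column[[i]]
    ok <- all(vapply(taken, function(j) {
      abs(cor(cand, sig$column[[j]])) < cor_cut
    }, logical(1)))
    if (ok) taken <- c(taken, i)
  }
  sig[taken, , drop = FALSE]
}

#' Discover cis instrumental variables for every gene
#'
#' For each gene: scan its cis window (gene body +/- `flank` bp), stratify
#' variants by MAF, test common variants marginally against the PC-adjusted
#' expression, pool low-MAF and rare variants into an adaptive burden (aSum)
#' candidate, then select up to `max_ivs` decorrelated instruments
#' significant at `alpha`.
#'
#' @param dataset a [regulatory_dataset()].
#' @param flank cis window flank in bp (default 1000).
#' @param alpha per-candidate significance level (default 0.05).
#' @param alpha0,n_perm aSum tuning (see [asum_test()]).
#' @param max_ivs,cor_cut selection caps (see [select_ivs()]).
#' @param pool_rare pool low-MAF and rare strata into one burden candidate
#'   (default) or test the two strata separately.
#' @param bonferroni divide `alpha` by the number of candidates in the
#'   window (off by default: a single prespecified level is used).
#' @param seed RNG seed (aSum permutations).
#' @return An object of class `iv_map`: per-gene instrument column matrices
#'   plus a summary tibble.
#' @export
discover_ivs <- function(dataset, flank = 1000, alpha = 0.05, alpha0 = 0.1,
                         n_perm = 1000, max_ivs = 3, cor_cut = 0.3,
                         pool_rare = TRUE, bonferroni = FALSE, seed = 1) {
  genes <- dataset$gene_annotation
  p <- nrow(genes)
  X <- dataset$genotypes
  entries <- vector("list", p)
  for (k in seq_len(p)) {
    win <- cis_window(genes[k, ], dataset$variant_annotation, flank)
    y <- dataset$expression_iv[, k]
    cands <- tibble::tibble(id = character(), p_value = numeric(),
                            position = numeric(), stratum = character(),
                            members = list(), column = list())
    if (length(win) > 0) {
      strata <- vapply(win, function(j) categorize_maf(X[, j]), character(1))
      informative <- apply(X[, win, drop = FALSE], 2, sd) > 0
      common <- win[strata == "common" & informative]
      for (j in common) {
        mt <- marginal_iv_test(y, X[, j])
        cands <- dplyr::bind_rows(cands, tibble::tibble(
          id = dataset$variant_annotation$variant_id[j],
          p_value = mt$p_value,
          position = dataset$variant_annotation$pos[j],
          stratum = "common", members = list(j), column = list(X[, j])))
      }
      rare_sets <- if (pool_rare) {
        list(lowrare = win[strata %in% c("low", "rare") & informative])
      } else {
        list(low = win[strata == "low" & informative],
             rare = win[strata == "rare" & informative])
      }
      for (nm in names(rare_sets)) {
        rs <- rare_sets[[nm]]
        if (length(rs) == 0) next
        at <- asum_test(y, X[, rs, drop = FALSE], alpha0 = alpha0,
                        n_perm = n_perm, seed = derive_seed(seed, k))
        cands <- dplyr::bind_rows(cands, tibble::tibble(
          id = paste0(genes$gene_id[k], "_", nm, "_burden"),
          p_value = at$p_value,
          position = min(dataset$variant_annotation$pos[rs]),
          stratum = nm, members = list(rs), column = list(at$score)))
      }
    }
    a <- if (bonferroni && nrow(cands) > 0) alpha / nrow(cands) else alpha
    sel <- select_ivs(cands, alpha = a, max_ivs = max_ivs, cor_cut = cor_cut)
    cols <- if (nrow(sel) > 0) {
      m <- do.call(cbind, sel$column)
      colnames(m) <- sel$id
      m
    } else NULL
    entries[[k]] <- list(
      info = if (nrow(sel) > 0) {
        dplyr::mutate(sel[, c("id", "p_value", "position", "stratum",
                              "members")],
                      gene = genes$gene_id[k], .before = 1)
      } else NULL,
      columns = cols, members = sel$members)
  }
  structure(list(genes = genes$gene_id, entries = entries,
                 params = list(flank = flank, alpha = alpha,
                               max_ivs = max_ivs, cor_cut = cor_cut)),
            class = "iv_map")
}

#' @export
print.iv_map <- function(x, ...) {
  n_iv <- vapply(x$entries, function(e) {
    if (is.null(e$columns)) 0L else ncol(e$columns)
  }, integer(1))
  cat(sprintf("<iv_map> %d genes, %d with instruments, %d instruments total\n",
              length(x$genes), sum(n_iv > 0), sum(n_iv)))
  invisible(x)
}

#' Summary table of an instrument map
#'
#' @param x an `iv_map`.
#' @param ... unused.
#' @return Tibble: gene, instrument id, stratum, p-value, member count.
#' @method tidy iv_map
#' @export
tidy.iv_map <- function(x, ...) {
  rows <- purrr::compact(purrr::map(x$entries, "info"))
  if (length(rows) == 0) {
    return(tibble::tibble(gene = character(), id = character(),
                          p_value = numeric(), position = numeric(),
                          stratum = character(), n_members = integer()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(n_members = lengths(.data$members)) |>
    dplyr::select(-"members")
}

# Instrument columns of one gene (n x s matrix or NULL).
iv_columns <- function(ivmap, k) ivmap$entries[[k]]$columns

# Pooled genome-wide instrument matrix with the owning gene of each column.
iv_pool <- function(ivmap) {
  cols <- list(); owner <- integer(0)
  for (k in seq_along(ivmap$entries)) {
    m <- ivmap$entries[[k]]$columns
    if (is.null(m)) next
    cols[[length(cols) + 1]] <- m
    owner <- c(owner, rep(k, ncol(m)))
  }
  if (length(cols) == 0) return(list(matrix = NULL, owner = integer(0)))
  list(matrix = do.call(cbind, cols), owner = owner)
}
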