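#' Ground-truth structural model for a gene regulatory system
#'
#' Container for the parameters of the linear structural equation model
#' \deqn{Y = Y \Gamma + X \Psi + \epsilon,}
#' where `gamma` (\eqn{\Gamma}, p x p) holds regulatory effects with a zero
#' diagonal, `psi` (\eqn{\Psi}, q x p) holds sparse cis-genetic effects whose
#' nonzero rows for gene k are restricted to that gene's own instrument
#' variants, and `noise_sd` scales the per-gene Gaussian disturbances.
#' `gamma[j, k]` is the effect of gene j on gene k, so column k collects the
#' regulators of gene k.
#'
#' @param gamma p x p numeric matrix of regulatory effects, zero diagonal.
#' @param psi q x p numeric matrix of cis effects.
#' @param noise_sd length-p (or scalar) disturbance standard deviations.
#' @param iv_assignment list mapping each gene index to the variant indices
#'   it owns (its candidate cis instruments).
#' @param spectral_bound upper bound that the spectral radius of `gamma` must
#'   stay strictly below so that `I - gamma` is invertible with a convergent
#'   reduced form.
#' @return An object of class `sem_parameters`.
#' @export
sem_parameters <- function(gamma, psi, noise_sd = 1, iv_assignment,
                           spectral_bound = 0.8) {
  gamma <- as_matrix(gamma, "gamma")
  psi <- as_matrix(psi, "psi")
  p <- ncol(gamma)
  q <- nrow(psi)
  abort_if(nrow(gamma) != p, "gamma must be square")
  abort_if(ncol(psi) != p, "psi must have one column per gene")
  abort_if(any(diag(gamma) != 0), "gamma must have an all-zero diagonal")
  rho <- spectral_radius(gamma)
  abort_if(rho >= spectral_bound,
           sprintf("spectral radius of gamma (%.3f) must be < %.3f",
                   rho, spectral_bound))
  abort_if(length(iv_assignment) != p,
           "iv_assignment must have one entry per gene")
  noise_sd <- rep_len(noise_sd, p)
  abort_if(any(noise_sd <= 0), "noise_sd must be positive")
  # cis structure: psi rows outside the owner's assignment must be zero
  owner <- rep(NA_integer_, q)
  for (k in seq_len(p)) owner[iv_assignment[[k]]] <- k
  nz <- which(psi != 0, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    abort_if(any(owner[nz[, 1]] != nz[, 2], na.rm = TRUE) ||
               anyNA(owner[nz[, 1]]),
             "nonzero psi entries must lie in the owning gene's iv_assignment")
  }
  structure(
    list(gamma = gamma, psi = psi, noise_sd = noise_sd,
         gene_count = p, variant_count = q,
         iv_assignment = iv_assignment, spectral_bound = spectral_bound),
    class = "sem_parameters"
  )
}

#' @export
print.sem_parameters <- function(x, ...) {
  cat(sprintf(
    "<sem_parameters> %d genes, %d variants, %d regulatory edges, rho(gamma) = %.3f\n",
    x$gene_count, x$variant_count, sum(x$gamma != 0),
    spectral_radius(x$gamma)))
  invisible(x)
}

#' Simulate a sparse (possibly cyclic) regulatory structure
#'
#' Draws a ground-truth regulation matrix \eqn{\Gamma} with random support and
#' random-sign effects, cis effect matrix \eqn{\Psi}, and the gene -> variant
#' instrument assignment. Cyclic structures (reciprocal pairs, longer loops)
#' are permitted when `allow_cycles = TRUE`; after sampling, \eqn{\Gamma} is
#' rescaled if needed so its spectral radius stays strictly below
#' `spectral_bound`, guaranteeing a unique reduced form.
#'
#' The edge support can be specified three ways: `edge_density` (each ordered
#' off-diagonal pair is an edge independently with this probability),
#' `n_edges` (exactly this many edges drawn uniformly), or an explicit
#' `edges` data frame with columns `regulator`, `target` and optionally
#' `effect` for full control.
#'
#' @param p number of genes (>= 2).
#' @param edge_density probability that an ordered gene pair carries an edge.
#' @param n_edges exact number of edges (alternative to `edge_density`).
#' @param edges explicit edge table overriding random support.
#' @param effect_range magnitude range (low, high) for regulatory effects;
#'   signs are random.
#' @param cis_range magnitude range for cis effects in psi.
#' @param ivs_per_gene number of cis variants assigned to each gene.
#' @param allow_cycles if `FALSE`, support is restricted to the strict upper
#'   triangle of a random gene ordering (an acyclic graph).
#' @param reciprocal_pairs number of reciprocal pairs (i <-> j) forced into
#'   the support when `allow_cycles = TRUE`.
#' @param noise_sd per-gene disturbance SD.
#' @param spectral_bound spectral-radius bound for gamma (default 0.8).
#' @param seed integer RNG seed.
#' @return A [sem_parameters()] object.
#' @examples
#' truth <- simulate_network(p = 10, n_edges = 8, seed = 1)
#' sum(truth$gamma != 0)
#' @export
simulate_network <- function(p, edge_density = NULL, n_edges = NULL,
                             edges = NULL, effect_range = c(0.4, 0.8),
                             cis_range = c(0.7, 1.2), ivs_per_gene = 3,
                             allow_cycles = TRUE, reciprocal_pairs = 0,
                             noise_sd = 1, spectral_bound = 0.8, seed = 1) {
  abort_if(p < 2, "p must be >= 2")
  abort_if(length(effect_range) != 2 || effect_range[1] <= 0 ||
             effect_range[1] > effect_range[2],
           "effect_range must satisfy 0 < low <= high")
  abort_if(!is.null(edge_density) &&
             (edge_density < 0 || edge_density >= 1),
           "edge_density must be in [0, 1)")
  with_seed(seed, {
    gamma <- matrix(0, p, p)
    if (!is.null(edges)) {
      for (r in seq_len(nrow(edges))) {
        eff <- if ("effect" %in% names(edges)) edges$effect[r] else
          sample(c(-1, 1), 1) * runif(1, effect_range[1], effect_range[2])
        gamma[edges$regulator[r], edges$target[r]] <- eff
      }
    } else {
      offdiag <- which(row(gamma) != col(gamma))
      if (!allow_cycles) {
        ord <- sample.int(p)
        rank_of <- order(ord)
        offdiag <- offdiag[rank_of[row(gamma)[offdiag]] <
                             rank_of[col(gamma)[offdiag]]]
      }
      support <- integer(0)
      if (reciprocal_pairs > 0) {
        abort_if(!allow_cycles,
                 "reciprocal pairs require allow_cycles = TRUE")
        pairs <- matrix(sample.int(p, 2 * reciprocal_pairs), ncol = 2)
        support <- c((pairs[, 2] - 1) * p + pairs[, 1],
                     (pairs[, 1] - 1) * p + pairs[, 2])
        support <- support[row(gamma)[support] != col(gamma)[support]]
      }
      if (!is.null(n_edges)) {
        extra <- setdiff(offdiag, support)
        need <- max(0, n_edges - length(support))
        abort_if(need > length(extra), "n_edges exceeds available gene pairs")
        support <- c(support, sample(extra, need))
      } else if (!is.null(edge_density)) {
        rest <- setdiff(offdiag, support)
        support <- c(support, rest[runif(length(rest)) < edge_density])
      }
      gamma[support] <- sample(c(-1, 1), length(support), replace = TRUE) *
        runif(length(support), effect_range[1], effect_range[2])
    }
    diag(gamma) <- 0
    # cycle safety: shrink toward the bound while preserving support
    rho <- spectral_radius(gamma)
    tries <- 0
    while (rho >= spectral_bound && tries < 20) {
      gamma <- gamma * (0.95 * spectral_bound / rho)
      rho <- spectral_radius(gamma)
      tries <- tries + 1
    }
    abort_if(rho >= spectral_bound,
             "could not rescale gamma below the spectral bound")
    q <- p * ivs_per_gene
    iv_assignment <- split(seq_len(q), rep(seq_len(p), each = ivs_per_gene))
    names(iv_assignment) <- NULL
    psi <- matrix(0, q, p)
    for (k in seq_len(p)) {
      idx <- iv_assignment[[k]]
      psi[idx, k] <- sample(c(-1, 1), length(idx), replace = TRUE) *
        runif(length(idx), cis_range[1], cis_range[2])
    }
    sem_parameters(gamma, psi, noise_sd, iv_assignment, spectral_bound)
  })
}

#' Simulate genotype dosages under Hardy-Weinberg proportions
#'
#' Each variant's dosage (count of its target allele) is drawn as
#' Binomial(2, MAF) independently across samples. Variant positions are
#' assigned inside the owning gene's genomic interval when a `sem_parameters`
#' object (or its annotations) defines the geometry, so that cis-window
#' scanning operates on realistic coordinates.
#'
#' @param n number of samples.
#' @param maf target minor-allele frequency per variant, recycled to the
#'   variant count; all values must lie in (0, 0.5].
#' @param variants number of variants (defaults to `length(maf)`).
#' @param seed RNG seed.
#' @return An `n x variants` integer dosage matrix in {0, 1, 2} with the
#'   target MAFs attached as attribute `"maf"`.
#' @export
simulate_genotypes <- function(n, maf, variants = length(maf), seed = 1) {
  maf <- rep_len(maf, variants)
  abort_if(any(maf <= 0 | maf > 0.5), "all MAF targets must be in (0, 0.5]")
  with_seed(seed, {
    X <- vapply(maf, function(f) rbinom(n, 2L, f), integer(n))
    dim(X) <- c(n, variants)
    colnames(X) <- paste0("v", seq_len(variants))
    attr(X, "maf") <- maf
    X
  })
}

#' Gene and variant annotations for a simulated model
#'
#' Lays each gene out on chromosome "1" as a disjoint 2 kb interval with 10 kb
#' spacing (so +/-1 kb cis windows never overlap across genes) and places each
#' gene's instrument variants at distinct positions inside its interval.
#'
#' @param params a [sem_parameters()] object.
#' @param gene_length,gene_spacing interval geometry in base pairs.
#' @return A list with tibbles `gene_annotation` (gene_id, chrom, start, end)
#'   and `variant_annotation` (variant_id, chrom, pos, gene).
#' @export
build_annotations <- function(params, gene_length = 2000,
                              gene_spacing = 10000) {
  p <- params$gene_count
  start <- 1 + (seq_len(p) - 1) * gene_spacing
  genes <- tibble::tibble(
    gene_id = paste0("g", seq_len(p)), chrom = "1",
    start = start, end = start + gene_length - 1L)
  rows <- purrr::map_dfr(seq_len(p), function(k) {
    idx <- params$iv_assignment[[k]]
    m <- length(idx)
    pos <- genes$start[k] + round(seq(0.1, 0.9, length.out = max(m, 1)) *
                                    (gene_length - 1))
    tibble::tibble(variant = idx, pos = pos[seq_len(m)], gene = k)
  })
  rows <- rows[order(rows$variant), ]
  variants <- tibble::tibble(
    variant_id = paste0("v", rows$variant), chrom = "1",
    pos = rows$pos, gene = genes$gene_id[rows$gene])
  list(gene_annotation = genes, variant_annotation = variants)
}

#' Solve the structural model for expression
#'
#' Draws disturbances \eqn{\epsilon} with independent Gaussian columns and
#' returns \eqn{Y = (X \Psi + \epsilon)(I - \Gamma)^{-1}}, the unique reduced
#' form of the structural system. The realized disturbance draw is attached as
#' attribute `"epsilon"` so the defining identity
#' \eqn{Y(I - \Gamma) = X\Psi + \epsilon} can be checked exactly.
#'
#' @param params a [sem_parameters()] object.
#' @param genotypes `n x q` dosage matrix with `q = params$variant_count`.
#' @param seed RNG seed for the disturbance draw.
#' @param confounder_sd if positive, a shared per-sample confounder scaled by
#'   this SD is added to every gene's disturbance (for testing covariate
#'   adjustment); the structural identity still holds for the stored epsilon.
#' @return `n x p` expression matrix with attribute `"epsilon"`.
#' @export
simulate_expression <- function(params, genotypes, seed = 1,
                                confounder_sd = 0) {
  X <- as_matrix(genotypes, "genotypes")
  abort_if(ncol(X) != params$variant_count,
           "genotype column count must equal params$variant_count")
  p <- params$gene_count
  n <- nrow(X)
  I_minus_gamma <- diag(p) - params$gamma
  d <- determinant(I_minus_gamma, logarithm = TRUE)
  abort_if(!is.finite(d$modulus), "I - gamma is singular: invalid model")
  with_seed(seed, {
    eps <- matrix(rnorm(n * p), n, p) %*% diag(params$noise_sd, p)
    if (confounder_sd > 0) {
      u <- rnorm(n)
      eps <- eps + outer(u * confounder_sd, rep(1, p))
    }
    Y <- (X %*% params$psi + eps) %*% solve(I_minus_gamma)
    colnames(Y) <- paste0("g", seq_len(p))
    attr(Y, "epsilon") <- eps
    Y
  })
}

#' Render log-scale expression as negative-binomial counts
#'
#' Produces a raw-count matrix whose per-sample expected totals follow the
#' supplied library sizes and whose within-sample composition is proportional
#' to `2^expression`, with negative-binomial dispersion. Used to exercise
#' count-level preprocessing (filters, normalization) on synthetic data.
#'
#' @param expression `n x p` log2-scale expression matrix.
#' @param library_sizes length-n positive totals (recycled).
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); must be > 0.
#' @param seed RNG seed.
#' @return `n x p` nonnegative integer matrix.
#' @export
render_counts <- function(expression, library_sizes = 1e6, dispersion = 0.05,
                          seed = 1) {
  abort_if(dispersion <= 0, "dispersion must be > 0")
  E <- as_matrix(expression, "expression")
  n <- nrow(E)
  ls <- rep_len(library_sizes, n)
  abort_if(any(ls <= 0), "library sizes must be positive")
  w <- 2^E
  mu <- (w / rowSums(w)) * ls
  with_seed(seed, {
    cnt <- matrix(rnbinom(length(mu), size = 1 / dispersion, mu = mu),
                  n, ncol(E))
    dimnames(cnt) <- dimnames(E)
    cnt
  })
}

#' Simulate a complete synthetic regulatory dataset
#'
#' Convenience wrapper tying the generator together: regulatory structure
#' (unless supplied), Hardy-Weinberg genotypes at the requested MAF strata,
#' expression solving the structural model, genomic annotations, sample
#' covariates (sex and sequencing batch, with no expression effect unless
#' `covariate_sd > 0`, in which case their effect enters through the
#' disturbance term so the structural identity is preserved), and optionally
#' a negative-binomial raw-count rendering.
#'
#' @param n sample count.
#' @param truth optional [sem_parameters()]; simulated from `...` otherwise.
#' @param maf MAF targets recycled across variants (default common, 0.3).
#' @param covariate_sd SD of covariate effects injected into the disturbance.
#' @param missing_rate fraction of genotype entries masked to `NA` (for QC
#'   tests).
#' @param render_counts if `TRUE`, also draw raw counts.
#' @param seed master seed; all component draws derive from it.
#' @param ... passed to [simulate_network()] when `params` is `NULL`.
#' @return An object of class `synthetic_dataset`.
#' @export
simulate_dataset <- function(n, truth = NULL, maf = 0.3, covariate_sd = 0,
                             missing_rate = 0, render_counts = FALSE,
                             seed = 1, ...) {
  params <- truth
  if (is.null(params)) params <- simulate_network(seed = derive_seed(seed, 1), ...)
  X <- simulate_genotypes(n, maf, variants = params$variant_count,
                          seed = derive_seed(seed, 2))
  ann <- build_annotations(params)
  covariates <- with_seed(derive_seed(seed, 3), tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    batch = sample(c("b1", "b2"), n, replace = TRUE)))
  Y <- simulate_expression(params, X, seed = derive_seed(seed, 4))
  if (covariate_sd > 0) {
    D <- cbind(covariates$sex == "M", covariates$batch == "b2") * 1
    B <- with_seed(derive_seed(seed, 5),
                   matrix(rnorm(2 * params$gene_count, sd = covariate_sd),
                          2, params$gene_count))
    eps <- attr(Y, "epsilon") + D %*% B
    Y <- (X %*% params$psi + eps) %*% solve(diag(params$gene_count) - params$gamma)
    colnames(Y) <- paste0("g", seq_len(params$gene_count))
    attr(Y, "epsilon") <- eps
  }
  if (missing_rate > 0) {
    X <- with_seed(derive_seed(seed, 6), {
      mask <- matrix(runif(length(X)) < missing_rate, nrow(X))
      X[mask] <- NA_integer_
      X
    })
  }
  counts <- if (render_counts) {
    render_counts(Y - min(Y) + 4, library_sizes = 1e6, dispersion = 0.05,
                  seed = derive_seed(seed, 7))
  } else NULL
  rownames(Y) <- covariates$sample_id
  rownames(X) <- covariates$sample_id
  structure(
    list(genotypes = X, expression = Y, raw_counts = counts,
         gene_annotation = ann$gene_annotation,
         variant_annotation = ann$variant_annotation,
         covariates = covariates, truth = params, seed = seed),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d samples, %d genes, %d variants (seed %d)\n",
              nrow(x$expression), ncol(x$expression), ncol(x$genotypes),
              x$seed))
  invisible(x)
}

#' True edge list of a structural model
#'
#' @param x a `sem_parameters` object.
#' @param ... unused.
#' @return Tibble with columns `regulator`, `target`, `effect`.
#' @method tidy sem_parameters
#' @export
tidy.sem_parameters <- function(x, ...) {
  nz <- which(x$gamma != 0, arr.ind = TRUE)
  tibble::tibble(regulator = paste0("g", nz[, 1]),
                 target = paste0("g", nz[, 2]),
                 effect = x$gamma[nz]) |>
    dplyr::arrange(.data$target, .data$regulator)
}
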