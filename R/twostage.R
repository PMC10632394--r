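#' Configuration for the two-stage network estimator
#'
#' Collects every tunable of the two-stage procedure with its default.
#'
#' @param isis_target_size number of instrument columns retained by the
#'   screening step before ridge prediction; default `floor(n / log(n))`
#'   (resolved at fit time).
#' @param isis_batch columns added per screening iteration; default
#'   `ceiling(target_size / 3)`.
#' @param ridge_grid ridge penalty grid; default 50 log-spaced values
#'   spanning `[1e-4, 1e4]` times the mean squared singular value of the
#'   design.
#' @param lasso_folds cross-validation folds for the adaptive LASSO
#'   (default 10).
#' @param lasso_lambda optional fixed LASSO penalty; `0` reduces stage 2 to
#'   unpenalized least squares on the candidate set (used for classical
#'   two-stage least squares equivalence checks).
#' @param lasso_rule penalty choice along the cross-validation curve:
#'   `"1se"` (default; the sparsest penalty within one standard error of the
#'   minimum, which controls false edges) or `"min"` (the plain minimizer).
#' @param require_iv restrict candidate regulators to genes holding at least
#'   one instrument (default `TRUE`; the rank condition for identifying a
#'   regulator's effect needs an instrument for that regulator).
#' @param exclude_own_ivs drop a gene's own instruments from its stage-1
#'   prediction pool (default `FALSE`; the stage-2 projection removes the
#'   gene's own cis component regardless).
#' @param workers worker processes for per-gene fits; results are
#'   worker-count invariant.
#' @param seed master seed for cross-validation fold assignment.
#' @return A list of class `twostage_config`.
#' @export
twostage_config <- function(isis_target_size = NULL, isis_batch = NULL,
                            ridge_grid = NULL, lasso_folds = 10,
                            lasso_lambda = NULL, lasso_rule = c("1se", "min"),
                            require_iv = TRUE,
                            exclude_own_ivs = FALSE, workers = 1, seed = 1) {
  lasso_rule <- match.arg(lasso_rule)
  structure(list(isis_target_size = isis_target_size,
                 isis_batch = isis_batch, ridge_grid = ridge_grid,
                 lasso_folds = lasso_folds, lasso_lambda = lasso_lambda,
                 lasso_rule = lasso_rule,
                 require_iv = require_iv, exclude_own_ivs = exclude_own_ivs,
                 workers = workers, seed = seed),
            class = "twostage_config")
}

#' Iterative sure independence screening
#'
#' Ranks pool columns by absolute marginal correlation with the current
#' residual, retains a batch, refits (ridge with GCV) on the retained set,
#' recomputes the residual, and repeats until `target_size` columns are
#' retained or no remaining column correlates with the residual. Iterating
#' on residuals recovers predictors whose marginal correlation with the raw
#' target is masked by other predictors, which one-pass screening misses.
#'
#' @param target response vector.
#' @param iv_pool `n x Q` predictor matrix.
#' @param target_size number of columns to retain.
#' @param batch_size columns added per iteration (default
#'   `ceiling(target_size / 3)`).
#' @return Integer vector of retained column indices (ordered by entry).
#' @export
isis_screen <- function(target, iv_pool, target_size,
                        batch_size = NULL) {
  P <- as_matrix(iv_pool, "iv_pool")
  abort_if(target_size < 1, "target_size must be >= 1")
  Q <- ncol(P)
  if (Q <= target_size) return(seq_len(Q))
  if (is.null(batch_size)) batch_size <- ceiling(target_size / 3)
  usable <- which(apply(P, 2, sd) > 0)
  retained <- integer(0)
  resid <- target - mean(target)
  while (length(retained) < target_size) {
    pool <- setdiff(usable, retained)
    if (length(pool) == 0) break
    r <- abs(suppressWarnings(cor(P[, pool, drop = FALSE], resid)))
    r[is.na(r)] <- 0
    if (max(r) < 1e-12) break
    take <- pool[order(r, decreasing = TRUE)]
    take <- take[seq_len(min(batch_size, target_size - length(retained),
                             length(take)))]
    retained <- c(retained, take)
    fit <- ridge_gcv(target, P[, retained, drop = FALSE])
    resid <- target - fit$fitted
  }
  retained
}

#' Ridge regression with generalized cross-validation
#'
#' Solves the ridge problem over a penalty grid on mean-centered data (the
#' intercept is unpenalized via centering) using the singular-value
#' decomposition, and returns the solution at the GCV-minimizing penalty
#' `GCV(lambda) = n RSS(lambda) / (n - tr(S_lambda))^2`, ties resolved
#' toward the smaller penalty.
#'
#' @param target response vector.
#' @param design `n x m` predictor matrix.
#' @param lambda_grid penalty grid; default 50 log-spaced values over
#'   `[1e-4, 1e4]` times the mean squared singular value.
#' @return List with `coefficients`, `intercept`, `fitted`, `lambda`
#'   (chosen), and `gcv` (tibble of the grid).
#' @export
ridge_gcv <- function(target, design, lambda_grid = NULL) {
  X <- as_matrix(design, "design")
  abort_if(ncol(X) < 1, "design must have at least one column")
  n <- nrow(X)
  xm <- colMeans(X); ym <- mean(target)
  Xc <- sweep(X, 2, xm); yc <- target - ym
  sv <- svd(Xc)
  d2 <- sv$d^2
  if (is.null(lambda_grid)) {
    s <- mean(d2)
    if (s <= 0) s <- 1
    lambda_grid <- exp(seq(log(1e-4 * s), log(1e4 * s), length.out = 50))
  }
  uty <- crossprod(sv$u, yc)
  yss <- sum(yc^2)
  stats_grid <- vapply(lambda_grid, function(l) {
    shrink <- d2 / (d2 + l)
    fit_u <- shrink * uty
    rss <- yss - 2 * sum(uty * fit_u) + sum(fit_u^2)
    df <- sum(shrink)
    denom <- n - df
    gcv <- if (denom <= 0) Inf else n * rss / denom^2
    c(rss = max(rss, 0), df = df, gcv = gcv)
  }, numeric(3))
  if (all(!is.finite(stats_grid["gcv", ]))) {
    warning("all penalties give n - tr(S) <= 0; using the largest penalty")
    best <- length(lambda_grid)
  } else {
    best <- which.min(stats_grid["gcv", ])  # which.min takes the first tie
  }
  l <- lambda_grid[best]
  coef <- sv$v %*% ((sv$d / (d2 + l)) * uty)
  fitted <- as.numeric(Xc %*% coef) + ym
  list(coefficients = as.numeric(coef), intercept = ym - sum(xm * coef),
       fitted = fitted, lambda = l,
       gcv = tibble::tibble(lambda = lambda_grid,
                            rss = stats_grid["rss", ],
                            df = stats_grid["df", ],
                            gcv = stats_grid["gcv", ]))
}

#' Residual-maker projection onto the orthocomplement of a column space
#'
#' Builds the operator `v -> v - X (X'X)^{-1} X' v` for the given columns,
#' stored through its low-rank pieces (never as a dense n x n matrix).
#' With zero columns the operator is the identity. Collinear columns are
#' dropped by pivoted QR at tolerance 1e-10.
#'
#' @param X_Sk `n x s` matrix of a gene's instrument columns (s >= 0), or
#'   `NULL`.
#' @return An object of class `residual_projection`; apply it with
#'   [project_residual()].
#' @export
make_projection <- function(X_Sk) {
  if (is.null(X_Sk) || NCOL(X_Sk) == 0) {
    return(structure(list(X = NULL), class = "residual_projection"))
  }
  X <- as_matrix(X_Sk, "X_Sk")
  qx <- qr(X, tol = 1e-10)
  if (qx$rank < ncol(X)) {
    warning("dropping ", ncol(X) - qx$rank,
            " collinear instrument column(s)")
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  g <- crossprod(X)
  inv <- tryCatch(solve(g), error = function(e) {
    stop("singular instrument gram matrix", call. = FALSE)
  })
  structure(list(X = X, XtX_inv = inv), class = "residual_projection")
}

#' Apply a residual-maker projection
#'
#' @param proj a [make_projection()] object.
#' @param v vector or matrix with matching row count.
#' @return The projected vector/matrix (same shape as `v`).
#' @export
project_residual <- function(proj, v) {
  if (is.null(proj$X)) return(v)
  v - proj$X %*% (proj$XtX_inv %*% crossprod(proj$X, v))
}

#' Adaptive LASSO with cross-validated penalty
#'
#' Weighted L1 regression: columns are standardized internally, per-column
#' weights are `1 / |beta_init|` with `beta_init` from ridge regression
#' (GCV-tuned) on the same data (columns with `|beta_init| < 1e-10` are
#' excluded), the weighted problem is solved over a log-spaced penalty path,
#' and the penalty is chosen by k-fold cross-validation with the fold
#' assignment fixed by `seed`. Coefficients are returned on the original
#' scale. Response and predictors are mean-centered (unpenalized intercept).
#'
#' @param response numeric vector.
#' @param design `n x m` predictor matrix.
#' @param folds CV folds (default 10).
#' @param seed seed fixing the fold assignment.
#' @param lambda optional fixed penalty; `0` means unpenalized least squares
#'   on the weight-eligible columns.
#' @param weight_exponent exponent on the initial estimate (default 1).
#' @param rule `"1se"` or `"min"` (see [twostage_config()]).
#' @param foldid optional explicit fold assignment (overrides `seed`).
#' @return Numeric coefficient vector of length `ncol(design)` (zeros for
#'   excluded columns), with the chosen penalty as attribute `"lambda"`.
#' @export
adaptive_lasso <- function(response, design, folds = 10, seed = 1,
                           lambda = NULL, weight_exponent = 1,
                           rule = c("1se", "min"), foldid = NULL) {
  rule <- match.arg(rule)
  X <- as_matrix(design, "design")
  n <- nrow(X); m <- ncol(X)
  out <- numeric(m)
  yc <- response - mean(response)
  sds <- apply(X, 2, sd)
  ok <- which(sds > 1e-12)
  if (length(ok) == 0) {
    warning("no informative predictor column; returning the empty model")
    return(structure(out, lambda = NA_real_))
  }
  Xs <- scale(X[, ok, drop = FALSE])
  init <- ridge_gcv(yc, Xs)$coefficients
  w <- 1 / abs(init)^weight_exponent
  active <- which(is.finite(w) & abs(init) >= 1e-10)
  if (length(active) == 0) {
    warning("all adaptive weights infinite; returning the empty model")
    return(structure(out, lambda = NA_real_))
  }
  Xa <- Xs[, active, drop = FALSE]
  wa <- w[active]
  if (!is.null(lambda) && lambda == 0) {
    beta <- qr.coef(qr(cbind(1, Xa)), yc)[-1]
    beta[is.na(beta)] <- 0
    out[ok[active]] <- beta / sds[ok[active]]
    return(structure(out, lambda = 0))
  }
  if (length(active) == 1) {
    # glmnet needs >= 2 columns; with one candidate the weighted-L1 solution
    # is closed-form soft-thresholded least squares, tuned by the same CV.
    res <- lasso_single_cv(as.numeric(Xa), yc, folds = folds,
                           seed = derive_seed(seed, 131), rule = rule,
                           foldid = foldid)
    out[ok[active]] <- res$beta / sds[ok[active]]
    return(structure(out, lambda = res$lambda))
  }
  if (!is.null(lambda)) {
    # fixed penalty: solve exactly at that value, no cross-validation
    g <- glmnet::glmnet(Xa, yc, penalty.factor = wa, standardize = FALSE,
                        intercept = FALSE, lambda = lambda)
    beta <- as.numeric(g$beta)
    out[ok[active]] <- beta / sds[ok[active]]
    return(structure(out, lambda = lambda))
  }
  if (is.null(foldid)) {
    foldid <- with_seed(derive_seed(seed, 97), {
      sample(rep_len(seq_len(folds), n))
    })
  }
  cv <- glmnet::cv.glmnet(Xa, yc, foldid = foldid, penalty.factor = wa,
                          standardize = FALSE, intercept = FALSE)
  sel_lambda <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- as.numeric(coef(cv$glmnet.fit, s = sel_lambda, exact = FALSE))[-1]
  out[ok[active]] <- beta / sds[ok[active]]
  structure(out, lambda = sel_lambda)
}

# Deterministic, permutation-invariant fold assignment: folds follow the
# sorted order of sample ids, so reordering rows relabels positions but
# leaves every fold's sample content unchanged.
fold_assignment <- function(ids, folds) {
  f <- integer(length(ids))
  f[order(ids)] <- rep_len(seq_len(folds), length(ids))
  f
}

# Single-predictor L1 path with k-fold CV: minimizes
# (1/2n)||y - x b||^2 + lambda |b|, whose solution is soft-thresholded
# least squares; mirrors the glmnet objective used for wider designs.
lasso_single_cv <- function(x, y, folds = 10, seed = 1,
                            rule = c("1se", "min"), foldid = NULL) {
  rule <- match.arg(rule)
  n <- length(y)
  soft_fit <- function(xi, yi, lam) {
    z <- sum(xi * yi) / length(yi)
    g <- sum(xi^2) / length(yi)
    sign(z) * max(abs(z) - lam, 0) / g
  }
  lam_max <- abs(sum(x * y)) / n
  if (lam_max == 0) return(list(beta = 0, lambda = 0))
  path <- exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = 100))
  path[1] <- lam_max  # exact, so the null model is exactly representable
  if (is.null(foldid)) {
    foldid <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  }
  err <- vapply(path, function(lam) {
    vapply(seq_len(folds), function(f) {
      tr <- foldid != f
      b <- soft_fit(x[tr], y[tr], lam)
      mean((y[!tr] - x[!tr] * b)^2)
    }, numeric(1))
  }, numeric(folds))
  cvm <- colMeans(err)
  cvsd <- apply(err, 2, sd) / sqrt(folds)
  i_min <- which.min(cvm)
  i <- if (rule == "1se") {
    which(cvm <= cvm[i_min] + cvsd[i_min])[1]  # path is decreasing in lambda
  } else i_min
  lam <- path[i]
  list(beta = soft_fit(x, y, lam), lambda = lam)
}

resolve_config <- function(config, n) {
  config$isis_target_size <- config$isis_target_size %||%
    max(2L, floor(n / log(n)))
  config
}

#' Stage 1: predict every gene's expression from genome-wide instruments
#'
#' Pools the selected instrument columns of all genes, and for each gene
#' screens the pool by iterative sure independence screening, then fits
#' ridge regression with GCV-selected penalty to produce the genetically
#' predicted expression used as stage-2 regressors. Genes are processed
#' independently, so results do not depend on processing order or worker
#' count.
#'
#' @param dataset a [regulatory_dataset()].
#' @param ivmap an [discover_ivs()] instrument map.
#' @param config a [twostage_config()].
#' @return Object of class `stage1_fit` with `predicted` (n x p),
#'   `residuals`, per-gene `lambda`, `screened` indices and the pool.
#' @export
stage1_predict <- function(dataset, ivmap, config = twostage_config()) {
  pool <- iv_pool(ivmap)
  abort_if(is.null(pool$matrix), "empty instrument pool")
  Y <- dataset$expression_net
  n <- nrow(Y); p <- ncol(Y)
  config <- resolve_config(config, n)
  fit_one <- function(j) {
    cols <- seq_len(ncol(pool$matrix))
    if (config$exclude_own_ivs) cols <- cols[pool$owner != j]
    if (length(cols) == 0) {
      return(list(pred = rep(mean(Y[, j]), n), lambda = NA_real_,
                  screened = integer(0)))
    }
    keep <- isis_screen(Y[, j], pool$matrix[, cols, drop = FALSE],
                        target_size = config$isis_target_size,
                        batch_size = config$isis_batch)
    if (length(keep) == 0) {
      return(list(pred = rep(mean(Y[, j]), n), lambda = NA_real_,
                  screened = integer(0)))
    }
    rf <- ridge_gcv(Y[, j], pool$matrix[, cols[keep], drop = FALSE],
                    lambda_grid = config$ridge_grid)
    list(pred = rf$fitted, lambda = rf$lambda, screened = cols[keep])
  }
  fits <- run_parallel(seq_len(p), fit_one, config$workers)
  pred <- vapply(fits, `[[`, numeric(n), "pred")
  colnames(pred) <- colnames(Y)
  structure(list(predicted = pred, residuals = Y - pred,
                 lambda = vapply(fits, `[[`, numeric(1), "lambda"),
                 screened = lapply(fits, `[[`, "screened"),
                 pool_owner = pool$owner),
            class = "stage1_fit")
}

# Order-preserving parallel map; deterministic regardless of worker count.
run_parallel <- function(ids, fn, workers = 1) {
  if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(ids, fn, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(ids, fn)
  }
}

#' Stage 2: identify the regulators of one gene
#'
#' Projects the gene's expression and the predicted expression of candidate
#' regulators onto the orthocomplement of the gene's own instrument columns
#' (removing its cis-genetic component), then selects regulators by adaptive
#' LASSO. Candidates are all other genes, restricted to genes holding at
#' least one instrument when `config$require_iv` is `TRUE`.
#'
#' @param k target gene index.
#' @param dataset a [regulatory_dataset()].
#' @param stage1 a [stage1_predict()] fit.
#' @param ivmap the instrument map.
#' @param config a [twostage_config()].
#' @return Object of class `stage2_fit`: `gene`, `gamma` (length-p effect
#'   vector, structural zero at `k`), `candidates`, `lambda`.
#' @export
fit_gene <- function(k, dataset, stage1, ivmap,
                     config = twostage_config()) {
  Y <- dataset$expression_net
  p <- ncol(Y)
  config <- resolve_config(config, nrow(Y))
  has_iv <- vapply(seq_len(p), function(j) !is.null(iv_columns(ivmap, j)),
                   logical(1))
  cand <- setdiff(if (config$require_iv) which(has_iv) else seq_len(p), k)
  gamma <- numeric(p)
  lam <- NA_real_
  if (length(cand) > 0) {
    own <- iv_columns(ivmap, k)
    # intercept-augmented span: annihilates the gene's instrument columns
    # and the constant direction, so centered data stay centered
    H <- make_projection(if (is.null(own)) NULL else
      cbind(intercept = 1, own))
    resp <- as.numeric(project_residual(H, Y[, k]))
    des <- project_residual(H, stage1$predicted[, cand, drop = FALSE])
    beta <- adaptive_lasso(resp, des, folds = config$lasso_folds,
                           seed = derive_seed(config$seed, k),
                           lambda = config$lasso_lambda,
                           rule = config$lasso_rule %||% "1se",
                           foldid = fold_assignment(dataset$sample_ids,
                                                    config$lasso_folds))
    gamma[cand] <- beta
    lam <- attr(beta, "lambda")
  }
  structure(list(gene = k, gamma = gamma, candidates = cand, lambda = lam),
            class = "stage2_fit")
}

#' Fit the full regulatory network by two-stage penalized least squares
#'
#' Runs stage 1 once, then the stage-2 regulator selection for every gene,
#' and assembles the sparse coefficient matrix `C` with `C[i, j]` the
#' estimated effect of gene `j` on gene `i` (rows index targets). The result
#' is invariant to gene processing order and worker count.
#'
#' @param dataset a [regulatory_dataset()].
#' @param ivmap an instrument map from [discover_ivs()].
#' @param config a [twostage_config()].
#' @return Object of class `grn_fit` with the sparse `coefficients` matrix,
#'   the stage-1 fit, and the resolved config.
#' @export
fit_network <- function(dataset, ivmap, config = twostage_config()) {
  p <- ncol(dataset$expression_net)
  config <- resolve_config(config, nrow(dataset$expression_net))
  stage1 <- stage1_predict(dataset, ivmap, config)
  fits <- run_parallel(seq_len(p), function(k) {
    fit_gene(k, dataset, stage1, ivmap, config)
  }, config$workers)
  G <- vapply(fits, `[[`, numeric(p), "gamma")  # column k = regulators of k
  C <- Matrix::Matrix(t(G), sparse = TRUE)      # row i = regulators of i
  dimnames(C) <- list(colnames(dataset$expression_net),
                      colnames(dataset$expression_net))
  structure(list(coefficients = C, stage1 = stage1, config = config,
                 genes = colnames(dataset$expression_net) %||%
                   paste0("g", seq_len(p))),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf("<grn_fit> %d genes, %d regulations\n",
              nrow(x$coefficients), sum(x$coefficients != 0)))
  invisible(x)
}

#' Edge list of a fitted network
#'
#' @param x a `grn_fit`.
#' @param ... unused.
#' @return Tibble with `target`, `regulator`, `effect` (nonzero entries of
#'   the coefficient matrix; `C[i, j]` is the effect of `j` on `i`).
#' @method tidy grn_fit
#' @export
tidy.grn_fit <- function(x, ...) {
  s <- Matrix::summary(x$coefficients)
  g <- x$genes
  tibble::tibble(target = g[s$i], regulator = g[s$j], effect = s$x) |>
    dplyr::filter(.data$effect != 0) |>
    dplyr::arrange(.data$target, .data$regulator)
}

#' One-row summary of a fitted network
#'
#' @param x a `grn_fit`.
#' @param ... unused.
#' @return Tibble with gene count, edge count and density.
#' @method glance grn_fit
#' @export
glance.grn_fit <- function(x, ...) {
  p <- nrow(x$coefficients)
  ne <- sum(x$coefficients != 0)
  tibble::tibble(n_genes = p, n_edges = ne,
                 density = ne / (p * (p - 1)))
}
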