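test_that("screening ranks a perfectly correlated column first", {
  set.seed(30)
  pool <- matrix(rnorm(100 * 8), 100, 8)
  target <- pool[, 5]
  keep <- isis_screen(target, pool, target_size = 3, batch_size = 1)
  expect_equal(keep[1], 5L)
  # small pool: everything returned
  expect_equal(isis_screen(target, pool[, 1:4], target_size = 10), 1:4)
})

test_that("iterative screening recovers a marginally masked predictor", {
  # classic construction: x2 = -0.5 x1 + u with var(u) = 0.25, so
  # cov(y, x2) = cov(x1 + x2, x2) = -0.5 + 0.5 = 0: x2 is marginally
  # invisible yet jointly essential
  set.seed(31)
  n <- 1000
  x1 <- rnorm(n)
  x2 <- -0.5 * x1 + rnorm(n, sd = 0.5)
  y <- x1 + x2 + rnorm(n, sd = 0.1)
  noise <- matrix(rnorm(n * 30), n, 30)
  pool <- cbind(x1, x2, noise)
  expect_lt(abs(cor(y, x2)), 0.1)
  one_pass <- order(abs(cor(pool, y)), decreasing = TRUE)[1:2]
  expect_false(2 %in% one_pass)     # plain SIS misses x2
  keep <- isis_screen(y, pool, target_size = 2, batch_size = 1)
  expect_true(all(c(1, 2) %in% keep))
})

test_that("ridge with GCV matches OLS at zero penalty and shrinks to the mean", {
  set.seed(32)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- X %*% c(1, -1, 0.5, 0, 2) + rnorm(60, sd = 0.2)
  r0 <- ridge_gcv(y, X, lambda_grid = 1e-12)
  ols <- lm(y ~ X)
  expect_equal(r0$coefficients, unname(coef(ols)[-1]), tolerance = 1e-6)
  rb <- ridge_gcv(y, X, lambda_grid = 1e12)
  expect_lt(max(abs(rb$coefficients)), 1e-6)
  expect_equal(rb$fitted, rep(mean(y), 60), tolerance = 1e-4)
})

test_that("GCV curve matches an independent dense-solve evaluation", {
  set.seed(33)
  X <- matrix(rnorm(50 * 10), 50, 10)
  y <- rnorm(50)
  r <- ridge_gcv(y, X)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  for (i in c(1, 10, 25, 50)) {
    l <- r$gcv$lambda[i]
    S <- Xc %*% solve(crossprod(Xc) + l * diag(10)) %*% t(Xc)
    rss <- sum((yc - S %*% yc)^2)
    expect_equal(r$gcv$gcv[i], 50 * rss / (50 - sum(diag(S)))^2,
                 tolerance = 1e-8)
  }
  # chosen lambda is the grid minimizer
  expect_equal(r$lambda, r$gcv$lambda[which.min(r$gcv$gcv)])
})

test_that("GCV minimizer agrees with the reference ridge implementation", {
  set.seed(34)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- X %*% rnorm(6) + rnorm(80)
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 40))
  mine <- ridge_gcv(y, X, lambda_grid = grid)
  # MASS scales predictors by sd with divisor n; feed pre-scaled columns so
  # the two parameterizations coincide
  n <- 80
  Xs <- scale(X, scale = apply(X, 2, function(c) {
    sqrt(sum((c - mean(c))^2) / n)
  }))
  ms <- MASS::lm.ridge(y ~ Xs, lambda = grid)
  mine_s <- ridge_gcv(y, Xs, lambda_grid = grid)
  expect_equal(order(mine_s$gcv$gcv)[1], unname(which.min(ms$GCV)))
})

test_that("projection operators satisfy their algebraic contracts", {
  set.seed(35)
  X <- matrix(rbinom(200 * 3, 2, 0.3), 200, 3)
  H <- make_projection(X)
  # annihilation of every instrument column
  expect_lt(max(abs(project_residual(H, X))), 1e-8)
  v <- rnorm(200)
  hv <- project_residual(H, v)
  # idempotence
  expect_lt(max(abs(project_residual(H, hv) - hv)), 1e-8)
  # symmetry via the inner-product identity <Hu, v> = <u, Hv>
  u <- rnorm(200)
  expect_lt(abs(sum(project_residual(H, u) * v) -
                  sum(u * project_residual(H, v))), 1e-8)
  # empty instrument set: identity
  H0 <- make_projection(NULL)
  expect_identical(project_residual(H0, v), v)
  # collinear columns are pruned with a warning
  expect_warning(H2 <- make_projection(cbind(X, X[, 1])), "collinear")
  expect_lt(max(abs(project_residual(H2, X))), 1e-8)
})

test_that("adaptive LASSO recovers a planted sparse support", {
  hits <- vapply(1:40, function(s) {
    set.seed(s + 500)
    n <- 300
    X <- matrix(rnorm(n * 50), n, 50)
    y <- X[, 3] + X[, 17] + rnorm(n, sd = 0.5)
    b <- adaptive_lasso(y, X, seed = s)
    identical(which(b != 0), c(3L, 17L))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("adaptive LASSO stays near-empty on pure noise", {
  fp <- vapply(1:30, function(s) {
    set.seed(s + 600)
    X <- matrix(rnorm(200 * 40), 200, 40)
    sum(adaptive_lasso(rnorm(200), X, seed = s) != 0)
  }, numeric(1))
  expect_lte(median(fp), 1)
})

test_that("orthonormal-design solution equals weighted soft-thresholding", {
  set.seed(36)
  n <- 64
  # orthogonal mean-zero columns with X'X = n I: the weighted-L1 solution
  # has a closed form, soft-thresholding the per-column least squares fit
  M <- scale(matrix(rnorm(n * 5), n), scale = FALSE)
  Q <- qr.Q(qr(M))
  X <- Q * sqrt(n)
  y <- as.numeric(X %*% c(2, -1.5, 1, 0, 0) + rnorm(n, sd = 0.3))
  yc <- y - mean(y)
  lam <- 0.05
  out <- adaptive_lasso(y, X, lambda = lam)
  # reproduce the internal standardization (divisor n - 1) and weights
  sds <- apply(X, 2, sd)
  Xs <- scale(X)
  init <- ridge_gcv(yc, Xs)$coefficients
  w <- 1 / abs(init)
  wbar <- w / mean(w)              # glmnet rescales factors to mean one
  z <- as.numeric(crossprod(Xs, yc)) / n
  beta_std <- sign(z) * pmax(abs(z) - lam * wbar, 0) * n / (n - 1)
  expect_equal(unname(as.numeric(out)), beta_std / sds, tolerance = 1e-4)
})

test_that("stage-1 predictions hit the oracle R2 when regulation is absent", {
  # gamma = 0: expression = X psi + eps, so the genetic component is fully
  # predictable and oracle R2 = var(X psi) / var(Y)
  p <- 8
  truth <- simulate_network(p = p, n_edges = 0, ivs_per_gene = 3,
                            cis_range = c(0.7, 1.2), seed = 40)
  truth$gamma[] <- 0
  d <- simulate_dataset(n = 400, truth = truth, maf = 0.3, seed = 41)
  ds <- preprocess_data(d, n_pcs = 0)
  iv <- discover_ivs(ds, n_perm = 100, seed = 1)
  st1 <- stage1_predict(ds, iv, twostage_config(seed = 1))
  gen <- d$genotypes %*% truth$psi
  for (j in seq_len(p)) {
    oracle_r2 <- var(gen[, j]) / var(d$expression[, j])
    pred_r2 <- cor(st1$predicted[, j], ds$expression_net[, j])^2
    expect_gte(pred_r2, oracle_r2 - 0.1)
  }
})

test_that("two-stage estimate matches classical 2SLS with a single candidate", {
  for (s in 1:20) {
    truth <- two_gene_truth()
    d <- simulate_dataset(n = 400, truth = truth, seed = s + 700)
    ds <- preprocess_data(d, n_pcs = 0)
    iv <- discover_ivs(ds, n_perm = 50, seed = s)
    skip_unless <- vapply(1:2, function(k) {
      !is.null(grniv:::iv_columns(iv, k))
    }, logical(1))
    expect_true(all(skip_unless))
    cfg <- twostage_config(ridge_grid = 1e-10, lasso_lambda = 0, seed = s)
    st1 <- stage1_predict(ds, iv, cfg)
    f2 <- fit_gene(2, ds, st1, iv, cfg)
    # closed-form 2SLS with the same projections, via lm()
    x1 <- grniv:::iv_columns(iv, 1); x2 <- grniv:::iv_columns(iv, 2)
    yhat1 <- fitted(lm(ds$expression_net[, 1] ~ x1 + x2))
    h <- function(v) residuals(lm(v ~ x2))
    slope <- coef(lm(h(ds$expression_net[, 2]) ~ h(yhat1)))[[2]]
    expect_equal(f2$gamma[1], slope, tolerance = 1e-6)
  }
})

test_that("a gene never appears among its own regulators", {
  fx <- benchmark_dataset(8, n = 200)
  iv <- discover_ivs(fx$dataset, n_perm = 50, seed = 1)
  st1 <- stage1_predict(fx$dataset, iv, twostage_config(seed = 1))
  f <- fit_gene(4, fx$dataset, st1, iv, twostage_config(seed = 1))
  expect_equal(f$gamma[4], 0)
  expect_false(4 %in% f$candidates)
})

test_that("network fit is invariant to sample order and worker count", {
  fx <- benchmark_dataset(9, n = 200)
  iv <- discover_ivs(fx$dataset, n_perm = 50, seed = 2)
  fit1 <- fit_network(fx$dataset, iv, twostage_config(seed = 3))
  # scrambling rows of all aligned matrices together
  set.seed(44)
  idx <- sample.int(200)
  ds2 <- grniv:::resample_dataset(fx$dataset, idx)
  iv2 <- grniv:::resample_ivmap(iv, idx)
  fit2 <- fit_network(ds2, iv2, twostage_config(seed = 3))
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
  # worker-count invariance
  fit4 <- fit_network(fx$dataset, iv, twostage_config(seed = 3, workers = 4))
  expect_identical(fit1$coefficients, fit4$coefficients)
})

test_that("null networks stay almost empty", {
  truth <- simulate_network(p = 30, n_edges = 0, ivs_per_gene = 3, seed = 50)
  truth$gamma[] <- 0
  d <- simulate_dataset(n = 500, truth = truth, maf = 0.3, seed = 51)
  ds <- preprocess_data(d)
  iv <- discover_ivs(ds, n_perm = 50, seed = 1)
  fit <- fit_network(ds, iv, twostage_config(seed = 1))
  spurious <- sum(fit$coefficients != 0) / (30 * 29)
  expect_lte(spurious, 0.005)
})

test_that("support recovery improves with sample size", {
  f1 <- vapply(1:3, function(s) {
    truth <- simulate_network(p = 6, n_edges = 5, seed = s)
    f <- function(n) {
      d <- simulate_dataset(n = n, truth = truth, seed = s + 10)
      ds <- preprocess_data(d, n_pcs = 0)
      iv <- discover_ivs(ds, n_perm = 50, seed = s)
      edge_metrics(fit_network(ds, iv, twostage_config(seed = s)), truth)$f1
    }
    c(f(200), f(2000))
  }, numeric(2))
  expect_gte(median(f1[2, ]), median(f1[1, ]))
})
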