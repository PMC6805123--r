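test_that("design matrix appends intercept and squared columns", {
  Z <- matrix(c(-1.2247, 0, 1.2247, 0.5, -0.5, 0), 3, 2,
              dimnames = list(NULL, c("z", "w")))
  d <- build_design_matrix(Z, quadratic = "z")
  expect_equal(colnames(d$X), c("(Intercept)", "z", "w", "z_sq"))
  expect_equal(d$X[, "z_sq"], Z[, "z"]^2)
  expect_equal(d$X[, "z_sq"], c(1.5, 0, 1.5), tolerance = 1e-4)
  expect_equal(ncol(build_design_matrix(Z)$X), 3)  # no quadratics: P = ncov + 1
  expect_error(build_design_matrix(Z, quadratic = "missing"), "missing covariate")
})

test_that("lattice adjacency and ICAR precision are rook-correct", {
  a <- build_adjacency(2, 2)
  expect_equal(unname(a$degree), rep(2, 4))
  expect_equal(sum(a$A) / 2, 4)  # 4 undirected edges
  expect_equal(max(abs(rowSums(a$Q))), 0)
  a2 <- build_adjacency(3, 1)
  expect_equal(unname(a2$degree), c(1, 2, 1))
  a3 <- build_adjacency(7, 5)
  expect_true(isSymmetric(a3$A))
  expect_equal(max(abs(diag(a3$A))), 0)
  expect_equal(max(abs(rowSums(a3$Q))), 0)
  q8 <- build_adjacency(3, 3, rule = "queen")
  expect_equal(unname(q8$degree[5]), 8)  # centre cell
  expect_error(build_adjacency(1, 1), "degenerate")
})

test_that("RSR basis is orthonormal, de-confounded and matches a dense eigen oracle", {
  fx <- make_toy_model(nx = 3, ny = 3, n_sites = 5, q = 2, seed = 3)
  a <- build_adjacency(3, 3)
  X <- matrix(1, 9, 1)  # intercept-only
  b <- build_rsr_basis(X, a$A, a$Q, q = 2)
  expect_equal(crossprod(b$K), diag(2), tolerance = 1e-8)
  expect_lt(max(abs(colSums(b$K))), 1e-8)  # orthogonal to the constant vector
  # dense oracle: eigendecompose Pperp A Pperp directly
  Pp <- diag(9) - X %*% solve(crossprod(X), t(X))
  es <- eigen((Pp %*% a$A %*% Pp + t(Pp %*% a$A %*% Pp)) / 2, symmetric = TRUE)
  for (k in 1:2) {
    dot <- abs(sum(b$K[, k] * es$vectors[, k]))
    expect_equal(dot, 1, tolerance = 1e-8)  # match up to sign
  }
  expect_equal(b$values, es$values[1:2], tolerance = 1e-10)
  # with covariates: K'X vanishes
  b2 <- fx$basis
  expect_lt(max(abs(crossprod(b2$K, fx$lat$X_lambda))), 1e-8)
  # KQK symmetric positive definite
  ev <- eigen(b2$KQK, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_error(build_rsr_basis(X, a$A, a$Q, q = 100), "exceeds")
})

test_that("NegBin log pmf matches its closed forms and the Poisson limit", {
  # normalization
  expect_equal(sum(exp(negbin_logpmf(0:1000, 3, 2))), 1, tolerance = 1e-10)
  # phi = 1 is geometric with p = phi/(phi+lam) = 1/4
  expect_equal(exp(negbin_logpmf(2, 3, 1)), 0.25 * 0.75^2)
  expect_equal(exp(negbin_logpmf(2, 3, 1)), 0.140625)
  # Poisson limit
  expect_equal(exp(negbin_logpmf(0:20, 3, 1e8)), dpois(0:20, 3), tolerance = 1e-6)
  # agreement with the stats parameterization everywhere
  expect_equal(negbin_logpmf(0:50, 2.7, 0.8),
               dnbinom(0:50, size = 0.8, mu = 2.7, log = TRUE), tolerance = 1e-12)
  expect_error(negbin_logpmf(2, -1, 1), "positive")
})

test_that("integrated cell likelihood equals naive enumeration and its closed form", {
  # geometric-series closed form: y = 0, gd = 1, lam = 1, phi = 1
  # sum_N (1/2)^{N+1} e^{-N} = 0.5 / (1 - e^{-1}/2)
  closed <- log(0.5 / (1 - exp(-1) / 2))
  expect_equal(cell_integrated_loglik(0, 1, 1, 1, Nmax = 500), closed,
               tolerance = 1e-6)
  expect_equal(exp(closed), 0.612700, tolerance = 1e-6)
  # empty cell contributes zero
  expect_equal(cell_integrated_loglik(numeric(0), numeric(0), 2, 1), 0)
  # brute-force oracle on 200 random toy cells
  set.seed(17)
  for (r in 1:200) {
    n <- sample(0:4, 1)
    y <- if (n > 0) rpois(n, 4) else numeric(0)
    gd <- if (n > 0) runif(n, 0.3, 25) else numeric(0)
    lam <- runif(1, 0.1, 9)
    phi <- runif(1, 0.2, 6)
    expect_equal(cell_integrated_loglik(y, gd, lam, phi),
                 naive_cell_loglik(y, gd, lam, phi), tolerance = 1e-10)
  }
  expect_error(cell_integrated_loglik(-1, 1, 1, 1), "negative")
})

test_that("truncation beyond the NegBin tail does not move the likelihood", {
  set.seed(31)
  y <- c(3, 1); gd <- c(2, 4); lam <- 2.5; phi <- 1.5
  qhi <- qnbinom(1 - 1e-12, size = phi, mu = lam)
  l1 <- cell_integrated_loglik(y, gd, lam, phi, Nmax = qhi)
  l2 <- cell_integrated_loglik(y, gd, lam, phi, Nmax = qhi + 200)
  expect_lt(abs(l2 - l1), 1e-8)
})

test_that("log posterior decomposes into likelihood plus priors and guards its support", {
  fx <- make_toy_model(nx = 5, ny = 4, n_sites = 12, q = 3, seed = 5)
  mod <- fx$model
  st <- herbiscaper:::state_template(mod)
  st$beta_lambda <- c(0.2, 0.4, -0.1)
  st$beta_gamma <- c(-1, 0.2)
  st$delta <- c(0.1, -0.2, 0.05)
  st$eps <- rnorm(mod$S, 0, 0.1)
  st$phi <- 1.5; st$sigma <- 0.4; st$tau <- 2

  # out-of-support states give -Inf, not an error
  bad <- st; bad$sigma <- 100
  expect_identical(total_log_posterior(bad, mod), -Inf)
  bad$sigma <- -1
  expect_identical(total_log_posterior(bad, mod), -Inf)
  bad <- st; bad$phi <- 0
  expect_identical(total_log_posterior(bad, mod), -Inf)

  # independent re-implementation, terms summed in a different order
  pr <- mod$priors
  loglam <- drop(mod$X_lambda %*% st$beta_lambda) + drop(mod$basis$K %*% st$delta)
  gam <- exp(drop(mod$X_gamma %*% st$beta_gamma) + st$eps)
  cells <- sort(unique(mod$site_cell))
  ll <- 0
  for (j in rev(cells)) {  # reversed cell order
    idx <- which(mod$site_cell == j)
    ll <- ll + naive_cell_loglik(mod$y[idx], gam[idx] * mod$effort[idx],
                                 exp(loglam[j]), st$phi, mod$Nmax)
  }
  prior <- dgamma(st$phi, pr$phi_shape, rate = pr$phi_rate, log = TRUE) +
    dgamma(st$tau, pr$tau_shape, rate = pr$tau_rate, log = TRUE) +
    dunif(st$sigma, 0, pr$sigma_max, log = TRUE) +
    sum(dnorm(rev(st$eps), 0, st$sigma, log = TRUE)) +
    sum(dnorm(rev(c(st$beta_lambda, st$beta_gamma)), 0,
              1 / sqrt(pr$beta_prec), log = TRUE)) +
    mod$q / 2 * log(st$tau) -
    st$tau / 2 * drop(crossprod(st$delta, mod$basis$KQK %*% st$delta))
  expect_equal(total_log_posterior(st, mod), ll + prior, tolerance = 1e-9)

  # no-data model: posterior equals the prior sum alone
  mod0 <- abundance_model(numeric(0), numeric(0), integer(0),
                          mod$X_lambda, mod$X_gamma[0, , drop = FALSE],
                          fx$basis)
  st0 <- st; st0$eps <- numeric(0)
  expect_equal(total_log_posterior(st0, mod0),
               prior - sum(dnorm(st$eps, 0, st$sigma, log = TRUE)),
               tolerance = 1e-9)
})
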