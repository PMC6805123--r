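#' Build a design matrix with intercept and quadratic terms
#'
#' Prepends an intercept and appends element-wise squared columns for the
#' requested covariates. Covariates are expected standardized, so squared
#' columns are squares of standardized parents (allowing an interior optimum
#' on the log link).
#'
#' @param covariates matrix or data.frame of (standardized) covariates.
#' @param quadratic character vector of covariate names to square.
#' @return list with `X` (matrix, first column `(Intercept)`), `names`,
#'   `quadratic`.
#' @export
build_design_matrix <- function(covariates, quadratic = character(0)) {
  Z <- as.matrix(covariates)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("V", seq_len(ncol(Z)))
  missing <- setdiff(quadratic, colnames(Z))
  if (length(missing))
    stop("quadratic requested for missing covariate: ", paste(missing, collapse = ", "))
  X <- cbind(`(Intercept)` = rep(1, nrow(Z)), Z)
  for (nm in quadratic) {
    q <- Z[, nm]^2
    X <- cbind(X, q)
    colnames(X)[ncol(X)] <- paste0(nm, "_sq")
  }
  list(X = X, names = colnames(X), quadratic = quadratic)
}

#' Lattice adjacency and ICAR precision
#'
#' Builds the rook (4-neighbour) or queen (8-neighbour) adjacency matrix of an
#' `nx x ny` regular grid in column-major cell order, and the intrinsic CAR
#' precision `Q = diag(degree) - A`.
#'
#' @param nx,ny grid dimensions (at least 2 cells in total).
#' @param rule `"rook"` (default) or `"queen"`.
#' @return list with dense matrices `A`, `Q` and the `degree` vector.
#' @export
build_adjacency <- function(nx, ny, rule = c("rook", "queen")) {
  rule <- match.arg(rule)
  G <- nx * ny
  if (G < 2) stop("degenerate grid: need at least 2 cells")
  ix <- (seq_len(G) - 1L) %% nx
  iy <- (seq_len(G) - 1L) %/% nx
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (rule == "queen") offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    jx <- ix + o[1]; jy <- iy + o[2]
    ok <- jx >= 0 & jx < nx & jy >= 0 & jy < ny
    from <- c(from, which(ok))
    to <- c(to, (jx + jy * nx + 1L)[ok])
  }
  A <- matrix(0, G, G)
  A[cbind(from, to)] <- 1
  A[cbind(to, from)] <- 1
  deg <- rowSums(A)
  list(A = A, Q = diag(deg) - A, degree = deg)
}

#' Restricted spatial regression (Moran) basis
#'
#' Constructs the reduced-rank spatial basis orthogonal to the fixed-effect
#' design: with `Pperp = I - X (X'X)^-1 X'`, the Moran operator is
#' `Pperp A Pperp`; the basis `K` collects its top `q` eigenvectors (positive
#' eigenvalues), which carry smooth spatial patterns de-confounded from the
#' covariates. The prior precision kernel of the basis coefficients is
#' `K' Q K`.
#'
#' @param X_lambda landscape design matrix (`G x P`, full column rank).
#' @param A adjacency matrix.
#' @param Q ICAR precision `diag(degree) - A`.
#' @param q number of eigenvectors; default `min(ceiling(0.1 * G), #positive)`.
#' @return an `rsr_basis`: list `K` (`G x q`, orthonormal), `values`
#'   (eigenvalues), `KQK` (`q x q` SPD kernel), `q`.
#' @export
build_rsr_basis <- function(X_lambda, A, Q, q = NULL) {
  X <- as.matrix(X_lambda)
  G <- nrow(X)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) stop("X'X is singular; drop collinear columns")
  Pp <- diag(G) - X %*% solve(XtX, t(X))
  M <- Pp %*% A %*% Pp
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  npos <- sum(es$values > 1e-8)
  if (is.null(q)) q <- min(ceiling(0.1 * G), npos)
  if (q < 1 || q > npos)
    stop("q = ", q, " exceeds the ", npos, " positive Moran eigenvalues")
  K <- es$vectors[, seq_len(q), drop = FALSE]
  KQK <- crossprod(K, Q %*% K)
  KQK <- (KQK + t(KQK)) / 2
  structure(list(K = K, values = es$values[seq_len(q)], KQK = KQK, q = q),
            class = "rsr_basis")
}

#' Negative-Binomial log pmf (mean/dispersion parameterization)
#'
#' `P(N) = Gamma(N + phi) / (Gamma(phi) N!) * (phi/(phi+lam))^phi *
#' (lam/(phi+lam))^N`, i.e. mean `lam` and variance `lam + lam^2/phi`.
#'
#' @param N non-negative integer(s).
#' @param lam mean, `> 0`.
#' @param phi dispersion, `> 0`.
#' @return log probabilities.
#' @export
negbin_logpmf <- function(N, lam, phi) {
  if (any(N != floor(N))) stop("N must be integer")
  negbin_logpmf_cpp(as.integer(N), lam, phi)
}

#' Integrated likelihood of one grid cell
#'
#' Sums the latent abundance out of the cell's joint likelihood:
#' `log sum_{N=0}^{Nmax} NegBin(N | lam, phi) prod_i Poisson(y_i | N g_i)`,
#' where `g_i = gamma_i * d_i` is the site's trapping rate times effort. The
#' sum is computed in log space (log-sum-exp); a cell without cameras
#' contributes 0.
#'
#' @param y site counts in the cell (may be empty).
#' @param gd per-site `gamma_i * d_i`, same length as `y`.
#' @param lam,phi Negative-Binomial mean and dispersion of the cell abundance.
#' @param Nmax truncation of the latent-abundance sum (default 100, the
#'   assumed maximum number of individuals using one cell).
#' @return scalar log likelihood.
#' @export
cell_integrated_loglik <- function(y, gd, lam, phi, Nmax = 100L) {
  if (length(y) != length(gd)) stop("y and gd must have equal length")
  if (length(y) == 0) return(0)
  if (any(y < 0)) stop("negative counts")
  nmix_loglik_cpp(log(lam), phi, as.integer(Nmax), as.numeric(y),
                  as.numeric(gd), rep(0L, length(y)))
}

#' Prior configuration for the hierarchical abundance model
#'
#' Defaults: diffuse `N(0, precision 1e-3)` on all regression coefficients,
#' `sigma ~ U(0, 100)` on the site-error SD, `Gamma(0.1, 0.1)` on the RSR
#' precision `tau` and on the Negative-Binomial dispersion `phi`.
#'
#' @param beta_prec normal prior precision for regression coefficients.
#' @param sigma_max upper bound of the uniform prior on `sigma`.
#' @param tau_shape,tau_rate gamma prior on `tau`.
#' @param phi_shape,phi_rate gamma prior on `phi`.
#' @return list of prior hyper-parameters.
#' @export
model_priors <- function(beta_prec = 1e-3, sigma_max = 100,
                         tau_shape = 0.1, tau_rate = 0.1,
                         phi_shape = 0.1, phi_rate = 0.1) {
  stopifnot(beta_prec > 0, sigma_max > 0, tau_shape > 0, tau_rate > 0,
            phi_shape > 0, phi_rate > 0)
  list(beta_prec = beta_prec, sigma_max = sigma_max, tau_shape = tau_shape,
       tau_rate = tau_rate, phi_shape = phi_shape, phi_rate = phi_rate)
}

#' Assemble the hierarchical abundance model
#'
#' Bundles data, design matrices, spatial basis and priors into the model
#' object consumed by [run_mcmc()], [total_log_posterior()] and the prediction
#' tools.
#'
#' @param y site counts.
#' @param effort effort days per site (`>= 1`).
#' @param site_cell 1-based grid-cell index per site.
#' @param X_lambda landscape design (`G x P`, intercept first).
#' @param X_gamma site design (`S x Qd`, intercept first).
#' @param basis an [build_rsr_basis()] result, or `NULL` for a non-spatial fit.
#' @param priors a [model_priors()] list.
#' @param Nmax latent-abundance truncation.
#' @return an `abundance_model` list.
#' @export
abundance_model <- function(y, effort, site_cell, X_lambda, X_gamma,
                            basis = NULL, priors = model_priors(), Nmax = 100L) {
  S <- length(y)
  G <- nrow(X_lambda)
  stopifnot(length(effort) == S, length(site_cell) == S, nrow(X_gamma) == S)
  if (any(effort <= 0)) stop("negative or zero effort")
  if (any(site_cell < 1 | site_cell > G)) stop("site references missing cell")
  if (any(y < 0)) stop("negative counts")
  q <- if (is.null(basis)) 0L else basis$q
  # CSR layout of sites grouped by cell (for single-cell updates)
  ord <- order(site_cell)
  counts <- tabulate(site_cell, nbins = G)
  cell_ptr <- c(0L, cumsum(counts))
  structure(list(y = as.numeric(y), effort = as.numeric(effort),
                 site_cell = as.integer(site_cell),
                 X_lambda = as.matrix(X_lambda), X_gamma = as.matrix(X_gamma),
                 basis = basis, priors = priors, Nmax = as.integer(Nmax),
                 G = G, S = S, q = q,
                 ylg = lgamma(y + 1), logd = log(effort),
                 cell_ptr = cell_ptr, cell_site = as.integer(ord - 1L)),
            class = "abundance_model")
}

# parameter vector layout helpers -------------------------------------------

state_template <- function(model) {
  list(beta_lambda = numeric(ncol(model$X_lambda)),
       beta_gamma = numeric(ncol(model$X_gamma)),
       eps = numeric(model$S),
       delta = numeric(model$q),
       tau = 1, phi = 1, sigma = 1)
}

state_loglam <- function(state, model) {
  ll <- drop(model$X_lambda %*% state$beta_lambda)
  if (model$q > 0) ll <- ll + drop(model$basis$K %*% state$delta)
  ll
}

state_loggamma <- function(state, model) {
  drop(model$X_gamma %*% state$beta_gamma) + state$eps
}

#' Joint log posterior of the hierarchical abundance model
#'
#' The integrated likelihood summed over cells plus all log priors: diffuse
#' normals on the regression coefficients, `eps_i ~ N(0, sigma^2)` with
#' `sigma ~ U(0, sigma_max)`, `delta ~ N(0, (tau K'QK)^-1)` with
#' `tau ~ Gamma`, and a gamma prior on `phi`. States outside the support
#' return `-Inf` (so a sampler rejects them) rather than erroring.
#'
#' @param state list with `beta_lambda`, `beta_gamma`, `eps`, `delta`, `tau`,
#'   `phi`, `sigma`.
#' @param model an [abundance_model()].
#' @return scalar log posterior density (up to a constant).
#' @export
total_log_posterior <- function(state, model) {
  pr <- model$priors
  if (state$phi <= 0 || state$tau <= 0 ||
      state$sigma <= 0 || state$sigma >= pr$sigma_max) return(-Inf)
  loglam <- state_loglam(state, model)
  gd <- exp(state_loggamma(state, model)) * model$effort
  ll <- nmix_loglik_cpp(loglam, state$phi, model$Nmax, model$y, gd,
                        model$site_cell - 1L)
  bsd <- 1 / sqrt(pr$beta_prec)
  lp <- sum(dnorm(c(state$beta_lambda, state$beta_gamma), 0, bsd, log = TRUE)) +
    sum(dnorm(state$eps, 0, state$sigma, log = TRUE)) +
    dunif(state$sigma, 0, pr$sigma_max, log = TRUE) +
    dgamma(state$phi, pr$phi_shape, rate = pr$phi_rate, log = TRUE)
  if (model$q > 0) {
    M <- model$basis$KQK
    quad <- drop(crossprod(state$delta, M %*% state$delta))
    lp <- lp + model$q / 2 * log(state$tau) - state$tau / 2 * quad +
      dgamma(state$tau, pr$tau_shape, rate = pr$tau_rate, log = TRUE)
  }
  ll + lp
}
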