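#' Run MCMC
#'
#' Generic front-end. The method for [abundance_model()] runs the blocked
#' adaptive Metropolis-Hastings sampler on the integrated likelihood; the
#' method for plain functions runs component-wise adaptive random-walk
#' Metropolis on any log-density (used for sampler validation against known
#' targets).
#'
#' @param model an [abundance_model()], or a function `theta -> log density`.
#' @param ... passed to methods.
#' @return a `posterior_samples` object: per-chain draw matrices (post
#'   burn-in, thinned), acceptance rates, and run metadata.
#' @export
run_mcmc <- function(model, ...) UseMethod("run_mcmc")

# ---- adaptive proposal helpers --------------------------------------------

# Robbins-Monro step-size adaptation toward a target acceptance rate
rm_adapt <- function(log_s, accepted, it, target) {
  log_s + it^-0.6 * ((if (accepted) 1 else 0) - target)
}

new_block_adapter <- function(d, s0 = 0.1) {
  list(d = d, n = 0, mean = numeric(d), M2 = matrix(0, d, d),
       chol = diag(s0 / sqrt(d), d), log_mult = 0, warm = 250L,
       acc = 0L, tries = 0L)
}

block_update_stats <- function(ad, x) {
  ad$n <- ad$n + 1
  delta <- x - ad$mean
  ad$mean <- ad$mean + delta / ad$n
  ad$M2 <- ad$M2 + tcrossprod(delta, x - ad$mean)
  ad
}

block_refresh_chol <- function(ad) {
  if (ad$n > ad$warm) {
    C <- ad$M2 / (ad$n - 1)
    S <- 2.38^2 / ad$d * C + 1e-10 * diag(ad$d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (!is.null(ch)) ad$chol <- t(ch)
  }
  ad
}

block_propose <- function(ad, x) {
  x + exp(ad$log_mult) * drop(ad$chol %*% rnorm(ad$d))
}

check_finite <- function(lp, what) {
  if (is.nan(lp) || is.na(lp))
    stop("log posterior returned NaN during ", what,
         " update; check data and priors")
  lp
}

# ---- abundance-model sampler ----------------------------------------------

# initialization: Poisson GLM ignoring the latent layer, then small jitter
init_abn_state <- function(model, jitter_sd = 0.1) {
  st <- state_template(model)
  Xl <- model$X_lambda[model$site_cell, -1, drop = FALSE]
  Xg <- model$X_gamma[, -1, drop = FALSE]
  XX <- cbind(Xl, Xg)
  fit <- tryCatch(
    glm(model$y ~ XX + offset(model$logd), family = poisson()),
    error = function(e) NULL, warning = function(w) suppressWarnings(
      glm(model$y ~ XX + offset(model$logd), family = poisson())))
  if (!is.null(fit) && all(is.finite(coef(fit)))) {
    cf <- coef(fit)
    nl <- ncol(Xl)
    st$beta_lambda <- c(cf[1], if (nl) cf[1 + seq_len(nl)] else NULL)
    st$beta_gamma <- c(0, if (ncol(Xg)) cf[1 + nl + seq_len(ncol(Xg))] else NULL)
  }
  st$beta_lambda <- st$beta_lambda + rnorm(length(st$beta_lambda), 0, jitter_sd)
  st$beta_gamma <- st$beta_gamma + rnorm(length(st$beta_gamma), 0, jitter_sd)
  st
}

abn_param_names <- function(model) {
  c(paste0("beta_lambda[", colnames(model$X_lambda), "]"),
    paste0("beta_gamma[", colnames(model$X_gamma), "]"),
    if (model$q > 0) paste0("delta[", seq_len(model$q), "]"),
    paste0("eps[", seq_len(model$S), "]"),
    "phi", "sigma", "tau")
}

run_chain_abn <- function(model, n_iter, n_burn, thin, chain_seed) {
  set.seed(chain_seed)
  pr <- model$priors
  st <- init_abn_state(model)
  sc0 <- model$site_cell - 1L
  K <- if (model$q > 0) model$basis$K else NULL
  M <- if (model$q > 0) model$basis$KQK else NULL

  Xlb <- drop(model$X_lambda %*% st$beta_lambda)
  Komega <- if (model$q > 0) drop(K %*% st$delta) else 0
  loglam <- Xlb + Komega
  lin <- drop(model$X_gamma %*% st$beta_gamma)
  gd <- exp(lin + st$eps) * model$effort
  ll <- nmix_loglik_cpp(loglam, st$phi, model$Nmax, model$y, gd, sc0)
  check_finite(ll, "initial")

  ad_bl <- new_block_adapter(length(st$beta_lambda))
  ad_bg <- new_block_adapter(length(st$beta_gamma))
  ad_d <- if (model$q > 0) new_block_adapter(model$q, s0 = 0.5) else NULL
  s_eps <- rep(0.5, model$S)
  s_phi <- 0.5; s_sig <- 0.2; s_tau <- 1
  acc <- c(beta_lambda = 0, beta_gamma = 0, delta = 0, eps = 0,
           phi = 0, sigma = 0, tau = 0)

  nkeep <- (n_iter - n_burn) %/% thin
  draws <- matrix(NA_real_, nkeep, length(abn_param_names(model)))
  colnames(draws) <- abn_param_names(model)
  kept <- 0L
  bprec <- pr$beta_prec
  quad_d <- if (model$q > 0) drop(crossprod(st$delta, M %*% st$delta)) else 0

  for (it in seq_len(n_iter)) {
    adapting <- it <= n_burn
    target_b <- 0.25

    # beta_lambda block
    prop <- block_propose(ad_bl, st$beta_lambda)
    Xlb_p <- drop(model$X_lambda %*% prop)
    ll_p <- check_finite(nmix_loglik_cpp(Xlb_p + Komega, st$phi, model$Nmax,
                                         model$y, gd, sc0), "beta_lambda")
    lr <- ll_p - ll - bprec / 2 * (sum(prop^2) - sum(st$beta_lambda^2))
    a <- is.finite(lr) && log(runif(1)) < lr
    if (a) { st$beta_lambda <- prop; Xlb <- Xlb_p; loglam <- Xlb + Komega; ll <- ll_p }
    if (adapting) {
      ad_bl$log_mult <- rm_adapt(ad_bl$log_mult, a, it, target_b)
      ad_bl <- block_update_stats(ad_bl, st$beta_lambda)
      if (it %% 25 == 0) ad_bl <- block_refresh_chol(ad_bl)
    } else acc["beta_lambda"] <- acc["beta_lambda"] + a

    # delta block (spatial basis coefficients)
    if (model$q > 0) {
      prop <- block_propose(ad_d, st$delta)
      Ko_p <- drop(K %*% prop)
      ll_p <- check_finite(nmix_loglik_cpp(Xlb + Ko_p, st$phi, model$Nmax,
                                           model$y, gd, sc0), "delta")
      quad_p <- drop(crossprod(prop, M %*% prop))
      lr <- ll_p - ll - st$tau / 2 * (quad_p - quad_d)
      a <- is.finite(lr) && log(runif(1)) < lr
      if (a) { st$delta <- prop; Komega <- Ko_p; loglam <- Xlb + Komega
               ll <- ll_p; quad_d <- quad_p }
      if (adapting) {
        ad_d$log_mult <- rm_adapt(ad_d$log_mult, a, it, target_b)
        ad_d <- block_update_stats(ad_d, st$delta)
        if (it %% 25 == 0) ad_d <- block_refresh_chol(ad_d)
      } else acc["delta"] <- acc["delta"] + a
    }

    # beta_gamma block
    prop <- block_propose(ad_bg, st$beta_gamma)
    lin_p <- drop(model$X_gamma %*% prop)
    gd_p <- exp(lin_p + st$eps) * model$effort
    ll_p <- check_finite(nmix_loglik_cpp(loglam, st$phi, model$Nmax,
                                         model$y, gd_p, sc0), "beta_gamma")
    lr <- ll_p - ll - bprec / 2 * (sum(prop^2) - sum(st$beta_gamma^2))
    a <- is.finite(lr) && log(runif(1)) < lr
    if (a) { st$beta_gamma <- prop; lin <- lin_p; gd <- gd_p; ll <- ll_p }
    if (adapting) {
      ad_bg$log_mult <- rm_adapt(ad_bg$log_mult, a, it, target_b)
      ad_bg <- block_update_stats(ad_bg, st$beta_gamma)
      if (it %% 25 == 0) ad_bg <- block_refresh_chol(ad_bg)
    } else acc["beta_gamma"] <- acc["beta_gamma"] + a

    # site errors, component-wise sweep in compiled code
    sw <- eps_sweep_cpp(st$eps, s_eps, model$y, model$ylg, lin, model$logd,
                        sc0, model$cell_ptr, model$cell_site,
                        loglam, st$phi, st$sigma, model$Nmax)
    st$eps <- sw$eps
    if (adapting) s_eps <- s_eps * exp(it^-0.6 * (sw$accepted - 0.35))
    else acc["eps"] <- acc["eps"] + mean(sw$accepted)
    gd <- exp(lin + st$eps) * model$effort
    ll <- nmix_loglik_cpp(loglam, st$phi, model$Nmax, model$y, gd, sc0)

    # phi: random walk on log scale
    phi_p <- st$phi * exp(s_phi * rnorm(1))
    ll_p <- check_finite(nmix_loglik_cpp(loglam, phi_p, model$Nmax,
                                         model$y, gd, sc0), "phi")
    lr <- ll_p - ll +
      dgamma(phi_p, pr$phi_shape, rate = pr$phi_rate, log = TRUE) -
      dgamma(st$phi, pr$phi_shape, rate = pr$phi_rate, log = TRUE) +
      log(phi_p) - log(st$phi)
    a <- is.finite(lr) && log(runif(1)) < lr
    if (a) { st$phi <- phi_p; ll <- ll_p }
    if (adapting) s_phi <- s_phi * exp(it^-0.6 * (a - 0.35))
    else acc["phi"] <- acc["phi"] + a

    # sigma: random walk on (0, sigma_max); only the eps prior is involved
    sig_p <- st$sigma + s_sig * rnorm(1)
    if (sig_p > 0 && sig_p < pr$sigma_max) {
      lr <- sum(dnorm(st$eps, 0, sig_p, log = TRUE)) -
        sum(dnorm(st$eps, 0, st$sigma, log = TRUE))
      a <- is.finite(lr) && log(runif(1)) < lr
    } else a <- FALSE
    if (a) st$sigma <- sig_p
    if (adapting) s_sig <- s_sig * exp(it^-0.6 * (a - 0.35))
    else acc["sigma"] <- acc["sigma"] + a

    # tau: random walk on log scale; only the delta prior is involved
    if (model$q > 0) {
      tau_p <- st$tau * exp(s_tau * rnorm(1))
      lr <- model$q / 2 * (log(tau_p) - log(st$tau)) -
        (tau_p - st$tau) / 2 * quad_d +
        dgamma(tau_p, pr$tau_shape, rate = pr$tau_rate, log = TRUE) -
        dgamma(st$tau, pr$tau_shape, rate = pr$tau_rate, log = TRUE) +
        log(tau_p) - log(st$tau)
      a <- is.finite(lr) && log(runif(1)) < lr
      if (a) st$tau <- tau_p
      if (adapting) s_tau <- s_tau * exp(it^-0.6 * (a - 0.35))
      else acc["tau"] <- acc["tau"] + a
    }

    if (it > n_burn && (it - n_burn) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- c(st$beta_lambda, st$beta_gamma,
                         if (model$q > 0) st$delta, st$eps,
                         st$phi, st$sigma, st$tau)
    }
  }
  n_post <- n_iter - n_burn
  rates <- acc / n_post
  rates["eps"] <- acc["eps"] / n_post
  list(draws = draws, acceptance = rates)
}

#' @rdname run_mcmc
#' @param n_iter iterations per chain.
#' @param n_burn burn-in iterations discarded (adaptation happens only here,
#'   so detailed balance holds for the retained draws).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param n_chains number of independent chains.
#' @param seed integer seed; chain `c` uses `seed + 1000 * (c - 1)`.
#' @export
run_mcmc.abundance_model <- function(model, n_iter = 20000, n_burn = 10000,
                                     thin = 10, n_chains = 3, seed = 1L, ...) {
  if (n_burn >= n_iter) stop("n_burn must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  chains <- lapply(seq_len(n_chains), function(cc)
    run_chain_abn(model, n_iter, n_burn, thin, chain_seed = seed + 1000L * (cc - 1L)))
  structure(list(chains = lapply(chains, `[[`, "draws"),
                 acceptance = lapply(chains, `[[`, "acceptance"),
                 n_iter = n_iter, n_burn = n_burn, thin = thin,
                 n_chains = n_chains, seed = seed,
                 groups = abn_groups(model)),
            class = "posterior_samples")
}

abn_groups <- function(model) {
  nm <- abn_param_names(model)
  list(beta_lambda = grep("^beta_lambda\\[", nm),
       beta_gamma = grep("^beta_gamma\\[", nm),
       delta = grep("^delta\\[", nm),
       eps = grep("^eps\\[", nm),
       phi = which(nm == "phi"), sigma = which(nm == "sigma"),
       tau = which(nm == "tau"))
}

#' @rdname run_mcmc
#' @param init numeric initial parameter vector (function method).
#' @param step_sd initial proposal SD (function method).
#' @export
run_mcmc.function <- function(model, init, n_iter = 20000, n_burn = 10000,
                              thin = 1, n_chains = 2, seed = 1L,
                              step_sd = 1, ...) {
  if (n_burn >= n_iter) stop("n_burn must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  d <- length(init)
  nm <- if (!is.null(names(init))) names(init) else paste0("theta", seq_len(d))
  one_chain <- function(chain_seed) {
    set.seed(chain_seed)
    x <- init + rnorm(d, 0, step_sd / 2)
    lp <- model(x)
    check_finite(lp, "initial")
    s <- rep(step_sd, d)
    nkeep <- (n_iter - n_burn) %/% thin
    draws <- matrix(NA_real_, nkeep, d, dimnames = list(NULL, nm))
    kept <- 0L; acc <- numeric(d)
    for (it in seq_len(n_iter)) {
      for (k in seq_len(d)) {
        xp <- x; xp[k] <- x[k] + s[k] * rnorm(1)
        lpp <- check_finite(model(xp), nm[k])
        a <- is.finite(lpp - lp) && log(runif(1)) < lpp - lp
        if (a) { x <- xp; lp <- lpp }
        if (it <= n_burn) s[k] <- s[k] * exp(it^-0.6 * (a - 0.35))
        else acc[k] <- acc[k] + a
      }
      if (it > n_burn && (it - n_burn) %% thin == 0) {
        kept <- kept + 1L
        draws[kept, ] <- x
      }
    }
    list(draws = draws, acceptance = setNames(acc / (n_iter - n_burn), nm))
  }
  chains <- lapply(seq_len(n_chains), function(cc)
    one_chain(seed + 1000L * (cc - 1L)))
  structure(list(chains = lapply(chains, `[[`, "draws"),
                 acceptance = lapply(chains, `[[`, "acceptance"),
                 n_iter = n_iter, n_burn = n_burn, thin = thin,
                 n_chains = n_chains, seed = seed, groups = NULL),
            class = "posterior_samples")
}

#' Pool posterior draws across chains
#'
#' @param samples a `posterior_samples` object.
#' @param pars optional parameter-name regular expression to select columns.
#' @return matrix of pooled draws.
#' @export
pool_draws <- function(samples, pars = NULL) {
  m <- do.call(rbind, samples$chains)
  if (!is.null(pars)) m <- m[, grep(pars, colnames(m)), drop = FALSE]
  m
}

#' Gelman-Rubin potential scale reduction
#'
#' Computed per parameter from the within-chain variance `W` and the
#' between-chain variance of chain means `B/n` as
#' `Rhat = sqrt((W + B/n) / W)` — the large-sample form of the classic
#' statistic, which equals exactly 1 when chains are identical. Values near 1
#' indicate convergence; > 1.1 is commonly taken as failure.
#'
#' @param samples a `posterior_samples` object (>= 2 chains, >= 10 draws each)
#'   or a list of draw matrices.
#' @return named numeric vector of Rhat values (NA for degenerate parameters
#'   with zero total variance).
#' @export
gelman_rubin <- function(samples) {
  chains <- if (inherits(samples, "posterior_samples")) samples$chains else samples
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains")
  n <- nrow(chains[[1]])
  if (n < 10) stop("need at least 10 draws per chain")
  if (!all(vapply(chains, nrow, 1L) == n)) stop("chains differ in length")
  W <- Reduce(`+`, lapply(chains, function(ch) apply(ch, 2, var))) / m
  mu <- vapply(chains, colMeans, numeric(ncol(chains[[1]])))
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  Bn <- apply(mu, 1, var)  # = B/n
  rhat <- sqrt((W + Bn) / W)
  rhat[W == 0 & Bn == 0] <- 1
  setNames(rhat, colnames(chains[[1]]))
}

#' Posterior summary table
#'
#' @param samples a `posterior_samples` object or a draw matrix.
#' @param levels lower/upper quantiles of the credibility interval.
#' @param pars optional parameter-selection regular expression.
#' @return data.frame `parameter`, `mean`, `sd`, `lower`, `upper`,
#'   `differs_from_zero` (TRUE iff the CI excludes 0).
#' @export
summarize_posterior <- function(samples, levels = c(0.025, 0.975), pars = NULL) {
  m <- if (inherits(samples, "posterior_samples")) pool_draws(samples, pars)
       else as.matrix(samples)
  if (nrow(m) == 0) stop("empty samples")
  qs <- apply(m, 2, quantile, probs = levels, names = FALSE)
  out <- data.frame(parameter = colnames(m),
                    mean = colMeans(m),
                    sd = apply(m, 2, sd),
                    lower = qs[1, ], upper = qs[2, ],
                    stringsAsFactors = FALSE)
  out$differs_from_zero <- out$lower > 0 | out$upper < 0
  rownames(out) <- NULL
  out
}

#' Posterior predictive Bayesian p-value
#'
#' For each retained draw, data are re-simulated from the fitted model (latent
#' abundance, then counts) and a discrepancy is computed on both the replicate
#' and the observed counts; the p-value is the fraction of draws with
#' `D(y_rep) >= D(y_obs)` (ties count toward the upper tail). The default
#' discrepancy is the chi-square-type statistic `sum((y - E[y])^2 / E[y])`
#' with `E[y] = lambda_cell * gamma * effort`. Values near 0 or 1 indicate
#' misfit.
#'
#' @param samples `posterior_samples` from [run_mcmc()] on this model.
#' @param model the fitted [abundance_model()].
#' @param discrepancy function `(y, Ey) -> scalar`; `NULL` uses the default.
#' @param max_draws cap on the number of posterior draws used.
#' @param seed RNG seed for the replicate simulations.
#' @return scalar p-value in `[0, 1]`.
#' @export
posterior_predictive_pvalue <- function(samples, model, discrepancy = NULL,
                                        max_draws = 200L, seed = 1L) {
  m <- pool_draws(samples)
  if (nrow(m) == 0) stop("zero retained draws")
  if (is.null(discrepancy))
    discrepancy <- function(y, Ey) sum((y - Ey)^2 / pmax(Ey, 1e-12))
  g <- samples$groups
  idx <- unique(round(seq(1, nrow(m), length.out = min(max_draws, nrow(m)))))
  K <- if (model$q > 0) model$basis$K else NULL
  with_seed(seed, {
    exceed <- vapply(idx, function(r) {
      bl <- m[r, g$beta_lambda]
      bg <- m[r, g$beta_gamma]
      phi <- m[r, g$phi]
      loglam <- drop(model$X_lambda %*% bl)
      if (model$q > 0) loglam <- loglam + drop(K %*% m[r, g$delta])
      gam <- exp(drop(model$X_gamma %*% bg) + m[r, g$eps])
      lam_site <- exp(loglam)[model$site_cell]
      Ey <- lam_site * gam * model$effort
      d_obs <- discrepancy(model$y, Ey)
      N_rep <- rnbinom(model$G, size = phi, mu = exp(loglam))
      y_rep <- rpois(model$S, N_rep[model$site_cell] * gam * model$effort)
      d_rep <- discrepancy(y_rep, Ey)
      d_rep >= d_obs
    }, logical(1))
    mean(exceed)
  })
}
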