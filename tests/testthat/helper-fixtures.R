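# shared builders for model-scale fixtures

# small simulated survey + assembled model, deterministic in `seed`
make_toy_model <- function(nx = 10, ny = 10, n_sites = 40, q = 8, seed = 2,
                           beta_lambda = c(0.5, 0.8, -0.4), phi = 2, sigma = 0.3) {
  cfg <- sim_config(nx = nx, ny = ny, n_sites = n_sites, seed = seed,
                    beta_lambda = beta_lambda, phi = phi, sigma = sigma)
  gr <- generate_landscape(cfg)
  lat <- simulate_latent_abundance(gr, cfg$beta_lambda, phi = cfg$phi,
                                   seed = seed + 1)
  svy <- simulate_camera_survey(gr, lat$N, cfg, seed = seed + 2)
  adj <- build_adjacency(nx, ny)
  basis <- build_rsr_basis(lat$X_lambda, adj$A, adj$Q, q = q)
  Xg <- cbind(`(Intercept)` = rep(1, nrow(svy)), gcov1 = svy$gcov1)
  mod <- abundance_model(svy$y, svy$effort, svy$cell, lat$X_lambda, Xg, basis)
  list(cfg = cfg, grid = gr, lat = lat, svy = svy, adj = adj, basis = basis,
       model = mod)
}

# naive integrated likelihood of one cell: direct summation, no log-sum-exp
naive_cell_loglik <- function(y, gd, lam, phi, Nmax = 100) {
  if (length(y) == 0) return(0)
  s <- sum(vapply(0:Nmax, function(N)
    exp(dnbinom(N, size = phi, mu = lam, log = TRUE) +
          sum(dpois(y, N * gd, log = TRUE))), numeric(1)))
  log(s)
}

# replicate parameter-recovery fits are expensive; run once, share across tests
recovery_cache <- new.env(parent = emptyenv())

recovery_fits <- function(n_rep = 5, seed0 = 101) {
  key <- paste0("fits_", n_rep, "_", seed0)
  if (!is.null(recovery_cache[[key]])) return(recovery_cache[[key]])
  truth <- list(beta_lambda = c(0.5, 0.8, -0.4), phi = 2, sigma = 0.3)
  fits <- lapply(seq_len(n_rep), function(r) {
    seed <- seed0 + r
    fx <- make_toy_model(nx = 20, ny = 20, n_sites = 150, q = 40, seed = seed,
                         beta_lambda = truth$beta_lambda, phi = truth$phi,
                         sigma = truth$sigma)
    sm <- run_mcmc(fx$model, n_iter = 20000, n_burn = 10000, thin = 10,
                   n_chains = 3, seed = seed)
    list(fx = fx, samples = sm,
         summary = summarize_posterior(sm, pars = "^beta_lambda\\["))
  })
  out <- list(truth = truth, fits = fits)
  recovery_cache[[key]] <- out
  out
}
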