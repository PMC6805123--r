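#' Default pipeline configuration
#'
#' Desk-scale settings for the staged analysis: a small landscape, one
#' predator and two herbivore species whose relative densities respond to the
#' landscape gradients and (for herbivores) to the predator's space use, a
#' short sampler run, clustering into herbivory regimes and a vegetation
#' stage. Pass the result (possibly edited, or loaded from YAML) to
#' [run_pipeline()]. `paper_scale = TRUE` switches the sampler to the
#' full-length settings (3 chains x 500,000 iterations, burn-in 400,000,
#' thinning 20).
#'
#' @param seed master seed; every stage derives its RNG stream from it.
#' @param paper_scale use full-length sampler settings?
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, paper_scale = FALSE) {
  sampler <- if (paper_scale)
    list(n_iter = 500000L, n_burn = 400000L, thin = 20L, n_chains = 3L)
  else list(n_iter = 4000L, n_burn = 2000L, thin = 5L, n_chains = 2L)
  list(
    seed = as.integer(seed),
    grid = list(nx = 12L, ny = 12L, cell_size = 500),
    covariates = list(
      list(name = "forest_openness", smoothing = 3, quadratic = FALSE),
      list(name = "conifer_share", smoothing = 3, quadratic = FALSE)),
    survey = list(n_sites = 70L, effort_range = c(20L, 40L), max_per_cell = 2L),
    predator = list(name = "wolf", beta_lambda = c(-0.2, 0.5, -0.3),
                    beta_gamma = c(-2.3), phi = 3, sigma = 0.2),
    herbivores = list(
      list(name = "red_deer_female", beta_lambda = c(0.6, 0.5, -0.3),
           beta_risk = -0.5, beta_gamma = c(-2.0), phi = 2, sigma = 0.2),
      list(name = "wild_boar", beta_lambda = c(0.4, -0.4, 0.2),
           beta_risk = 0.1, beta_gamma = c(-2.0), phi = 2, sigma = 0.2)),
    model = list(Nmax = 100L, q_frac = 0.1, adjacency = "rook"),
    sampler = sampler,
    clustering = list(k = 3L, consolidate = TRUE),
    vegetation = list(browse_prob = c(0.55, 0.35, 0.15), n_plots = 300L),
    stages = c("simulate", "fit_predator", "fit_herbivores", "predict",
               "community", "vegetation"))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- pipeline_config()
  utils::modifyList(base, config)
}

pipe_seed <- function(master, stage_no) master + 7919L * stage_no

fit_one_species <- function(y, effort, cell, X_lambda, adj, config, seed) {
  Sd <- length(y)
  X_gamma <- matrix(1, Sd, 1, dimnames = list(NULL, "(Intercept)"))
  basis <- build_rsr_basis(X_lambda, adj$A, adj$Q,
                           q = max(2L, ceiling(config$model$q_frac * nrow(X_lambda))))
  mod <- abundance_model(y, effort, cell, X_lambda, X_gamma, basis,
                         Nmax = config$model$Nmax)
  sm <- run_mcmc(mod, n_iter = config$sampler$n_iter, n_burn = config$sampler$n_burn,
                 thin = config$sampler$thin, n_chains = config$sampler$n_chains,
                 seed = seed)
  list(model = mod, samples = sm)
}

#' Run the staged analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate the landscape and
#' surveys, fit the predator model, export its fitted density as a
#' standardized risk covariate, fit each herbivore with that covariate,
#' predict relative-density surfaces, build the community products (biomass,
#' FDis, herbivory-regime clustering) and run the vegetation stage. All
#' tabular artifacts are written as CSV into `output_dir` together with a YAML
#' config snapshot; outputs are pure functions of (config, seed).
#'
#' @param config a [pipeline_config()] list, a partial list of overrides, or a
#'   YAML file path.
#' @param output_dir directory for artifacts (created if missing).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = tempfile("run_")) {
  cfg <- read_pipeline_config(if (is.list(config)) config else config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  res <- list()
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stop("stage '", stage, "' requires missing upstream artifact '", what, "'")
  }
  wcsv <- function(df, name) write.csv(df, file.path(output_dir, name), row.names = FALSE)

  specs <- lapply(cfg$covariates, function(cv)
    cov_spec(cv$name, cv$smoothing, isTRUE(cv$quadratic)))
  adj <- NULL

  if ("simulate" %in% stages) {
    all_sp <- c(list(cfg$predator), cfg$herbivores)
    sc <- sim_config(nx = cfg$grid$nx, ny = cfg$grid$ny, cell_size = cfg$grid$cell_size,
                     covariates = specs,
                     beta_lambda = cfg$predator$beta_lambda,
                     beta_gamma = cfg$predator$beta_gamma,
                     phi = cfg$predator$phi, sigma = cfg$predator$sigma,
                     n_sites = cfg$survey$n_sites,
                     effort_range = cfg$survey$effort_range,
                     max_per_cell = cfg$survey$max_per_cell,
                     n_site_covariates = 0L,
                     seed = pipe_seed(cfg$seed, 1L))
    grid <- generate_landscape(sc)
    Xl <- build_design_matrix(grid$covariates)$X
    # predator truth and survey
    pred_lat <- simulate_latent_abundance(grid, cfg$predator$beta_lambda,
                                          phi = cfg$predator$phi,
                                          seed = pipe_seed(cfg$seed, 2L))
    pred_cfg <- sc
    pred_svy <- simulate_camera_survey(grid, pred_lat$N, pred_cfg,
                                       seed = pipe_seed(cfg$seed, 3L))
    # herbivores respond to the predator's true (standardized) density surface
    risk_true <- drop(standardize_covariates(
      matrix(pred_lat$lambda, ncol = 1, dimnames = list(NULL, "risk")))$data)
    herb <- list()
    for (i in seq_along(cfg$herbivores)) {
      hcf <- cfg$herbivores[[i]]
      loglam <- drop(Xl %*% hcf$beta_lambda) + hcf$beta_risk * risk_true
      lam <- exp(loglam)
      N <- with_seed(pipe_seed(cfg$seed, 10L + i),
                     rnbinom(grid$G, size = hcf$phi, mu = lam))
      scfh <- sim_config(nx = cfg$grid$nx, ny = cfg$grid$ny,
                         cell_size = cfg$grid$cell_size, covariates = specs,
                         beta_lambda = hcf$beta_lambda, beta_gamma = hcf$beta_gamma,
                         phi = hcf$phi, sigma = hcf$sigma,
                         n_sites = cfg$survey$n_sites,
                         effort_range = cfg$survey$effort_range,
                         max_per_cell = cfg$survey$max_per_cell,
                         n_site_covariates = 0L, seed = cfg$seed)
      svy <- simulate_camera_survey(grid, N, scfh, seed = pipe_seed(cfg$seed, 20L + i))
      herb[[hcf$name]] <- list(cfg = hcf, N = N, lambda = lam, survey = svy)
      wcsv(svy, paste0("survey_", hcf$name, ".csv"))
    }
    res$grid <- grid
    res$X_lambda <- Xl
    res$predator_sim <- list(cfg = cfg$predator, lat = pred_lat, survey = pred_svy)
    res$herbivore_sim <- herb
    land <- data.frame(cell = seq_len(grid$G), x = grid$x, y = grid$y,
                       grid$covariates, check.names = FALSE)
    wcsv(land, "landscape.csv")
    wcsv(pred_svy, paste0("survey_", cfg$predator$name, ".csv"))
  }

  if (any(c("fit_predator", "fit_herbivores") %in% stages)) {
    need("grid", "fit")
    adj <- build_adjacency(res$grid$nx, res$grid$ny, rule = cfg$model$adjacency)
  }

  if ("fit_predator" %in% stages) {
    need("predator_sim", "fit_predator")
    svy <- res$predator_sim$survey
    fit <- fit_one_species(svy$y, svy$effort, svy$cell, res$X_lambda, adj, cfg,
                           seed = pipe_seed(cfg$seed, 30L))
    res$predator_fit <- fit
    surf <- predict_lambda_surface(fit$samples, fit$model,
                                   species = cfg$predator$name)
    res$predator_surface <- surf
    res$risk <- risk_covariate(surf, paste0(cfg$predator$name, "_risk"))
    wcsv(summarize_posterior(fit$samples, pars = "^beta|^phi$|^sigma$|^tau$"),
         paste0("posterior_", cfg$predator$name, ".csv"))
    wcsv(surf, paste0("surface_", cfg$predator$name, ".csv"))
  }

  if ("fit_herbivores" %in% stages) {
    need("herbivore_sim", "fit_herbivores")
    need("risk", "fit_herbivores")
    Xl_risk <- cbind(res$X_lambda, res$risk)
    res$herbivore_fits <- list()
    res$surfaces <- list()
    for (i in seq_along(res$herbivore_sim)) {
      nm <- names(res$herbivore_sim)[i]
      svy <- res$herbivore_sim[[i]]$survey
      fit <- fit_one_species(svy$y, svy$effort, svy$cell, Xl_risk, adj, cfg,
                             seed = pipe_seed(cfg$seed, 40L + i))
      res$herbivore_fits[[nm]] <- fit
      wcsv(summarize_posterior(fit$samples, pars = "^beta|^phi$|^sigma$|^tau$"),
           paste0("posterior_", nm, ".csv"))
    }
  }

  if ("predict" %in% stages) {
    need("herbivore_fits", "predict")
    for (nm in names(res$herbivore_fits)) {
      fit <- res$herbivore_fits[[nm]]
      surf <- predict_lambda_surface(fit$samples, fit$model, species = nm)
      res$surfaces[[nm]] <- surf
      wcsv(surf, paste0("surface_", nm, ".csv"))
    }
  }

  if ("community" %in% stages) {
    need("surfaces", "community")
    traits <- simulate_trait_table(6L)
    weights <- default_biomass_weights()
    bio <- biomass_surfaces(res$surfaces, weights)
    lam_mat <- vapply(res$surfaces, function(s) s$mean, numeric(res$grid$G))
    tr_sub <- traits[match(names(res$surfaces), traits$species), ]
    fdis <- compute_fdis(tr_sub, lam_mat)
    feats <- cbind(bio, fdis = fdis)
    cl <- hcpc_cluster(feats, k = cfg$clustering$k,
                       consolidate = isTRUE(cfg$clustering$consolidate),
                       seed = pipe_seed(cfg$seed, 50L))
    res$biomass <- bio
    res$fdis <- fdis
    res$clustering <- cl
    wcsv(cbind(cell = seq_len(res$grid$G), bio), "biomass.csv")
    wcsv(data.frame(cell = seq_len(res$grid$G), fdis = fdis,
                    cluster = cl$labels), "herbiscapes.csv")
    wcsv(cl$profiles, "cluster_profiles.csv")
  }

  if ("vegetation" %in% stages) {
    need("clustering", "vegetation")
    k <- max(res$clustering$labels)
    bp <- rep_len(cfg$vegetation$browse_prob, k)
    plots <- simulate_vegetation_plots(res$clustering$labels, bp,
                                       n_plots = cfg$vegetation$n_plots,
                                       seed = pipe_seed(cfg$seed, 60L))
    bi <- browsing_intensity(plots)
    fit <- fit_herbiscape_lm(bi, "intensity")
    res$vegetation <- list(plots = plots, intensity = bi, lm = fit)
    wcsv(plots, "vegetation_plots.csv")
    wcsv(fit$predictions, "vegetation_lm_predictions.csv")
    wcsv(fit$coefficients, "vegetation_lm_coefficients.csv")
  }

  yaml::write_yaml(cfg, file.path(output_dir, "config_snapshot.yaml"))
  invisible(res)
}
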