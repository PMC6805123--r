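#' Covariate specification for the landscape simulator
#'
#' @param name covariate name (unique within a configuration).
#' @param smoothing Gaussian smoothing length in cells; `0` gives standardized
#'   white noise, larger values give smoother, more spatially autocorrelated
#'   fields.
#' @param quadratic should downstream design matrices carry a squared column
#'   for this covariate?
#' @return a `cov_spec` list.
#' @export
cov_spec <- function(name, smoothing = 3, quadratic = FALSE) {
  stopifnot(is.character(name), nzchar(name), smoothing >= 0)
  structure(list(name = name, smoothing = smoothing, quadratic = isTRUE(quadratic)),
            class = "cov_spec")
}

#' Simulation configuration
#'
#' Bundles everything the synthetic-data generator needs: grid geometry,
#' covariate fields, the true parameters of the hierarchical abundance model
#' (log-linear effects on relative density and trapping rate, Negative-Binomial
#' dispersion, site-error SD, spatial-residual amplitude) and the camera plan.
#'
#' @param nx,ny grid dimensions in cells (`nx * ny = G >= 4`).
#' @param cell_size cell side in metres (default 500 m, i.e. 25 ha cells).
#' @param covariates list of [cov_spec()] entries; names must be unique.
#' @param beta_lambda true coefficients for the relative-density linear
#'   predictor, ordered `(intercept, covariates..., quadratics...)` to match
#'   [build_design_matrix()].
#' @param beta_gamma true coefficients for the trapping-rate linear predictor,
#'   `(intercept, site covariates...)`.
#' @param phi true Negative-Binomial dispersion (`> 0`; variance
#'   `lambda + lambda^2/phi`).
#' @param sigma true SD of the lognormal site-level detection noise (`>= 0`).
#' @param spatial_amplitude marginal SD of the smooth spatial residual added to
#'   `log(lambda)`; `0` disables spatial residuals.
#' @param spatial_range smoothing length (cells) of the spatial residual field.
#' @param n_sites number of camera sites.
#' @param effort_range integer range of effort days per site (all `>= 1`).
#' @param max_per_cell maximum cameras allowed in one cell.
#' @param n_site_covariates number of site-scale (detection) covariates to
#'   simulate; must be `length(beta_gamma) - 1`.
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(nx = 20, ny = 20, cell_size = 500,
                       covariates = list(cov_spec("forest_openness", 4, quadratic = FALSE),
                                         cov_spec("conifer_share", 4, quadratic = FALSE)),
                       beta_lambda = c(0.5, 0.8, -0.4),
                       beta_gamma = c(-1.9, 0.3),
                       phi = 2, sigma = 0.3,
                       spatial_amplitude = 0, spatial_range = 5,
                       n_sites = 150, effort_range = c(20L, 40L),
                       max_per_cell = 2L, n_site_covariates = length(beta_gamma) - 1L,
                       seed = 1L) {
  G <- nx * ny
  if (nx < 1 || ny < 1 || G < 4) stop("grid must have at least 4 cells")
  nm <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate covariate names: ", nm[duplicated(nm)][1])
  if (phi <= 0) stop("phi must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (any(effort_range < 1)) stop("all effort values must be >= 1 day")
  nquad <- sum(vapply(covariates, `[[`, logical(1), "quadratic"))
  p_lam <- 1L + length(covariates) + nquad
  if (length(beta_lambda) != p_lam)
    stop("beta_lambda must have length ", p_lam,
         " (intercept + covariates + quadratics)")
  if (length(beta_gamma) != n_site_covariates + 1L)
    stop("beta_gamma must have length n_site_covariates + 1")
  structure(list(nx = nx, ny = ny, cell_size = cell_size, covariates = covariates,
                 beta_lambda = beta_lambda, beta_gamma = beta_gamma, phi = phi,
                 sigma = sigma, spatial_amplitude = spatial_amplitude,
                 spatial_range = spatial_range, n_sites = as.integer(n_sites),
                 effort_range = as.integer(effort_range),
                 max_per_cell = as.integer(max_per_cell),
                 n_site_covariates = as.integer(n_site_covariates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Gaussian-kernel smoothing of an nx x ny field, separable in x and y.
# smoothing = 0 returns the field unchanged.
smooth_field <- function(z, smoothing) {
  if (smoothing <= 0) return(z)
  kern <- function(n) {
    d <- outer(seq_len(n), seq_len(n), `-`)
    k <- exp(-d^2 / (2 * smoothing^2))
    k / rowSums(k)
  }
  kern(nrow(z)) %*% z %*% t(kern(ncol(z)))
}

# population-SD standardization (divisor n), exactly mean 0 / SD 1
standardize_vec <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("cannot standardize a constant field")
  (x - mean(x)) / s
}

#' Generate a synthetic landscape grid
#'
#' Each covariate layer is produced by Gaussian-kernel smoothing of seeded
#' white noise and then standardized (zero mean, unit population SD), emulating
#' scaled environmental gradient rasters on a regular grid. The smoothing
#' length controls spatial autocorrelation.
#'
#' @param config a [sim_config()].
#' @return a `landscape_grid`: list with grid dims, cell size, cell-centre
#'   coordinates, a `G x n_cov` standardized covariate matrix and the covariate
#'   specs. Cells are indexed in column-major order (x fastest).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nx <- config$nx; ny <- config$ny; G <- nx * ny
  covs <- with_seed(config$seed, {
    vapply(config$covariates, function(sp) {
      z <- matrix(rnorm(G), nx, ny)
      standardize_vec(as.vector(smooth_field(z, sp$smoothing)))
    }, numeric(G))
  })
  colnames(covs) <- vapply(config$covariates, `[[`, character(1), "name")
  ix <- (seq_len(G) - 1L) %% nx
  iy <- (seq_len(G) - 1L) %/% nx
  structure(list(nx = nx, ny = ny, G = G, cell_size = config$cell_size,
                 x = (ix + 0.5) * config$cell_size,
                 y = (iy + 0.5) * config$cell_size,
                 covariates = covs,
                 specs = config$covariates),
            class = "landscape_grid")
}

#' Simulate a smooth spatial residual field
#'
#' A standardized Gaussian smooth field scaled to a given marginal SD, used as
#' the true spatial random effect `omega` on the log relative-density scale.
#'
#' @param grid a `landscape_grid`.
#' @param amplitude marginal SD of the field (0 returns all zeros).
#' @param range smoothing length in cells.
#' @param seed RNG seed.
#' @return numeric vector of length `G`.
#' @export
simulate_spatial_field <- function(grid, amplitude, range = 5, seed = 1L) {
  if (amplitude == 0) return(numeric(grid$G))
  with_seed(seed, {
    z <- matrix(rnorm(grid$G), grid$nx, grid$ny)
    amplitude * standardize_vec(as.vector(smooth_field(z, range)))
  })
}

#' Simulate latent cell abundances
#'
#' Draws the latent relative density per cell: `N_j ~ NegBin(mean lambda_j,
#' dispersion phi)` with `log(lambda_j) = x_j' beta_lambda + omega_j`.
#'
#' @param grid a `landscape_grid`.
#' @param beta_lambda coefficient vector matching the design built by
#'   [build_design_matrix()] from the grid covariates (quadratic columns for
#'   covariates flagged quadratic in the grid's specs).
#' @param omega spatial residual vector (length `G`) or `NULL` for zero.
#' @param phi Negative-Binomial dispersion, `> 0`.
#' @param seed RNG seed.
#' @return list with integer abundances `N`, expected densities `lambda`, and
#'   the design matrix `X_lambda` used.
#' @export
simulate_latent_abundance <- function(grid, beta_lambda, omega = NULL, phi, seed = 1L) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (phi <= 0) stop("phi must be > 0")
  if (is.null(omega)) omega <- numeric(grid$G)
  if (length(omega) != grid$G) stop("omega must have length G")
  quad <- vapply(grid$specs, function(s) if (s$quadratic) s$name else NA_character_,
                 character(1))
  X <- build_design_matrix(grid$covariates, quadratic = quad[!is.na(quad)])$X
  if (ncol(X) != length(beta_lambda))
    stop("beta_lambda length ", length(beta_lambda), " does not match design (",
         ncol(X), " columns)")
  lambda <- exp(drop(X %*% beta_lambda) + omega)
  N <- with_seed(seed, rnbinom(grid$G, size = phi, mu = lambda))
  list(N = as.integer(N), lambda = lambda, X_lambda = X)
}

#' Simulate a camera-trap survey
#'
#' Places cameras uniformly at random among cells (at most `max_per_cell` per
#' cell), draws per-site effort and detection covariates, then counts:
#' `y_i ~ Poisson(N_j(i) * gamma_i * d_i)` with
#' `log(gamma_i) = x_i' beta_gamma + eps_i`, `eps_i ~ N(0, sigma^2)`.
#'
#' @param grid a `landscape_grid`.
#' @param N integer latent abundance per cell.
#' @param config a [sim_config()] carrying the camera plan and true
#'   `beta_gamma`, `sigma`.
#' @param seed RNG seed.
#' @return a `camera_survey` data.frame: `site`, `cell` (1-based), `effort`
#'   (days), site covariates `gcov1..`, true `eps`, true `gamma`, and count `y`.
#' @export
simulate_camera_survey <- function(grid, N, config, seed = 1L) {
  stopifnot(inherits(grid, "landscape_grid"), inherits(config, "sim_config"))
  if (length(N) != grid$G) stop("N must have length G")
  if (any(N < 0)) stop("negative abundance")
  S <- config$n_sites
  if (S > grid$G * config$max_per_cell)
    stop("camera plan exceeds capacity: S > G * max_per_cell")
  with_seed(seed, {
    slots <- rep(seq_len(grid$G), config$max_per_cell)
    cell <- sort(slots[sample.int(length(slots), S)])
    eff_vals <- seq(config$effort_range[1], config$effort_range[2])
    effort <- eff_vals[sample.int(length(eff_vals), S, replace = TRUE)]
    k <- config$n_site_covariates
    Xg <- if (k > 0) matrix(rnorm(S * k), S, k) else matrix(numeric(0), S, 0)
    if (k > 0) {
      Xg <- apply(Xg, 2, standardize_vec)
      colnames(Xg) <- paste0("gcov", seq_len(k))
    }
    eps <- rnorm(S, 0, config$sigma)
    gamma <- exp(drop(cbind(1, Xg) %*% config$beta_gamma) + eps)
    y <- rpois(S, N[cell] * gamma * effort)
    out <- data.frame(site = paste0("site_", sprintf("%03d", seq_len(S))),
                      cell = cell, effort = effort)
    if (k > 0) out <- cbind(out, as.data.frame(Xg))
    out$eps <- eps
    out$gamma <- gamma
    out$y <- y
    class(out) <- c("camera_survey", "data.frame")
    out
  })
}

#' Species trait table
#'
#' The default six-species table mirrors a Central-European lowland-forest
#' ungulate community, with body masses (kg) 90 (red deer female), 150 (red
#' deer male), 20 (roe deer), 80 (wild boar), 200 (moose) and 400 (European
#' bison). Gut- and diet-type categories are plausible placeholders for that
#' community. Other `n_species` values draw masses lognormally and categories
#' from fixed vocabularies.
#'
#' @param n_species number of species (`>= 1`); 6 returns the default table.
#' @param seed RNG seed (used only when `n_species != 6`).
#' @return data.frame with `species`, `body_mass_kg`, `gut_type`, `diet_type`.
#' @export
simulate_trait_table <- function(n_species = 6L, seed = 1L) {
  if (n_species < 1) stop("n_species must be >= 1")
  if (n_species == 6L) {
    return(data.frame(
      species = c("red_deer_female", "red_deer_male", "roe_deer",
                  "wild_boar", "moose", "european_bison"),
      body_mass_kg = c(90, 150, 20, 80, 200, 400),
      gut_type = c("ruminant", "ruminant", "ruminant",
                   "monogastric", "ruminant", "ruminant"),
      diet_type = c("mixed_feeder", "mixed_feeder", "browser",
                    "omnivore", "browser", "grazer"),
      stringsAsFactors = FALSE))
  }
  guts <- c("ruminant", "monogastric")
  diets <- c("browser", "grazer", "mixed_feeder", "omnivore")
  with_seed(seed, data.frame(
    species = paste0("sp_", seq_len(n_species)),
    body_mass_kg = round(exp(rnorm(n_species, log(80), 0.8)), 1),
    gut_type = sample(guts, n_species, replace = TRUE),
    diet_type = sample(diets, n_species, replace = TRUE),
    stringsAsFactors = FALSE))
}

#' Simulate vegetation regeneration plots
#'
#' Emulates concentric-subplot tree-regeneration surveys: each plot carries a
#' herbivory-regime (cluster) label, a reserve flag, per-species sapling counts
#' in two height classes (`< 30 cm` and `>= 30 cm`) and, for the taller class,
#' a browsed-tree count drawn Bernoulli per tree with the cluster's browse
#' probability.
#'
#' @param cluster_labels integer cluster label per landscape cell (plots sample
#'   cells uniformly), or directly a vector of per-plot labels when
#'   `n_plots = length(cluster_labels)` and `sample_cells = FALSE`.
#' @param browse_prob named or positional vector of browse probabilities in
#'   `[0, 1]`, one per cluster level.
#' @param n_plots number of plots.
#' @param species species pool for the sapling community.
#' @param mean_small,mean_tall expected sapling counts per plot and species in
#'   the two height classes.
#' @param reserve_prob probability a plot falls inside a protected reserve.
#' @param sample_cells if `TRUE` (default), plots are assigned to clusters by
#'   sampling cells uniformly.
#' @param seed RNG seed.
#' @return long-format data.frame: `plot`, `cluster`, `reserve`, `species`,
#'   `n_small`, `n_tall`, `n_browsed` (`n_browsed <= n_tall`).
#' @export
simulate_vegetation_plots <- function(cluster_labels, browse_prob, n_plots = 500L,
                                      species = c("Carpinus", "Acer", "Tilia",
                                                  "Quercus", "Picea", "Other"),
                                      mean_small = 3, mean_tall = 2,
                                      reserve_prob = 0.5, sample_cells = TRUE,
                                      seed = 1L) {
  if (n_plots < 1) stop("n_plots must be >= 1")
  if (any(browse_prob < 0 | browse_prob > 1)) stop("browse_prob must lie in [0, 1]")
  levs <- sort(unique(cluster_labels))
  if (length(browse_prob) < length(levs))
    stop("need one browse probability per cluster level")
  pb <- if (is.null(names(browse_prob))) setNames(browse_prob[seq_along(levs)],
                                                  as.character(levs)) else browse_prob
  with_seed(seed, {
    cl <- if (sample_cells)
      cluster_labels[sample.int(length(cluster_labels), n_plots, replace = TRUE)]
    else cluster_labels[seq_len(n_plots)]
    reserve <- rbinom(n_plots, 1, reserve_prob)
    K <- length(species)
    n_small <- rpois(n_plots * K, mean_small)
    n_tall <- rpois(n_plots * K, mean_tall)
    p_plot <- pb[as.character(cl)]
    n_browsed <- rbinom(n_plots * K, n_tall, rep(p_plot, each = K))
    data.frame(plot = rep(seq_len(n_plots), each = K),
               cluster = rep(cl, each = K),
               reserve = rep(reserve, each = K),
               species = rep(species, times = n_plots),
               n_small = n_small, n_tall = n_tall, n_browsed = n_browsed,
               stringsAsFactors = FALSE)
  })
}
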