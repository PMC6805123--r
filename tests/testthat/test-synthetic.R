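test_that("landscape layers are standardized, deterministic and smoothing raises autocorrelation", {
  cfg <- sim_config(nx = 50, ny = 50, n_sites = 100,
                    covariates = list(cov_spec("white", 0), cov_spec("smooth", 5)),
                    beta_lambda = c(0, 0, 0), seed = 7)
  gr <- generate_landscape(cfg)
  expect_equal(colMeans(gr$covariates), c(white = 0, smooth = 0), tolerance = 1e-12)
  expect_equal(apply(gr$covariates, 2, function(x) sqrt(mean(x^2))),
               c(white = 1, smooth = 1), tolerance = 1e-12)
  gr2 <- generate_landscape(cfg)
  expect_identical(gr$covariates, gr2$covariates)

  # lag-1 Moran's I by direct double sum over rook neighbour pairs
  moran <- function(z, nx, ny) {
    zc <- z - mean(z)
    num <- 0; W <- 0
    for (j in seq_along(z)) {
      x <- (j - 1) %% nx; y <- (j - 1) %/% nx
      for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        xx <- x + o[1]; yy <- y + o[2]
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny) {
          k <- xx + yy * nx + 1
          num <- num + zc[j] * zc[k]; W <- W + 1
        }
      }
    }
    length(z) / W * num / sum(zc^2)
  }
  I_white <- moran(gr$covariates[, "white"], 50, 50)
  I_smooth <- moran(gr$covariates[, "smooth"], 50, 50)
  expect_gt(I_smooth, I_white)
  expect_gt(I_smooth, 0.5)
})

test_that("landscape rejects bad configurations", {
  expect_error(sim_config(nx = 1, ny = 2), "at least 4")
  expect_error(sim_config(covariates = list(cov_spec("a"), cov_spec("a")),
                          beta_lambda = c(0, 0, 0)), "duplicate")
  expect_error(sim_config(phi = 0), "phi")
  expect_error(sim_config(effort_range = c(0L, 5L)), "effort")
})

test_that("latent abundance follows the NegBin mean/variance structure", {
  cfg <- sim_config(nx = 317, ny = 316, n_sites = 10,  # ~1e5 cells
                    covariates = list(cov_spec("z", 0)),
                    beta_lambda = c(log(3), 0), phi = 2, seed = 11)
  gr <- generate_landscape(cfg)
  # zero slopes: lambda = 3 everywhere
  lat <- simulate_latent_abundance(gr, c(log(3), 0), phi = 2, seed = 12)
  expect_equal(lat$lambda, rep(3, gr$G), tolerance = 1e-12)
  expect_true(all(lat$N >= 0 & lat$N == floor(lat$N)))
  expect_equal(mean(lat$N), 3, tolerance = 0.03)
  expect_equal(var(lat$N), 3 + 9 / 2, tolerance = 0.05)  # lam + lam^2/phi
  # Poisson limit at huge dispersion
  lat2 <- simulate_latent_abundance(gr, c(log(3), 0), phi = 1e8, seed = 13)
  expect_equal(mean(lat2$N), 3, tolerance = 0.03)
  expect_equal(var(lat2$N), 3, tolerance = 0.05)
  # beta = 0, omega = 0 -> lambda 1
  lat3 <- simulate_latent_abundance(gr, c(0, 0), phi = 2, seed = 14)
  expect_true(all(lat3$lambda == 1))
  expect_error(simulate_latent_abundance(gr, c(0, 0), phi = -1, seed = 1), "phi")
  expect_error(simulate_latent_abundance(gr, c(0, 0, 0, 0), phi = 1, seed = 1),
               "does not match")
})

test_that("camera counts are Poisson with the effort offset", {
  # many replicate sites on a 2-cell-abundance landscape: E[y] = N * gamma * d
  cfg <- sim_config(nx = 230, ny = 220, n_sites = 50000,
                    covariates = list(cov_spec("z", 0)),
                    beta_lambda = c(0, 0), beta_gamma = c(0), sigma = 0,
                    effort_range = c(2L, 2L), max_per_cell = 1L,
                    n_site_covariates = 0L, seed = 21)
  gr <- generate_landscape(cfg)
  N <- rep(2L, gr$G)
  svy <- simulate_camera_survey(gr, N, cfg, seed = 22)
  expect_equal(mean(svy$y), 4, tolerance = 0.02)        # 2 * 1 * 2
  expect_equal(var(svy$y), 4, tolerance = 0.05)         # Poisson dispersion
  # zero abundance -> zero counts always
  svy0 <- simulate_camera_survey(gr, rep(0L, gr$G), cfg, seed = 23)
  expect_true(all(svy0$y == 0))
  # doubling effort doubles the expectation
  cfg2 <- sim_config(nx = 230, ny = 220, n_sites = 50000,
                     covariates = list(cov_spec("z", 0)),
                     beta_lambda = c(0, 0), beta_gamma = c(0), sigma = 0,
                     effort_range = c(4L, 4L), max_per_cell = 1L,
                     n_site_covariates = 0L, seed = 21)
  svy2 <- simulate_camera_survey(generate_landscape(cfg2), N, cfg2, seed = 22)
  expect_equal(mean(svy2$y) / mean(svy$y), 2, tolerance = 0.02)
  expect_error(simulate_camera_survey(gr, rep(-1L, gr$G), cfg, seed = 1),
               "negative")
})

test_that("trait table carries the six reference species and is deterministic", {
  tr <- simulate_trait_table(6)
  expect_equal(tr$body_mass_kg[tr$species == "red_deer_female"], 90)
  expect_equal(sort(tr$body_mass_kg), c(20, 80, 90, 150, 200, 400))
  expect_false(anyNA(tr))
  tr1 <- simulate_trait_table(4, seed = 5)
  expect_identical(tr1, simulate_trait_table(4, seed = 5))
  expect_true(all(tr1$gut_type %in% c("ruminant", "monogastric")))
  expect_equal(nrow(simulate_trait_table(1)), 1)
  expect_error(simulate_trait_table(0), "n_species")
})

test_that("vegetation plots reproduce planted browse probabilities", {
  labels <- rep(c(1, 2), each = 50)
  plots <- simulate_vegetation_plots(labels, c("1" = 0.6, "2" = 0.2),
                                     n_plots = 1000, seed = 31)
  bi <- browsing_intensity(plots)
  m <- tapply(bi$intensity, bi$cluster, mean, na.rm = TRUE)
  expect_lt(abs(m[["1"]] - 0.6), 0.05)
  expect_lt(abs(m[["2"]] - 0.2), 0.05)
  # degenerate probabilities
  p0 <- simulate_vegetation_plots(labels, c("1" = 0, "2" = 0), n_plots = 200, seed = 32)
  expect_true(all(browsing_intensity(p0)$intensity == 0, na.rm = TRUE))
  p1 <- simulate_vegetation_plots(labels, c("1" = 1, "2" = 1), n_plots = 200, seed = 33)
  i1 <- browsing_intensity(p1)$intensity
  expect_true(all(i1[!is.na(i1)] == 1))
  expect_error(simulate_vegetation_plots(labels, c(1.2, 0.1), n_plots = 10),
               "\\[0, 1\\]")
})

test_that("counts aggregated within a cell stay Poisson when sigma = 0", {
  # dispersion index of summed counts per cell at fixed N: variance/mean ~ 1
  cfg <- sim_config(nx = 100, ny = 100, n_sites = 20000,
                    covariates = list(cov_spec("z", 0)),
                    beta_lambda = c(0, 0), beta_gamma = c(-0.5), sigma = 0,
                    effort_range = c(3L, 3L), max_per_cell = 2L,
                    n_site_covariates = 0L, seed = 41)
  gr <- generate_landscape(cfg)
  N <- rep(3L, gr$G)
  svy <- simulate_camera_survey(gr, N, cfg, seed = 42)
  agg <- tapply(svy$y, svy$cell, sum)
  n_per <- tapply(svy$y, svy$cell, length)
  two <- agg[n_per == 2]  # cells with two cameras share one N
  expect_equal(var(two) / mean(two), 1, tolerance = 0.05)
})
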