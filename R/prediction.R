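#' Posterior relative-density surface
#'
#' Per draw, `lambda_j = exp(x_j' beta_lambda + (K delta)_j)` (the spatial
#' term is dropped when `include_sre = FALSE`); the surface reports the
#' cellwise posterior mean and quantile credibility interval.
#'
#' @param samples `posterior_samples` from a fitted [abundance_model()].
#' @param model the fitted model (supplies `X_lambda` and the basis).
#' @param include_sre include the spatial random effects in the prediction?
#' @param levels CI quantiles.
#' @param species optional species label carried in the result.
#' @return a `density_surface` data.frame: `cell`, `mean`, `lower`, `upper`.
#' @export
predict_lambda_surface <- function(samples, model, include_sre = TRUE,
                                   levels = c(0.025, 0.975), species = NA_character_) {
  lam <- lambda_draws(samples, model, include_sre)
  qs <- apply(lam, 2, quantile, probs = levels, names = FALSE)
  out <- data.frame(cell = seq_len(model$G), mean = colMeans(lam),
                    lower = qs[1, ], upper = qs[2, ])
  attr(out, "species") <- species
  attr(out, "include_sre") <- include_sre
  class(out) <- c("density_surface", "data.frame")
  out
}

# draws x G matrix of lambda surfaces
lambda_draws <- function(samples, model, include_sre = TRUE) {
  m <- pool_draws(samples)
  g <- samples$groups
  loglam <- m[, g$beta_lambda, drop = FALSE] %*% t(model$X_lambda)
  if (include_sre && model$q > 0)
    loglam <- loglam + m[, g$delta, drop = FALSE] %*% t(model$basis$K)
  exp(loglam)
}

#' Posterior mean spatial random effects
#'
#' The fitted spatial residual surface `omega = K delta` — log-scale
#' deviations from the covariate-explained density ("hot/cold spots"),
#' orthogonal to the fixed-effect design by construction.
#'
#' @param samples `posterior_samples`.
#' @param model the fitted [abundance_model()] (must carry a spatial basis).
#' @return data.frame `cell`, `mean`, `lower`, `upper` of `omega` per cell.
#' @export
extract_spatial_effects <- function(samples, model, levels = c(0.025, 0.975)) {
  if (model$q == 0) stop("model was fitted without a spatial basis")
  m <- pool_draws(samples)
  om <- m[, samples$groups$delta, drop = FALSE] %*% t(model$basis$K)
  qs <- apply(om, 2, quantile, probs = levels, names = FALSE)
  data.frame(cell = seq_len(model$G), mean = colMeans(om),
             lower = qs[1, ], upper = qs[2, ])
}

#' Covariate effect curve on the response scale
#'
#' Varies one (standardized) covariate over a grid of values with every other
#' covariate held at 0 (its mean) and the intercept included; if the covariate
#' has a quadratic column it moves with its parent. Returns the posterior mean
#' and CI of the response (`lambda` or `gamma`) at each value.
#'
#' @param samples `posterior_samples`.
#' @param model the fitted [abundance_model()].
#' @param covariate covariate (column) name.
#' @param values grid of standardized covariate values.
#' @param scale `"lambda"` (relative density) or `"gamma"` (trapping rate).
#' @param levels CI quantiles.
#' @return data.frame `value`, `mean`, `lower`, `upper`.
#' @export
effect_curve <- function(samples, model, covariate,
                         values = seq(-2, 2, length.out = 41),
                         scale = c("lambda", "gamma"),
                         levels = c(0.025, 0.975)) {
  scale <- match.arg(scale)
  X <- if (scale == "lambda") model$X_lambda else model$X_gamma
  g <- samples$groups
  idx <- if (scale == "lambda") g$beta_lambda else g$beta_gamma
  cn <- colnames(X)
  if (!covariate %in% cn) stop("unknown covariate: ", covariate)
  Xnew <- matrix(0, length(values), ncol(X), dimnames = list(NULL, cn))
  Xnew[, "(Intercept)"] <- 1
  Xnew[, covariate] <- values
  qcol <- paste0(covariate, "_sq")
  if (qcol %in% cn) Xnew[, qcol] <- values^2
  m <- pool_draws(samples)[, idx, drop = FALSE]
  resp <- exp(m %*% t(Xnew))
  qs <- apply(resp, 2, quantile, probs = levels, names = FALSE)
  data.frame(value = values, mean = colMeans(resp), lower = qs[1, ], upper = qs[2, ])
}

#' Ranked density curve
#'
#' Cell values sorted in descending order (ties keep the original cell-index
#' order), e.g. to compare how concentrated different species' landscape use
#' is.
#'
#' @param surface a `density_surface` or a numeric vector of cell values.
#' @return data.frame `rank`, `cell`, `value`.
#' @export
ranked_density_curve <- function(surface) {
  v <- if (is.data.frame(surface)) surface$mean else as.numeric(surface)
  cells <- if (is.data.frame(surface)) surface$cell else seq_along(v)
  ord <- order(-v, cells)   # stable: ties by cell index
  data.frame(rank = seq_along(v), cell = cells[ord], value = v[ord])
}

#' Export a fitted density surface as a standardized risk covariate
#'
#' Standardizes a predator's posterior-mean density surface (zero mean, unit
#' SD over cells) so it can enter a prey model's landscape design like any
#' other covariate.
#'
#' @param surface a `density_surface`.
#' @param name column name for the exported covariate.
#' @return one-column matrix of standardized per-cell values.
#' @export
risk_covariate <- function(surface, name = "predator_risk") {
  z <- standardize_covariates(matrix(surface$mean, ncol = 1,
                                     dimnames = list(NULL, name)))
  z$data
}
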